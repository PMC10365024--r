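# Internal helpers: classed errors, deterministic seeds, atomic writes.

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "pathnetvar_error", "error")))
}

.format_error    <- function(msg) .err(msg, "pnv_format_error")
.degenerate      <- function(msg) .err(msg, "pnv_degenerate_error")
.empty_overlap   <- function(msg) .err(msg, "pnv_empty_overlap_error")
.input_error     <- function(msg) .err(msg, "pnv_input_error")

# Stable 31-bit polynomial hash of a string; platform-independent, so
# per-pathway seeds do not depend on locale or iteration order.
.string_hash <- function(x) {
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Derive a reproducible child seed from a global seed and a string key
#'
#' Used to give every pathway (and every stochastic sub-step) its own
#' deterministic RNG seed, so results do not depend on the order in which
#' pathways are processed.
#'
#' @param seed Integer global seed.
#' @param key Character key, e.g. a pathway name.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  h <- ((abs(seed) %% 2147483647) * 48271) %% 2147483647
  as.integer((h + .string_hash(key)) %% 2147483647)
}

# Write a file atomically: the writer receives a temporary path in the
# destination directory, which is renamed into place only on success.
.write_atomic <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = basename(path), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    .err(sprintf("cannot write '%s'", path), "pnv_io_error")
  }
  invisible(path)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
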