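#' Named collection of gene sets (pathways)
#'
#' Holds a mapping from pathway name to a duplicate-free set of gene
#' identifiers, the gene universe (always the union of all member sets —
#' this is the population the permutation null samples from), and optional
#' per-pathway descriptions. Identifiers are opaque, case-sensitive
#' strings; no symbol normalization is attempted.
#'
#' @param pathways Named list of character vectors of gene identifiers.
#' @param descriptions Optional named character vector of descriptions.
#' @param source_description Free-text provenance note.
#' @return An object of class `pathway_collection` with components
#'   `pathways`, `universe`, `descriptions`, `source_description`.
#' @export
pathway_collection <- function(pathways, descriptions = NULL,
                               source_description = "") {
  if (length(pathways) == 0L) .input_error("empty pathway collection")
  nms <- names(pathways)
  if (is.null(nms) || any(!nzchar(nms))) .input_error("pathways must be named")
  if (anyDuplicated(nms)) {
    .input_error(sprintf("duplicate pathway name: '%s'",
                         nms[duplicated(nms)][1L]))
  }
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0L)) .input_error("pathway with no genes")
  if (is.null(descriptions)) {
    descriptions <- stats::setNames(rep("", length(pathways)), nms)
  }
  structure(list(
    pathways = pathways,
    universe = unique(unlist(pathways, use.names = FALSE)),
    descriptions = descriptions[nms],
    source_description = source_description
  ), class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' Read a GMT gene-set file
#'
#' Parses the MSigDB GMT dialect: one pathway per line, tab-separated as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate gene symbols
#' within a line are collapsed; duplicate pathway names are an error; a
#' line with fewer than three fields is a format error naming the line.
#'
#' @param path Path to the .gmt file.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) .format_error(sprintf("file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) .format_error(sprintf("empty GMT file: '%s'", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    .format_error(sprintf("malformed GMT line %d in '%s': fewer than 3 fields",
                          bad[1L], path))
  }
  nms <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nms)) {
    .format_error(sprintf("duplicate pathway name '%s' in '%s'",
                          nms[duplicated(nms)][1L], path))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])]))
  names(sets) <- nms
  descs <- stats::setNames(vapply(fields, `[[`, "", 2L), nms)
  pathway_collection(sets, descriptions = descs,
                     source_description = sprintf("GMT file '%s'", path))
}

#' Write a pathway collection in GMT format
#'
#' @param collection A [pathway_collection].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  .write_atomic(path, function(tmp) {
    lines <- vapply(names(collection$pathways), function(nm) {
      paste(c(nm, collection$descriptions[[nm]], collection$pathways[[nm]]),
            collapse = "\t")
    }, "")
    writeLines(lines, tmp)
  })
}
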