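#' Sample covariate table
#'
#' A table of per-sample covariates, each tagged `categorical` or
#' `numerical`; the tag decides which association test is used downstream
#' (Kruskal-Wallis versus Pearson correlation).
#'
#' @param samples Character vector of sample identifiers.
#' @param data Data frame of covariates (one row per sample).
#' @param types Named character vector, `"categorical"` or `"numerical"`
#'   per covariate; inferred from column classes when `NULL`.
#' @return An object of class `covariate_table`: a data frame with a
#'   `sample` column, covariate columns, and a `types` attribute.
#' @export
covariate_table <- function(samples, data, types = NULL) {
  samples <- as.character(samples)
  if (anyDuplicated(samples)) .input_error("duplicate sample identifiers")
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (nrow(data) != length(samples)) {
    .input_error("covariate rows must match samples")
  }
  if (is.null(types)) {
    types <- vapply(data, function(col) {
      if (is.numeric(col)) "numerical" else "categorical"
    }, "")
  }
  types <- types[names(data)]
  if (anyNA(types) || !all(types %in% c("categorical", "numerical"))) {
    .input_error("covariate types must be 'categorical' or 'numerical'")
  }
  out <- cbind(data.frame(sample = samples, stringsAsFactors = FALSE), data)
  attr(out, "types") <- types
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Read a sample covariate table from TSV
#'
#' Expects a header with first column `sample`. A column whose non-missing
#' values all parse as numbers is tagged `numerical`, anything else
#' `categorical`; the `categorical` argument overrides the inference for
#' named columns (e.g. integer-coded tumor grades).
#'
#' @param path Path to the TSV file.
#' @param categorical Character vector of column names to force categorical.
#' @return A [covariate_table].
#' @export
read_covariates <- function(path, categorical = NULL) {
  if (!file.exists(path)) .format_error(sprintf("file not found: '%s'", path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "", na.strings = c("NA", ""))
  if (ncol(df) < 2L || tolower(names(df)[1L]) != "sample") {
    .format_error("covariate table requires a leading 'sample' column")
  }
  data <- df[, -1L, drop = FALSE]
  types <- vapply(names(data), function(nm) {
    col <- data[[nm]]
    if (nm %in% categorical) return("categorical")
    num <- suppressWarnings(as.numeric(col))
    if (all(is.na(num) == is.na(col))) "numerical" else "categorical"
  }, "")
  for (nm in names(data)) {
    data[[nm]] <- if (types[[nm]] == "numerical") {
      suppressWarnings(as.numeric(data[[nm]]))
    } else {
      as.character(data[[nm]])
    }
  }
  covariate_table(as.character(df[[1L]]), data, types)
}

#' Write a covariate table as TSV
#' @param covars A [covariate_table].
#' @param path Output path.
#' @export
write_covariates <- function(covars, path) {
  stopifnot(inherits(covars, "covariate_table"))
  .write_atomic(path, function(tmp) {
    utils::write.table(as.data.frame(covars), tmp, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
}
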