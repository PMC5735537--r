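#' Load a delimited feature matrix and response
#'
#' Reads a CSV/TSV feature table (header row of feature names, one row per
#' sample) together with a response, given either as a separate
#' single-column file or as a named column of the feature table.  Values
#' must be fully numeric: missing or non-numeric cells are rejected with
#' their row/column location, never imputed.  The response is validated
#' against the family's domain (nonnegative counts for poisson, values in
#' \eqn{[0, 1]} for logistic).
#'
#' The delimiter is taken from the file extension (`.tsv`/`.tab` means
#' tab, anything else comma) unless `sep` is given; the same numbers in
#' CSV or TSV form load identically.
#'
#' @param features_path Path to the delimited feature table.
#' @param response_path Path to a single-column response file (header
#'   optional); mutually exclusive with `response_column`.
#' @param response_column Name of the feature-table column to use as the
#'   response.
#' @param family Family name used for response-domain validation.
#' @param sep Field separator; `NULL` picks it from the file extension.
#' @return An object of class `l0_dataset`: list with `x` (numeric
#'   matrix), `y`, `feature_names` and `family`.
#' @export
read_dataset <- function(features_path, response_path = NULL,
                         response_column = NULL,
                         family = c("linear", "logistic", "poisson"),
                         sep = NULL) {
  family <- l0_family(family)
  if (is.null(response_path) == is.null(response_column))
    stop("give exactly one of 'response_path' or 'response_column'")
  feat <- read_delim_numeric(features_path, sep, header = TRUE)
  if (!is.null(response_column)) {
    if (!response_column %in% colnames(feat))
      stop("response column '", response_column, "' not found in ",
           features_path)
    y <- feat[, response_column]
    x <- feat[, setdiff(colnames(feat), response_column), drop = FALSE]
  } else {
    resp <- read_delim_numeric(response_path, sep, header = NA)
    if (ncol(resp) != 1L)
      stop("response file ", response_path, " must have a single column")
    y <- resp[, 1L]
    x <- feat
    if (length(y) != nrow(x))
      stop("response length (", length(y), ") does not match the number ",
           "of samples (", nrow(x), ")")
  }
  if (anyDuplicated(colnames(x)))
    stop("feature names must be unique")
  family$check_y(y)
  structure(list(x = x, y = unname(y), feature_names = colnames(x),
                 family = family$name),
            class = "l0_dataset")
}

# strict numeric reader; header = NA sniffs whether the first row is a label
read_delim_numeric <- function(path, sep, header) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
    header <- any(is.na(suppressWarnings(as.numeric(first))))
  }
  df <- tryCatch(
    read.table(path, header = header, sep = sep, colClasses = "character",
               check.names = FALSE, strip.white = TRUE),
    error = function(e) stop("could not parse ", path, ": ",
                             conditionMessage(e)))
  m <- as.matrix(df)
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m),
                                dimnames = dimnames(m)))
  bad <- which(is.na(num) | m == "" | toupper(m) %in% c("NA", "NAN"),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-numeric or missing value in ", path, " at row ", bad[1L, 1L],
         ", column ", bad[1L, 2L],
         if (!is.null(colnames(m))) paste0(" ('", colnames(m)[bad[1L, 2L]],
                                           "')"),
         " (value: '", m[bad[1L, , drop = FALSE]], "')")
  num
}

#' Write a dataset to delimited text
#'
#' Writes the feature matrix (with a header of feature names) and the
#' response as delimited text at full double precision, so that
#' [read_dataset()] reproduces the values exactly.
#'
#' @param dataset An `l0_dataset` (from [read_dataset()]) or any list with
#'   elements `x` and `y`.
#' @param features_path Output path for the feature table.
#' @param response_path Output path for the single-column response file.
#' @param sep Field separator; `NULL` picks it from `features_path`'s
#'   extension.
#' @return Invisibly, the two paths.
#' @export
write_dataset <- function(dataset, features_path, response_path,
                          sep = NULL) {
  x <- as.matrix(dataset$x)
  y <- as.numeric(dataset$y)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|tab)$", features_path, ignore.case = TRUE))
      "\t" else ","
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(paste(colnames(x), collapse = sep),
             apply(x, 1L, function(r) paste(fmt(r), collapse = sep)))
  writeLines(lines, features_path)
  writeLines(c("y", fmt(y)), response_path)
  invisible(c(features_path, response_path))
}
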