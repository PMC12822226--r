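#' Construct an omics matrix
#'
#' An omics matrix is an ordinary numeric matrix with samples as rows and
#' features as columns, unique sample ids as rownames, unique feature ids as
#' colnames, and an `omics_tag` attribute recording the assay type. All
#' functions in this package accept any numeric matrix of that shape; this
#' constructor validates the invariants up front.
#'
#' @param values numeric matrix, samples x features. `NA` marks missing values
#'   (allowed until imputation).
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param feature_ids character vector of unique feature identifiers; defaults
#'   to `colnames(values)`.
#' @param omics_tag one of `"rna"`, `"methylation"`, `"fused"`, `"other"`.
#' @return the validated matrix with dimnames and an `omics_tag` attribute.
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 2, 3,
#'   dimnames = list(c("s1", "s2"), c("g1", "g2", "g3"))))
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         omics_tag = c("rna", "methylation", "fused", "other")) {
  omics_tag <- match.arg(omics_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("sample and feature ids are required (set dimnames or pass them)")
  }
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) must equal nrow(values)")
  }
  if (length(feature_ids) != ncol(values)) {
    stop("length(feature_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(feature_ids)) stop("feature ids must be unique")
  dimnames(values) <- list(sample_ids, feature_ids)
  attr(values, "omics_tag") <- omics_tag
  values
}

#' Assay tag of an omics matrix
#'
#' @param m omics matrix.
#' @param default tag returned when `m` carries none.
#' @return the `omics_tag` attribute, or `default` if unset.
#' @export
omics_tag <- function(m, default = "other") {
  tag <- attr(m, "omics_tag", exact = TRUE)
  if (is.null(tag)) default else tag
}

# Internal: common validation used by the operations. Most checks are cheap;
# missingness is only disallowed where an op requires an imputed matrix.
check_matrix <- function(m, allow_missing = TRUE, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) stop(sprintf("'%s' must be a numeric matrix", what))
  if (nrow(m) == 0L || ncol(m) == 0L) stop(sprintf("'%s' is empty", what))
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(sprintf("'%s' must have sample rownames and feature colnames", what))
  }
  if (!allow_missing && anyNA(m)) {
    stop(sprintf("'%s' contains missing values; impute first", what))
  }
  invisible(m)
}

#' Read a delimited omics matrix
#'
#' Reads a TSV/CSV table whose first column holds sample ids (or feature ids
#' when `transpose = TRUE`) and whose header row holds the other dimension's
#' ids. Empty fields and `"NA"` are read as missing.
#'
#' @param path file path.
#' @param sep field separator; inferred from the extension (`.csv` gives
#'   `","`, anything else tab) when `NULL`.
#' @param transpose if `TRUE` the file is features x samples and is transposed
#'   on read.
#' @param omics_tag assay tag to attach.
#' @return an [omics_matrix()].
#' @export
read_omics <- function(path, sep = NULL, transpose = FALSE,
                       omics_tag = c("rna", "methylation", "fused", "other")) {
  omics_tag <- match.arg(omics_tag)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE, na.strings = c("NA", ""),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (transpose) m <- t(m)
  omics_matrix(m, omics_tag = omics_tag)
}

#' Write an omics matrix to a delimited file
#'
#' @param m omics matrix.
#' @param path output path; `.csv` extension selects comma separation.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_omics <- function(m, path, sep = NULL) {
  check_matrix(m)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a clinical table
#'
#' Expects columns `sample_id` and `label` (extra columns are kept but
#' ignored by downstream functions).
#'
#' @param path TSV/CSV file path.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data frame with character `sample_id` and `label` columns.
#' @export
read_clinical <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("clinical table must have 'sample_id' and 'label' columns")
  }
  df$sample_id <- as.character(df$sample_id)
  df$label <- as.character(df$label)
  if (anyDuplicated(df$sample_id)) stop("clinical sample_id values must be unique")
  if (any(!nzchar(df$label) | is.na(df$label))) stop("clinical labels must be non-empty")
  df
}
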