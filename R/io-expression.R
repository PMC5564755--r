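#' Read a feature-by-sample expression matrix from TSV
#'
#' Reads a TSV with feature ids (genes or exons) in the first column and one
#' column per sample. Values must be nonnegative (FPKM/RPKM or raw counts;
#' the unit is recorded as an attribute, not inferred). When a manifest is
#' supplied, every expression column must be a known sample.
#'
#' @param path TSV path.
#' @param manifest Optional [cohort_manifest()] to validate sample ids
#'   against.
#' @param unit Unit tag to attach ("FPKM", "RPKM" or "count").
#' @return Numeric matrix (features x samples) with attribute `unit`.
#' @export
read_expression_matrix <- function(path, manifest = NULL,
                                   unit = c("FPKM", "RPKM", "count")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  expression_matrix(m, manifest = manifest, unit = unit)
}

#' Validate an in-memory expression matrix
#'
#' @param m Numeric matrix, features x samples, with dimnames.
#' @param manifest Optional manifest for sample-id validation.
#' @param unit Unit tag.
#' @return The validated matrix with attribute `unit`.
#' @export
expression_matrix <- function(m, manifest = NULL, unit = c("FPKM", "RPKM", "count")) {
  unit <- match.arg(unit)
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("expression matrix must have feature rownames and sample colnames")
  }
  if (anyNA(m)) stop("expression matrix contains missing values")
  if (any(m < 0)) stop("expression matrix contains negative values")
  if (!is.null(manifest)) {
    unknown <- setdiff(colnames(m), manifest$sample_id)
    if (length(unknown) > 0) {
      stop("expression columns not in manifest: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  attr(m, "unit") <- unit
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_column Header for the feature-id column.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
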