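#' Format p-values as in the nomination report
#'
#' Two significant figures in scientific notation (`2.0053e-5` prints as
#' `"2.0E-05"`); NA renders as `"*"` (unavailable).
#'
#' @param p Numeric vector.
#' @return Character vector.
#' @examples
#' format_pvalue(c(2.0053e-5, NA, 0.0425))
#' @export
format_pvalue <- function(p) {
  out <- ifelse(is.na(p), "*", formatC(signif(p, 2), format = "E", digits = 1))
  as.character(out)
}

.format_num <- function(x, digits = 3) {
  ifelse(is.na(x), "*", formatC(signif(x, digits), format = "fg", flag = "#"))
}

.format_yn <- function(x) ifelse(is.na(x), "*", ifelse(x, "Y", "N"))

#' Write the nomination report
#'
#' Serializes candidate records as a TSV whose columns mirror the
#' nomination-table layout: gene symbols, chromosomes, strand
#' configuration, partner distance, junction-at-splice-site and in-frame
#' flags (Y/N), positive tumor/benign counts, the Fisher enrichment p, mean
#' and variance of breakpoint expression over positive tumor and benign
#' samples, and the paired Wilcoxon p. P-values are printed to 2
#' significant figures in scientific notation; unavailable cells print as
#' `"*"`. A Benjamini-Hochberg column (`fisher_q`) is included for
#' transparency; it is never used for filtering.
#'
#' @param records Candidate records (the `records` element of a
#'   [run_cascade()] result).
#' @param path Output TSV path.
#' @return The path, invisibly. An empty record set writes a header-only
#'   file.
#' @export
write_nomination_report <- function(records, path) {
  df <- data.frame(
    gene5 = records$gene5,
    gene3 = records$gene3,
    chrom5 = records$chrom5,
    chrom3 = records$chrom3,
    strand = paste0(records$strand5, records$strand3),
    distance_bp = ifelse(is.na(records$distance_bp), "*",
                         as.character(records$distance_bp)),
    junction_at_splice_site = .format_yn(records$at_splice_site),
    in_frame = .format_yn(records$in_frame),
    n_tumor_pos = records$n_tumor_pos,
    n_benign_pos = records$n_benign_pos,
    fisher_p = format_pvalue(records$fisher_p),
    expr_mean_tumor = .format_num(records$expr_mean_tumor),
    expr_var_tumor = format_pvalue(records$expr_var_tumor),
    expr_mean_benign = .format_num(records$expr_mean_benign),
    expr_var_benign = format_pvalue(records$expr_var_benign),
    wilcoxon_p = format_pvalue(records$wilcoxon_p),
    fisher_q = format_pvalue(records$fisher_q),
    multimap_ratio = .format_num(records$multimap_ratio),
    read_through = .format_yn(records$read_through),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a nomination report back
#'
#' Inverse of [write_nomination_report()] to printed precision: `"*"` cells
#' become NA, Y/N become logicals, numeric columns are parsed.
#'
#' @param path Report TSV path.
#' @return Data frame of candidate records (printed precision).
#' @export
read_nomination_report <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  parse_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "*", NA, x)))
  parse_yn <- function(x) ifelse(x == "*", NA, x == "Y")
  for (col in c("distance_bp", "fisher_p", "expr_mean_tumor", "expr_var_tumor",
                "expr_mean_benign", "expr_var_benign", "wilcoxon_p", "fisher_q",
                "multimap_ratio", "n_tumor_pos", "n_benign_pos")) {
    df[[col]] <- parse_num(df[[col]])
  }
  for (col in c("junction_at_splice_site", "in_frame", "read_through")) {
    df[[col]] <- parse_yn(df[[col]])
  }
  df
}
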