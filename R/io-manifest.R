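#' Construct and validate a cohort manifest
#'
#' The manifest lists every sample with its condition (`tumor`/`benign`),
#' optional pair id linking a tumor to its matched benign sample, and the
#' total number of mapped reads (needed for RPKM; fusion-caller tables do
#' not carry library sizes). Each pair id must occur on exactly one tumor
#' and one benign sample; sample ids must be unique.
#'
#' @param df Data frame with columns `sample_id`, `condition`, `pair_id`
#'   (NA / empty for unpaired samples) and `total_mapped_reads`.
#' @return A `cohort_manifest` data frame.
#' @export
cohort_manifest <- function(df) {
  req <- c("sample_id", "condition", "pair_id", "total_mapped_reads")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$pair_id <- as.character(df$pair_id)
  df$pair_id[!is.na(df$pair_id) & df$pair_id == ""] <- NA_character_
  df$total_mapped_reads <- as.numeric(df$total_mapped_reads)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  if (!all(df$condition %in% c("tumor", "benign"))) {
    stop("condition must be 'tumor' or 'benign'")
  }
  if (anyNA(df$total_mapped_reads) || any(df$total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive for every sample")
  }
  paired <- df[!is.na(df$pair_id), , drop = FALSE]
  if (nrow(paired) > 0) {
    tab <- table(paired$pair_id, paired$condition)
    if (!all(colnames(tab) %in% c("tumor", "benign")) ||
        ncol(tab) < 2 || any(tab != 1L)) {
      bad <- rownames(tab)[apply(tab, 1, function(r) any(r != 1L)) |
                             rowSums(tab) != 2L]
      stop("each pair_id must occur on exactly one tumor and one benign sample; ",
           "offending pair_id(s): ", paste(bad, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Read a cohort manifest from CSV or TSV
#'
#' @param path File path; comma-separated if it ends in `.csv`, otherwise
#'   tab-separated.
#' @return A validated `cohort_manifest` (see [cohort_manifest()]).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  cohort_manifest(df)
}

#' Summarize a cohort manifest
#'
#' @param object A `cohort_manifest`.
#' @param ... Unused.
#' @return List with `n_tumor`, `n_benign`, `n_pairs`, `n_unpaired_tumor`.
#' @export
summary.cohort_manifest <- function(object, ...) {
  n_pairs <- length(unique(object$pair_id[!is.na(object$pair_id)]))
  out <- list(
    n_tumor = sum(object$condition == "tumor"),
    n_benign = sum(object$condition == "benign"),
    n_pairs = n_pairs,
    n_unpaired_tumor = sum(object$condition == "tumor" & is.na(object$pair_id))
  )
  class(out) <- "summary.cohort_manifest"
  out
}

#' @export
print.summary.cohort_manifest <- function(x, ...) {
  cat(sprintf("Cohort: %d tumor / %d benign samples; %d matched pairs; %d unpaired tumors\n",
              x$n_tumor, x$n_benign, x$n_pairs, x$n_unpaired_tumor))
  invisible(x)
}

#' Write a cohort manifest as TSV
#'
#' @param manifest A `cohort_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(as.data.frame(manifest), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
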