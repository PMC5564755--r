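#' Filter thresholds for the nomination cascade
#'
#' Bundles every tunable cutoff used by the call-level screen and the
#' candidate filter cascade. The defaults are the published criteria:
#' at least 5 discordant read pairs, at least 1 junction split read,
#' classifier probability >= 0.05, presence in at least 5 tumor samples,
#' enrichment/overexpression alpha 0.05, multimapping-ratio removal above
#' 0.6, the paired overexpression gate triggered when a fusion is present in
#' more than 2 benign samples, and partner biotypes restricted to
#' protein-coding, lincRNA and miRNA genes.
#'
#' @param min_discordant_pairs Minimum discordant (spanning) read pairs per
#'   call (inclusive).
#' @param min_split_reads Minimum junction split reads per call (inclusive).
#' @param min_probability Minimum fusion-caller classifier probability
#'   (inclusive).
#' @param min_tumor_samples Recurrence cutoff: minimum positive tumor
#'   samples (inclusive).
#' @param alpha Significance level for the Fisher enrichment and paired
#'   overexpression filters.
#' @param max_multimap_ratio Candidates whose pooled multimapping/total
#'   spanning-read ratio is strictly greater than this are removed.
#' @param benign_presence_trigger The paired overexpression test is applied
#'   only to candidates positive in strictly more than this many benign
#'   samples.
#' @param allowed_biotypes Gene biotypes allowed for both partners.
#'   Pseudogene biotypes are always rejected.
#' @param read_length Read length in bp; the breakpoint region used for
#'   split-read RPKM is `2 * read_length` (a read must overlap the junction
#'   to be a split read).
#' @return An object of class `filter_thresholds`.
#' @examples
#' filter_thresholds()
#' filter_thresholds(alpha = 0.01)
#' @export
filter_thresholds <- function(min_discordant_pairs = 5L,
                              min_split_reads = 1L,
                              min_probability = 0.05,
                              min_tumor_samples = 5L,
                              alpha = 0.05,
                              max_multimap_ratio = 0.6,
                              benign_presence_trigger = 2L,
                              allowed_biotypes = c("protein_coding", "lincRNA", "miRNA"),
                              read_length = 100L) {
  t <- list(
    min_discordant_pairs = as.integer(min_discordant_pairs),
    min_split_reads = as.integer(min_split_reads),
    min_probability = as.numeric(min_probability),
    min_tumor_samples = as.integer(min_tumor_samples),
    alpha = as.numeric(alpha),
    max_multimap_ratio = as.numeric(max_multimap_ratio),
    benign_presence_trigger = as.integer(benign_presence_trigger),
    allowed_biotypes = as.character(allowed_biotypes),
    read_length = as.integer(read_length)
  )
  nums <- c(t$min_discordant_pairs, t$min_split_reads, t$min_probability,
            t$min_tumor_samples, t$alpha, t$max_multimap_ratio,
            t$benign_presence_trigger, t$read_length)
  if (any(!is.finite(nums)) || any(nums < 0)) {
    stop("all thresholds must be finite and nonnegative")
  }
  if (t$alpha <= 0 || t$alpha > 1) stop("alpha must lie in (0, 1]")
  if (t$read_length < 1) stop("read_length must be positive")
  structure(t, class = "filter_thresholds")
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Fusion nomination filter thresholds\n")
  cat(sprintf("  call screen: discordant pairs >= %d, split reads >= %d, probability >= %g\n",
              x$min_discordant_pairs, x$min_split_reads, x$min_probability))
  cat(sprintf("  recurrence: >= %d positive tumor samples\n", x$min_tumor_samples))
  cat(sprintf("  enrichment/overexpression alpha: %g (overexpression gate: > %d benign positives)\n",
              x$alpha, x$benign_presence_trigger))
  cat(sprintf("  multimap ratio removal: > %g\n", x$max_multimap_ratio))
  cat(sprintf("  allowed biotypes: %s\n", paste(x$allowed_biotypes, collapse = ", ")))
  cat(sprintf("  read length: %d bp (breakpoint region %d bp)\n",
              x$read_length, 2L * x$read_length))
  invisible(x)
}
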