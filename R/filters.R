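#' Call-level screening criteria
#'
#' A call passes the initial screen iff it has at least
#' `min_discordant_pairs` discordant read pairs, at least `min_split_reads`
#' junction split reads, and classifier probability at least
#' `min_probability`. All three bounds are inclusive ("at least" / "no less
#' than").
#'
#' @param calls A `fusion_calls` data frame.
#' @param thresholds A [filter_thresholds()].
#' @return Logical vector, one entry per call.
#' @examples
#' # boundary call (5 pairs, 1 split read, p = 0.05) passes
#' @export
call_passes_initial <- function(calls, thresholds = filter_thresholds()) {
  calls$discordant_pairs >= thresholds$min_discordant_pairs &
    calls$split_reads >= thresholds$min_split_reads &
    calls$probability >= thresholds$min_probability
}

#' Aggregate screened calls into a gene-pair detection matrix
#'
#' Collapses per-sample calls into per-(gene pair, sample) positivity. A
#' sample is positive for an ordered (5', 3') gene pair iff it has at least
#' one call passing the initial screen for that pair; the support fields
#' retained for a positive cell are those of the call with the most split
#' reads (aggregation is idempotent over duplicate calls). Reciprocal
#' orientations are distinct pairs. Calls failing the screen are dropped
#' here (and counted in the cascade log upstream).
#'
#' @param calls A `fusion_calls` data frame (screened or unscreened; rows
#'   failing [call_passes_initial()] are ignored).
#' @param manifest A [cohort_manifest()]; every call's sample must be listed.
#' @param thresholds A [filter_thresholds()].
#' @return An object of class `pair_detection` with elements `support`
#'   (long data frame: pair, sample_id, support fields), `pairs` (one row
#'   per pair with the cohort-wide best-supported call's geometry) and
#'   `manifest`.
#' @export
aggregate_gene_pairs <- function(calls, manifest, thresholds = filter_thresholds()) {
  unknown <- setdiff(unique(calls$sample_id), manifest$sample_id)
  if (length(unknown) > 0) {
    stop("calls reference sample id(s) absent from manifest: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  keep <- call_passes_initial(calls, thresholds)
  df <- as.data.frame(calls)[keep, , drop = FALSE]
  df$pair <- paste(df$gene5, df$gene3, sep = "|")
  if (nrow(df) > 0) {
    # best call (max split reads) per (pair, sample); deterministic tie-break
    df <- df[order(df$pair, df$sample_id, -df$split_reads,
                   -df$discordant_pairs, df$breakpoint5), , drop = FALSE]
    support <- df[!duplicated(df[, c("pair", "sample_id")]), , drop = FALSE]
    # representative geometry per pair: cohort-wide max split reads
    best <- support[order(support$pair, -support$split_reads, support$sample_id), ,
                    drop = FALSE]
    pairs <- best[!duplicated(best$pair),
                  c("pair", "gene5", "gene3", "chrom5", "breakpoint5", "strand5",
                    "chrom3", "breakpoint3", "strand3"), drop = FALSE]
    support <- support[, c("pair", "sample_id", "split_reads", "discordant_pairs",
                           "multimap_spanning", "total_spanning", "probability")]
  } else {
    support <- data.frame(pair = character(0), sample_id = character(0),
                          split_reads = numeric(0), discordant_pairs = numeric(0),
                          multimap_spanning = numeric(0), total_spanning = numeric(0),
                          probability = numeric(0), stringsAsFactors = FALSE)
    pairs <- data.frame(pair = character(0), gene5 = character(0), gene3 = character(0),
                        chrom5 = character(0), breakpoint5 = numeric(0),
                        strand5 = character(0), chrom3 = character(0),
                        breakpoint3 = numeric(0), strand3 = character(0),
                        stringsAsFactors = FALSE)
  }
  pairs <- pairs[order(pairs$pair), , drop = FALSE]
  rownames(support) <- rownames(pairs) <- NULL
  structure(list(support = support, pairs = pairs, manifest = manifest),
            class = "pair_detection")
}

#' @export
print.pair_detection <- function(x, ...) {
  cat(sprintf("pair_detection: %d gene pairs, %d positive (pair, sample) cells over %d samples\n",
              nrow(x$pairs), nrow(x$support), nrow(x$manifest)))
  invisible(x)
}

#' Positive-sample counts per gene pair
#'
#' @param pdm A `pair_detection`.
#' @return Data frame: `pair`, `n_tumor_pos`, `n_benign_pos`.
#' @export
positive_counts <- function(pdm) {
  cond <- pdm$manifest$condition[match(pdm$support$sample_id, pdm$manifest$sample_id)]
  paired_ids <- pdm$manifest$sample_id
  tum <- tapply(cond == "tumor", pdm$support$pair, sum)
  ben <- tapply(cond == "benign", pdm$support$pair, sum)
  out <- data.frame(pair = pdm$pairs$pair, stringsAsFactors = FALSE)
  out$n_tumor_pos <- as.integer(ifelse(is.na(tum[out$pair]), 0L, tum[out$pair]))
  out$n_benign_pos <- as.integer(ifelse(is.na(ben[out$pair]), 0L, ben[out$pair]))
  out
}

#' Recurrence filter
#'
#' Keeps gene pairs detected in at least `min_tumor_samples` tumor samples
#' (inclusive boundary).
#'
#' @param pdm A `pair_detection`.
#' @param thresholds A [filter_thresholds()].
#' @return Character vector of surviving pair keys.
#' @export
recurrence_filter <- function(pdm, thresholds = filter_thresholds()) {
  counts <- positive_counts(pdm)
  counts$pair[counts$n_tumor_pos >= thresholds$min_tumor_samples]
}

#' Pooled multimapping-read ratio per gene pair
#'
#' Ratio of multimapping spanning reads to total spanning reads, summed
#' over the pair's positive samples (pooling is the stabler estimator when
#' per-sample totals are small). A pair with zero total spanning reads gets
#' ratio 0 with a warning. Candidates are removed downstream when the ratio
#' is strictly greater than `max_multimap_ratio`.
#'
#' @param pdm A `pair_detection`.
#' @param pairs Pair keys to compute (default: all).
#' @return Named numeric vector of ratios in \[0, 1\].
#' @export
multimap_ratio <- function(pdm, pairs = NULL) {
  if (is.null(pairs)) pairs <- pdm$pairs$pair
  s <- pdm$support[pdm$support$pair %in% pairs, , drop = FALSE]
  mm <- tapply(s$multimap_spanning, s$pair, sum)
  tot <- tapply(s$total_spanning, s$pair, sum)
  ratio <- stats::setNames(rep(0, length(pairs)), pairs)
  mm <- mm[pairs]; tot <- tot[pairs]
  zero <- is.na(tot) | tot == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero total spanning reads; ratio set to 0")
  }
  ratio[!zero] <- mm[!zero] / tot[!zero]
  ratio
}

.is_pseudogene <- function(biotype) grepl("pseudogene", biotype, fixed = TRUE)

#' Biotype and overlapping-gene filter
#'
#' A candidate is kept iff both partner genes have an allowed biotype
#' (pseudogene biotypes always reject) and the two genes' genomic spans do
#' not overlap on the same chromosome. Unannotated partners are rejected
#' with reason `"unannotated"`.
#'
#' @param pairs Data frame with columns `pair`, `gene5`, `gene3` (the
#'   `pairs` element of a `pair_detection`, possibly subset).
#' @param db An [annotation_db()].
#' @param thresholds A [filter_thresholds()].
#' @return Data frame: `pair`, `keep` (logical), `reason` (NA when kept).
#' @export
biotype_overlap_filter <- function(pairs, db, thresholds = filter_thresholds()) {
  res <- data.frame(pair = pairs$pair,
                    keep = rep_len(TRUE, nrow(pairs)),
                    reason = rep_len(NA_character_, nrow(pairs)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    g5 <- .gene_record(db, pairs$gene5[i])
    g3 <- .gene_record(db, pairs$gene3[i])
    if (is.null(g5) || is.null(g3)) {
      res$keep[i] <- FALSE
      res$reason[i] <- "unannotated"
      next
    }
    bad5 <- .is_pseudogene(g5$biotype) || !(g5$biotype %in% thresholds$allowed_biotypes)
    bad3 <- .is_pseudogene(g3$biotype) || !(g3$biotype %in% thresholds$allowed_biotypes)
    if (bad5 || bad3) {
      res$keep[i] <- FALSE
      res$reason[i] <- sprintf("biotype:%s",
                               if (bad5) g5$biotype else g3$biotype)
      next
    }
    if (g5$chrom == g3$chrom && g5$start <= g3$end && g3$start <= g5$end) {
      res$keep[i] <- FALSE
      res$reason[i] <- "overlapping_genes"
    }
  }
  res
}
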