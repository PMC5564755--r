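#' Per-sample breakpoint RPKM matrix for detected gene pairs
#'
#' Fusion expression proxy: split reads mapped to the breakpoint region
#' (of length `2 * read_length`) per kilobase per million mapped reads,
#' computed for every (pair, sample) cell; samples in which the pair was
#' not detected get 0.
#'
#' @param pdm A `pair_detection`.
#' @param thresholds A [filter_thresholds()] (supplies the read length).
#' @return Numeric matrix, pairs x manifest samples.
#' @export
pair_rpkm_matrix <- function(pdm, thresholds = filter_thresholds()) {
  region <- 2L * thresholds$read_length
  samples <- pdm$manifest$sample_id
  m <- matrix(0, nrow = nrow(pdm$pairs), ncol = length(samples),
              dimnames = list(pdm$pairs$pair, samples))
  if (nrow(pdm$support) > 0) {
    lib <- pdm$manifest$total_mapped_reads[match(pdm$support$sample_id, samples)]
    vals <- breakpoint_rpkm(pdm$support$split_reads, region, lib)
    m[cbind(pdm$support$pair, pdm$support$sample_id)] <- vals
  }
  m
}

# per-pair tumor/benign breakpoint-RPKM vectors over the matched pairs
.paired_rpkm <- function(rpkm, manifest) {
  paired <- manifest[!is.na(manifest$pair_id), , drop = FALSE]
  pair_ids <- sort(unique(paired$pair_id))
  tum <- paired$sample_id[match(paste0(pair_ids, ".tumor"),
                                paste0(paired$pair_id, ".", paired$condition))]
  ben <- paired$sample_id[match(paste0(pair_ids, ".benign"),
                                paste0(paired$pair_id, ".", paired$condition))]
  list(tumor = rpkm[, tum, drop = FALSE], benign = rpkm[, ben, drop = FALSE],
       pair_ids = pair_ids)
}

.log_entry <- function(stage, before, after, reason) {
  data.frame(stage = stage, n_before = before, n_after = after,
             reason = reason, stringsAsFactors = FALSE)
}

.removed_rows <- function(pairs, stage, reason) {
  data.frame(pair = pairs, stage = rep_len(stage, length(pairs)),
             reason = rep_len(reason, length(pairs)), stringsAsFactors = FALSE)
}

#' Run the candidate filter cascade
#'
#' Applies, in order: the call-level screen (read support and classifier
#' probability), tumor recurrence, one-sided Fisher enrichment (keep
#' p < alpha), the paired signed-rank overexpression gate (applied only to
#' candidates present in more than `benign_presence_trigger` benign
#' samples; keep p < alpha), the pooled multimapping-ratio filter (remove
#' ratio strictly above `max_multimap_ratio`), and the biotype/overlap
#' filter. Setting `alpha = 1` disables the two test-based filters
#' (useful for ablation).
#'
#' @param calls A `fusion_calls` data frame covering the cohort.
#' @param manifest A [cohort_manifest()].
#' @param db An [annotation_db()] for the biotype/overlap filter and
#'   junction annotation of survivors.
#' @param thresholds A [filter_thresholds()].
#' @param genome Optional contig sequences for peptide prediction.
#' @return An object of class `cascade_result`: `records` (candidate
#'   summary, one row per survivor), `log` (stage-by-stage survivor
#'   counts), `removed` (pair, stage, reason -- exactly one reason per
#'   removed pair), `pdm` (the detection matrix), `rpkm` (breakpoint RPKM
#'   matrix).
#' @export
run_cascade <- function(calls, manifest, db, thresholds = filter_thresholds(),
                        genome = NULL) {
  n_tumor <- sum(manifest$condition == "tumor")
  n_benign <- sum(manifest$condition == "benign")
  all_pairs <- unique(paste(calls$gene5, calls$gene3, sep = "|"))

  pdm <- aggregate_gene_pairs(calls, manifest, thresholds)
  log <- .log_entry("initial_criteria", length(all_pairs), nrow(pdm$pairs),
                    sprintf("discordant>=%d, split>=%d, prob>=%g",
                            thresholds$min_discordant_pairs,
                            thresholds$min_split_reads, thresholds$min_probability))
  removed <- .removed_rows(setdiff(all_pairs, pdm$pairs$pair),
                           "initial_criteria", "no call passing initial criteria")

  counts <- positive_counts(pdm)
  rownames(counts) <- counts$pair
  rpkm <- pair_rpkm_matrix(pdm, thresholds)

  # stage 1: recurrence
  surv <- recurrence_filter(pdm, thresholds)
  dropped <- setdiff(pdm$pairs$pair, surv)
  removed <- rbind(removed, .removed_rows(
    dropped, "recurrence",
    sprintf("tumor-positive < %d", thresholds$min_tumor_samples)))
  log <- rbind(log, .log_entry("recurrence", nrow(pdm$pairs), length(surv),
                               sprintf("present in >= %d tumor samples",
                                       thresholds$min_tumor_samples)))

  # stage 2: Fisher enrichment
  fisher_p <- stats::setNames(rep(NA_real_, length(surv)), surv)
  if (length(surv) > 0) {
    a <- counts[surv, "n_tumor_pos"]; c <- counts[surv, "n_benign_pos"]
    fisher_p[] <- fisher_enrichment(a, n_tumor - a, c, n_benign - c)
  }
  keep <- fisher_p < thresholds$alpha | thresholds$alpha >= 1
  removed <- rbind(removed, .removed_rows(
    surv[!keep], "enrichment", sprintf("Fisher p >= %g", thresholds$alpha)))
  log <- rbind(log, .log_entry("enrichment", length(surv), sum(keep),
                               sprintf("tumor enrichment, Fisher p < %g",
                                       thresholds$alpha)))
  surv <- surv[keep]

  # stage 3: paired overexpression gate for benign-prevalent candidates
  wilcoxon_p <- stats::setNames(rep(NA_real_, length(surv)), surv)
  gated <- surv[counts[surv, "n_benign_pos"] > thresholds$benign_presence_trigger]
  if (length(gated) > 0) {
    pr <- .paired_rpkm(rpkm, manifest)
    for (p in gated) {
      wilcoxon_p[p] <- suppressWarnings(
        paired_overexpression_test(pr$tumor[p, ], pr$benign[p, ]))
    }
  }
  keep <- is.na(wilcoxon_p) | wilcoxon_p < thresholds$alpha | thresholds$alpha >= 1
  removed <- rbind(removed, .removed_rows(
    surv[!keep], "overexpression",
    sprintf("paired signed-rank p >= %g with > %d benign positives",
            thresholds$alpha, thresholds$benign_presence_trigger)))
  log <- rbind(log, .log_entry(
    "overexpression", length(surv), sum(keep),
    sprintf("tumor > benign breakpoint RPKM (gate: > %d benign positives)",
            thresholds$benign_presence_trigger)))
  surv <- surv[keep]

  # stage 4: multimapping ratio (pooled; removal is strictly > threshold)
  ratio <- if (length(surv) > 0) multimap_ratio(pdm, surv) else numeric(0)
  keep <- ratio <= thresholds$max_multimap_ratio
  removed <- rbind(removed, .removed_rows(
    surv[!keep], "multimap",
    sprintf("multimap ratio > %g", thresholds$max_multimap_ratio)))
  log <- rbind(log, .log_entry("multimap", length(surv), sum(keep),
                               sprintf("multimap/total spanning ratio <= %g",
                                       thresholds$max_multimap_ratio)))
  surv <- surv[keep]

  # stage 5: biotype and overlapping-gene filter
  bo <- biotype_overlap_filter(pdm$pairs[match(surv, pdm$pairs$pair), , drop = FALSE],
                               db, thresholds)
  removed <- rbind(removed, .removed_rows(
    bo$pair[!bo$keep], "biotype_overlap", bo$reason[!bo$keep]))
  log <- rbind(log, .log_entry("biotype_overlap", length(surv), sum(bo$keep),
                               "allowed biotypes, non-overlapping spans"))
  surv <- bo$pair[bo$keep]

  records <- .build_records(surv, pdm, counts, fisher_p, wilcoxon_p,
                            multimap_ratio(pdm, surv), rpkm, manifest, db,
                            thresholds, genome)
  rownames(removed) <- rownames(log) <- NULL
  structure(list(records = records, log = log, removed = removed,
                 pdm = pdm, rpkm = rpkm, thresholds = thresholds),
            class = "cascade_result")
}

.build_records <- function(surv, pdm, counts, fisher_p, wilcoxon_p, ratio,
                           rpkm, manifest, db, thresholds, genome) {
  cols <- c("pair", "gene5", "gene3", "chrom5", "chrom3", "strand5", "strand3",
            "breakpoint5", "breakpoint3")
  rec <- pdm$pairs[match(surv, pdm$pairs$pair), cols, drop = FALSE]
  n <- nrow(rec)
  rec$distance_bp <- rep_len(NA_integer_, n)
  rec$read_through <- rep_len(NA, n)
  rec$at_splice_site <- rep_len(NA, n)
  rec$in_frame <- rep_len(NA, n)
  rec$n_tumor_pos <- counts[surv, "n_tumor_pos"]
  rec$n_benign_pos <- counts[surv, "n_benign_pos"]
  rec$fisher_p <- unname(fisher_p[surv])
  rec$wilcoxon_p <- unname(wilcoxon_p[surv])
  rec$multimap_ratio <- unname(ratio[surv])

  tum <- manifest$sample_id[manifest$condition == "tumor"]
  ben <- manifest$sample_id[manifest$condition == "benign"]
  pos_stats <- function(pair, group) {
    pos <- intersect(pdm$support$sample_id[pdm$support$pair == pair], group)
    v <- rpkm[pair, pos]
    c(mean = if (length(pos) == 0) 0 else mean(v),
      var = if (length(pos) < 2) NA_real_ else stats::var(v))
  }
  if (nrow(rec) > 0) {
    st <- t(vapply(rec$pair, pos_stats, numeric(2), group = tum))
    sb <- t(vapply(rec$pair, pos_stats, numeric(2), group = ben))
    rec$expr_mean_tumor <- st[, "mean"]; rec$expr_var_tumor <- st[, "var"]
    rec$expr_mean_benign <- sb[, "mean"]; rec$expr_var_benign <- sb[, "var"]
    for (i in seq_len(nrow(rec))) {
      g5 <- .gene_record(db, rec$gene5[i]); g3 <- .gene_record(db, rec$gene3[i])
      if (!is.null(g5) && !is.null(g3)) {
        geom <- classify_pair(rec$gene5[i], rec$gene3[i], db)
        rec$distance_bp[i] <- geom$inner_distance_bp
        rec$read_through[i] <- geom$read_through_candidate
        ja <- predict_frame(rec[i, ], db, genome = genome)
        rec$at_splice_site[i] <- ja$at_splice_sites
        rec$in_frame[i] <- ja$in_frame
      }
    }
  } else {
    rec$expr_mean_tumor <- rec$expr_var_tumor <- numeric(0)
    rec$expr_mean_benign <- rec$expr_var_benign <- numeric(0)
  }
  # transparency only: BH-adjusted enrichment p, never used for filtering
  rec$fisher_q <- stats::p.adjust(rec$fisher_p, method = "BH")
  rownames(rec) <- NULL
  rec
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Fusion candidate filter cascade\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-18s %5d -> %5d  (%s)\n", x$log$stage[i],
                x$log$n_before[i], x$log$n_after[i], x$log$reason[i]))
  }
  cat(sprintf("  nominated candidates: %d\n", nrow(x$records)))
  invisible(x)
}
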