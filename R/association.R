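#' Partition cohort samples by fusion detection status
#'
#' Splits the manifest samples into fusion-positive tumors, fusion-negative
#' tumors, and benign samples for one candidate gene pair. The three groups
#' are disjoint and exhaustive over the manifest.
#'
#' @param pair Pair key (`"GENE5|GENE3"`).
#' @param pdm A `pair_detection` (see [aggregate_gene_pairs()]).
#' @param manifest A [cohort_manifest()] (defaults to the one inside `pdm`).
#' @return List of sample-id vectors: `positive_tumor`, `negative_tumor`,
#'   `benign`.
#' @export
partition_samples <- function(pair, pdm, manifest = pdm$manifest) {
  pos <- pdm$support$sample_id[pdm$support$pair == pair]
  tumors <- manifest$sample_id[manifest$condition == "tumor"]
  benign <- manifest$sample_id[manifest$condition == "benign"]
  list(
    positive_tumor = intersect(tumors, pos),
    negative_tumor = setdiff(tumors, pos),
    benign = benign
  )
}

#' 3'-partner expression contrast between fusion-positive and -negative samples
#'
#' One-sided rank-sum tests of the 3' partner gene's expression:
#' fusion-positive tumors vs fusion-negative tumors, and fusion-positive
#' tumors vs benign samples. Up-regulation of the 3' partner in
#' fusion-positive samples is the expression signature of a read-through
#' fusion transcribed from the 5' partner's promoter.
#'
#' @param expr Expression matrix (genes x samples; see
#'   [expression_matrix()]).
#' @param gene3 Row name of the 3' partner gene in `expr`.
#' @param partition Sample partition from [partition_samples()].
#' @return List: `p_pos_vs_neg_tumor`, `p_pos_vs_benign`, `n_pos`, `n_neg`
#'   (NA p with a warning when a group is empty).
#' @export
three_prime_partner_test <- function(expr, gene3, partition) {
  if (!gene3 %in% rownames(expr)) stop("3' partner gene not in expression matrix: ", gene3)
  pos <- intersect(partition$positive_tumor, colnames(expr))
  neg <- intersect(partition$negative_tumor, colnames(expr))
  ben <- intersect(partition$benign, colnames(expr))
  p1 <- p2 <- NA_real_
  if (length(pos) == 0 || length(neg) == 0) {
    warning("empty fusion-positive or -negative tumor group; p undefined")
  } else {
    p1 <- unpaired_overexpression_test(expr[gene3, pos], expr[gene3, neg])
  }
  if (length(pos) == 0 || length(ben) == 0) {
    warning("empty group for tumor-vs-benign contrast; p undefined")
  } else {
    p2 <- unpaired_overexpression_test(expr[gene3, pos], expr[gene3, ben])
  }
  list(p_pos_vs_neg_tumor = p1, p_pos_vs_benign = p2,
       n_pos = length(pos), n_neg = length(neg))
}

#' Correlation between fusion expression and 3'-partner expression
#'
#' Spearman rank correlation between per-sample fusion expression
#' (breakpoint split-read RPKM, 0 in fusion-negative samples) and the 3'
#' partner gene's expression, optionally after a `log2(x + 1)` transform
#' (zeros are common in fusion-negative samples). The p-value is two-sided
#' with tie correction.
#'
#' @param fusion_expr,partner_expr Numeric vectors in the same sample order.
#' @param log_transform Apply `log2(x + 1)` first (default TRUE; rank-based
#'   rho is invariant to it, the option matters for plotting conventions).
#' @return List: `rho`, `p`, `n`. Constant input gives `rho = NA` with a
#'   warning.
#' @export
fusion_partner_correlation <- function(fusion_expr, partner_expr, log_transform = TRUE) {
  if (length(fusion_expr) != length(partner_expr)) {
    stop("vectors must have the same sample order and length")
  }
  x <- if (log_transform) log2(fusion_expr + 1) else fusion_expr
  y <- if (log_transform) log2(partner_expr + 1) else partner_expr
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant expression vector; Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = NULL))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-exon contrast of the 3' partner around the fusion junction
#'
#' Labels each exon of the 3' partner as upstream or downstream of the
#' fusion junction (transcription-strand-aware) and contrasts
#' library-size-normalized exon counts between fusion-positive and
#' fusion-negative tumors with a one-sided rank-sum test (positive >
#' negative) per exon. The read-through signature -- the fusion adds
#' transcription only downstream of the junction -- is reported when some
#' downstream exon is significantly higher in positives while the
#' most-upstream exon is not.
#'
#' @param exon_counts Count matrix (exons x samples), rownames matching
#'   `exon_info$exon_id`.
#' @param exon_info Data frame: `exon_id`, `start`, `end`, `strand` for the
#'   3' partner's exons.
#' @param junction Genomic breakpoint coordinate in the 3' partner.
#' @param partition Sample partition from [partition_samples()].
#' @param manifest A [cohort_manifest()] supplying `total_mapped_reads` for
#'   library-size normalization.
#' @param alpha Significance level for the signature call.
#' @return Data frame (one row per exon): `exon_id`,
#'   `upstream_of_junction`, `mean_pos`, `mean_neg` (normalized counts per
#'   million), `p`; attribute `signature` (logical).
#' @export
exon_contrast <- function(exon_counts, exon_info, junction, partition, manifest,
                          alpha = 0.05) {
  exon_info <- as.data.frame(exon_info, stringsAsFactors = FALSE)
  if (nrow(exon_info) == 0) stop("no exon features supplied")
  missing_rows <- setdiff(exon_info$exon_id, rownames(exon_counts))
  if (length(missing_rows) > 0) {
    stop("exon(s) absent from count matrix: ", paste(missing_rows, collapse = ", "))
  }
  pos <- intersect(partition$positive_tumor, colnames(exon_counts))
  neg <- intersect(partition$negative_tumor, colnames(exon_counts))
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both fusion-positive and fusion-negative tumor groups must be nonempty")
  }
  lib <- manifest$total_mapped_reads[match(colnames(exon_counts), manifest$sample_id)]
  if (anyNA(lib)) stop("count matrix has samples absent from the manifest")
  cpm <- sweep(exon_counts, 2, lib / 1e6, "/")

  strand <- exon_info$strand[1]
  upstream <- if (strand == "+") {
    exon_info$end < junction
  } else {
    exon_info$start > junction
  }
  res <- data.frame(exon_id = exon_info$exon_id,
                    upstream_of_junction = upstream,
                    stringsAsFactors = FALSE)
  res$mean_pos <- rowMeans(cpm[exon_info$exon_id, pos, drop = FALSE])
  res$mean_neg <- rowMeans(cpm[exon_info$exon_id, neg, drop = FALSE])
  res$p <- vapply(exon_info$exon_id, function(ex) {
    unpaired_overexpression_test(cpm[ex, pos], cpm[ex, neg])
  }, numeric(1))
  # transcription order: most-upstream exon first
  ord <- if (strand == "+") order(exon_info$start) else order(-exon_info$end)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  down_sig <- any(res$p[!res$upstream_of_junction] < alpha)
  first_up <- which(res$upstream_of_junction)[1]
  signature <- if (is.na(first_up)) down_sig else down_sig && res$p[first_up] >= alpha
  attr(res, "signature") <- signature
  res
}
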