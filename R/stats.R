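#' One-sided Fisher exact enrichment test on a detection contingency table
#'
#' Tests whether a fusion transcript is detected in more tumor than benign
#' samples. The 2x2 table is (tumor-positive `a`, tumor-negative `b`,
#' benign-positive `c`, benign-negative `d`); under the null the positive
#' samples are distributed hypergeometrically over the two cohorts, and the
#' p-value for `alternative = "greater"` is the exact upper tail
#' P(X >= a | a + c positives, a + b tumors).
#'
#' The default alternative is "greater" (more positives in tumors). This is
#' the variant used by the nomination cascade: it reproduces published
#' tumor/benign fusion enrichment p-values that a two-sided test does not.
#'
#' @param a,b,c,d Nonnegative integer cell counts: tumor-positive,
#'   tumor-negative, benign-positive, benign-negative. Vectors are recycled.
#' @param alternative One of "greater", "less", "two.sided".
#' @return Numeric vector of p-values in (0, 1], at full precision (rounding
#'   to 2 significant figures happens only in the report layer).
#' @examples
#' fisher_enrichment(27, 17, 1, 43)   # ~4.2e-10
#' fisher_enrichment(0, 44, 0, 44)    # 1
#' @export
fisher_enrichment <- function(a, b, c, d, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  cells <- cbind(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("contingency cells must be finite and nonnegative")
  }
  if (any(cells != round(cells))) stop("contingency cells must be integers")
  m <- a + c          # total positives (white balls)
  nn <- b + d         # total negatives
  k <- a + b          # tumor cohort size (draws)
  p <- switch(alternative,
    greater = stats::phyper(a - 1, m, nn, k, lower.tail = FALSE),
    less    = stats::phyper(a, m, nn, k, lower.tail = TRUE),
    two.sided = vapply(seq_len(n), function(i) {
      .fisher_two_sided(a[i], m[i], nn[i], k[i])
    }, numeric(1))
  )
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# fisher.test-style two-sided p: sum of table probabilities <= P(observed)
.fisher_two_sided <- function(a, m, nn, k, relErr = 1 + 1e-7) {
  lo <- max(0L, k - nn)
  hi <- min(k, m)
  support <- lo:hi
  dd <- stats::dhyper(support, m, nn, k)
  sum(dd[dd <= dd[support == a] * relErr])
}

#' Paired one-sided Wilcoxon signed-rank overexpression test
#'
#' Tests whether tumor expression exceeds matched benign expression across
#' sample pairs (alternative: tumor > benign). Zero differences are dropped
#' before ranking (the classic signed-rank convention). With at most
#' `exact_limit` nonzero pairs the exact null distribution of the
#' positive-rank sum is used (computed by convolution over the 2^n sign
#' assignments, which handles tied absolute differences); beyond that, a
#' normal approximation with tie correction and continuity correction.
#'
#' @param tumor,benign Equal-length numeric vectors, one entry per
#'   tumor/benign pair (e.g. per-pair breakpoint RPKM, 0 when undetected).
#' @param exact_limit Largest number of nonzero pairs for which the exact
#'   null distribution is used (default 25).
#' @return One-sided p-value in (0, 1]. All-zero differences give p = 1 with
#'   a warning.
#' @examples
#' paired_overexpression_test(2:11, 1:10)  # all-positive signs: 1/2^10
#' @export
paired_overexpression_test <- function(tumor, benign, exact_limit = 25L) {
  if (length(tumor) != length(benign)) {
    stop("tumor and benign vectors must be paired (equal length)")
  }
  if (anyNA(tumor) || anyNA(benign)) stop("paired vectors must not contain NA")
  d <- tumor - benign
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    # exact tail P(W+ >= w) over the 2^n equiprobable sign assignments:
    # convolve the distribution of 2*W+ (doubled ranks are integers even
    # with average ranks from ties)
    w2 <- as.integer(round(2 * r))
    top <- sum(w2)
    f <- numeric(top + 1)
    f[1] <- 1
    for (wi in w2) {
      g <- f
      idx <- (wi + 1L):(top + 1L)
      g[idx] <- g[idx] + f[idx - wi]
      f <- g / 2
    }
    p <- sum(f[(as.integer(round(2 * w)) + 1L):(top + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    if (sigma2 <= 0) {
      warning("degenerate signed-rank variance; p = 1")
      return(1)
    }
    z <- (w - mu - 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Unpaired one-sided Wilcoxon rank-sum (Mann-Whitney) test
#'
#' One-sided rank-sum comparison of two independent groups (alternative:
#' `group_a` stochastically greater than `group_b`), with tie correction.
#' Used for the unpaired contrasts: fusion-positive vs fusion-negative
#' tumors, tumors vs benign in the unpaired validation cohort.
#'
#' @param group_a,group_b Nonempty numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()]; default "greater".
#' @return p-value in (0, 1].
#' @export
unpaired_overexpression_test <- function(group_a, group_b, alternative = "greater") {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be nonempty")
  }
  p <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = NULL, correct = TRUE)$p.value
  )
  min(max(p, .Machine$double.xmin), 1)
}

#' Breakpoint split-read RPKM
#'
#' Approximate expression of a fusion transcript in one sample as the number
#' of junction split reads per kilobase of breakpoint region per million
#' mapped reads. The breakpoint region is the window in which a read can
#' overlap the junction, i.e. twice the read length (see
#' [filter_thresholds()]).
#'
#' @param split_reads Nonnegative split-read counts.
#' @param region_length_bp Positive region length in bp.
#' @param total_mapped_reads Positive library size (mapped reads).
#' @return RPKM values, linear in `split_reads`.
#' @examples
#' breakpoint_rpkm(10, 1000, 1e7)  # 1
#' @export
breakpoint_rpkm <- function(split_reads, region_length_bp, total_mapped_reads) {
  if (any(!is.finite(region_length_bp)) || any(region_length_bp <= 0)) {
    stop("region_length_bp must be positive")
  }
  if (any(!is.finite(total_mapped_reads)) || any(total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive")
  }
  if (any(split_reads < 0)) stop("split_reads must be nonnegative")
  split_reads / (region_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' Normalize per-pair differential expression profiles
#'
#' For fusion `i` and tumor/benign pair `j`, the normalized differential
#' expression is
#' `value'_ij = (Texp_ij - Nexp_ij) / max_j |Texp_ij - Nexp_ij|`,
#' i.e. each fusion's profile of tumor-minus-benign differences scaled by its
#' own maximum absolute difference, so values lie in \[-1, 1\] and every row
#' with any nonzero difference attains |value| = 1 somewhere. All-zero rows
#' map to all zeros.
#'
#' @param tumor,benign Numeric matrices of identical shape
#'   (fusions x pairs): expression in the tumor and the matched benign
#'   sample of each pair.
#' @return Matrix of normalized differential values in \[-1, 1\].
#' @examples
#' normalize_differential(matrix(c(3, 1, 5), 1), matrix(c(1, 2, 1), 1))
#' @export
normalize_differential <- function(tumor, benign) {
  if (!is.matrix(tumor)) tumor <- as.matrix(tumor)
  if (!is.matrix(benign)) benign <- as.matrix(benign)
  if (!identical(dim(tumor), dim(benign))) {
    stop("tumor and benign matrices must have the same shape")
  }
  if (anyNA(tumor) || anyNA(benign) || any(!is.finite(tumor)) || any(!is.finite(benign))) {
    stop("input matrices must be finite with no missing values")
  }
  d <- tumor - benign
  m <- apply(abs(d), 1, max)
  scale_by <- ifelse(m > 0, m, 1)
  sweep(d, 1, scale_by, "/")
}

#' Hierarchical clustering of expression profiles with Pearson distance
#'
#' Agglomerative clustering of profile rows using `1 - Pearson r` as the
#' distance between profiles. Rows with zero variance (Pearson correlation
#' undefined) are excluded with a warning.
#'
#' @param x Numeric matrix, one profile per row (>= 2 usable rows).
#' @param linkage Agglomeration method for [stats::hclust()]; default
#'   "average".
#' @return List with elements `hclust` (the tree), `order` (leaf labels in
#'   dendrogram order), `dist` (the Pearson distance matrix) and `excluded`
#'   (labels of zero-variance rows).
#' @export
cluster_profiles <- function(x, linkage = "average") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("profile", seq_len(nrow(x)))
  v <- apply(x, 1, stats::var)
  excluded <- rownames(x)[v == 0]
  if (length(excluded) > 0) {
    warning("excluding ", length(excluded),
            " zero-variance profile(s): Pearson correlation undefined")
    x <- x[v > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stop("need at least two non-degenerate profiles to cluster")
  d <- stats::as.dist(1 - stats::cor(t(x)))
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = hc$labels[hc$order], dist = d, excluded = excluded)
}
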