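# Statistical core: Fisher enrichment, rank tests, RPKM, normalization,
# clustering -- each checked against an independent oracle where one exists.

# brute-force hypergeometric tail from binomial coefficients (independent of
# phyper): P(X >= a) for a 2x2 with margins (a+b tumors, c+d benign)
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; k <- a + b
  support <- max(0, k - nn):min(k, m)
  probs <- choose(m, support) * choose(nn, k - support) / choose(m + nn, k)
  sum(probs[support >= a])
}

test_that("fisher enrichment reproduces published contingency p-values", {
  # counts from a 44 tumor / 44 benign cohort
  expect_equal(format_pvalue(fisher_enrichment(27, 17, 1, 43)), "4.2E-10")
  expect_equal(format_pvalue(fisher_enrichment(6, 38, 0, 44)), "1.3E-02")
  expect_equal(format_pvalue(fisher_enrichment(14, 30, 2, 42)), "8.2E-04")
  expect_equal(format_pvalue(fisher_enrichment(25, 19, 6, 38)), "2.0E-05")
  expect_equal(fisher_enrichment(0, 44, 0, 44), 1)
  expect_error(fisher_enrichment(-1, 2, 3, 4), "nonnegative")
})

test_that("fisher enrichment agrees with enumeration and fisher.test", {
  set.seed(1)
  for (n1 in c(5L, 11L, 20L)) {
    for (n2 in c(5L, 13L, 20L)) {
      for (a in 0:n1) {
        cc <- sample(0:n2, 1)
        p <- fisher_enrichment(a, n1 - a, cc, n2 - cc)
        expect_equal(p, fisher_oracle(a, n1 - a, cc, n2 - cc), tolerance = 1e-12)
      }
    }
  }
  # cross-check both tails against the reference implementation
  for (i in 1:20) {
    a <- sample(0:20, 1); b <- sample(0:20, 1)
    cc <- sample(0:20, 1); d <- sample(0:20, 1)
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    expect_equal(fisher_enrichment(a, b, cc, d),
                 fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    expect_equal(fisher_enrichment(a, b, cc, d, alternative = "two.sided"),
                 fisher.test(tab)$p.value, tolerance = 1e-12)
  }
})

test_that("fisher enrichment satisfies monotonicity and tail identities", {
  n <- 44L
  cc <- 3L
  p <- fisher_enrichment(0:n, n:0, cc, n - cc)
  # more tumor positives (c, d fixed) never increases the enrichment p
  expect_true(all(diff(p) <= 1e-15))
  # p(greater) + p(less) - P(observed) = 1
  for (a in c(0L, 5L, 17L, 44L)) {
    pg <- fisher_enrichment(a, n - a, cc, n - cc)
    pl <- fisher_enrichment(a, n - a, cc, n - cc, alternative = "less")
    pobs <- dhyper(a, a + cc, (n - a) + (n - cc), n)
    expect_equal(pg + pl - pobs, 1, tolerance = 1e-12)
  }
  expect_true(all(p > 0 & p <= 1))
})

# exhaustive 2^n sign enumeration for the signed-rank tail
signrank_oracle <- function(tumor, benign) {
  d <- tumor - benign
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs)
}

test_that("paired signed-rank test matches closed forms and enumeration", {
  expect_warning(p <- paired_overexpression_test(1:10, 1:10), "zero")
  expect_equal(p, 1)
  # all-positive signs, n = 10: exact p = 1/2^10
  expect_equal(paired_overexpression_test(2:11, 1:10), 1 / 1024)
  set.seed(42)
  for (i in 1:5) {
    tum <- rnorm(8); ben <- rnorm(8)
    expect_equal(paired_overexpression_test(tum, ben),
                 signrank_oracle(tum, ben), tolerance = 1e-12)
  }
  # agrees with the reference implementation when its exact path applies
  set.seed(7)
  tum <- rnorm(12, 0.5); ben <- rnorm(12)
  expect_equal(paired_overexpression_test(tum, ben),
               wilcox.test(tum, ben, paired = TRUE,
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  # the exact convolution handles tied absolute differences
  tum2 <- c(2, 2, 2, 3, 3, 5, 6, 1)
  ben2 <- c(1, 1, 1, 2, 2, 4, 5, 3)
  expect_equal(paired_overexpression_test(tum2, ben2),
               signrank_oracle(tum2, ben2), tolerance = 1e-12)
  # beyond the exact limit the tie-corrected normal path applies
  set.seed(11)
  tum3 <- rnorm(30, 0.3); ben3 <- rnorm(30)
  p3 <- paired_overexpression_test(tum3, ben3)
  expect_equal(p3, wilcox.test(tum3, ben3, paired = TRUE, exact = FALSE,
                               alternative = "greater")$p.value,
               tolerance = 1e-12)
})

test_that("unpaired rank-sum matches closed forms", {
  # complete separation, 5 vs 5: p = 1/C(10,5)
  expect_equal(unpaired_overexpression_test(6:10, 1:5), 1 / choose(10, 5))
  # fully tied groups: one-sided p near 1/2 (continuity correction shifts it up)
  expect_lt(abs(unpaired_overexpression_test(c(2, 3, 4), c(2, 3, 4)) - 0.5), 0.1)
  # single extreme positive vs 43: p = 1/44
  expect_equal(unpaired_overexpression_test(100, rnorm(43)), 1 / 44)
  expect_error(unpaired_overexpression_test(numeric(0), 1:3), "nonempty")
})

test_that("rank-sum p is uniform under the null", {
  set.seed(314)
  p <- replicate(1000, unpaired_overexpression_test(rnorm(30), rnorm(30)))
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("breakpoint RPKM is the normalized split-read count", {
  expect_equal(breakpoint_rpkm(0, 200, 5e7), 0)
  expect_equal(breakpoint_rpkm(10, 1000, 1e7), 1)
  # linear in split reads
  x <- breakpoint_rpkm(1:50, 200, 4.7e7)
  expect_equal(x * 2, breakpoint_rpkm(2 * (1:50), 200, 4.7e7))
  expect_error(breakpoint_rpkm(1, 0, 1e7), "positive")
  expect_error(breakpoint_rpkm(1, 200, 0), "positive")
})

test_that("differential normalization scales rows to max |value| of 1", {
  tum <- matrix(c(3, 1, 5), 1)
  ben <- matrix(c(1, 2, 1), 1)
  expect_equal(unname(normalize_differential(tum, ben)),
               matrix(c(0.5, -0.25, 1), 1))
  # T = N -> all zeros
  expect_equal(unname(normalize_differential(tum, tum)), matrix(0, 1, 3))
  # property: per-row max abs is exactly 0 or 1
  set.seed(5)
  for (i in 1:20) {
    tm <- matrix(rnorm(60), 6)
    nm <- matrix(rnorm(60), 6)
    nm[3, ] <- tm[3, ]  # one all-zero difference row
    v <- normalize_differential(tm, nm)
    expect_true(all(abs(v) <= 1))
    expect_true(all(apply(abs(v), 1, max) %in% c(0, 1)))
    expect_equal(sign(v), sign(tm - nm))
  }
  expect_error(normalize_differential(matrix(NaN, 1, 1), matrix(1, 1, 1)), "finite")
})

test_that("profile clustering uses Pearson distance deterministically", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  cl <- cluster_profiles(x)
  # identical (perfectly correlated) profiles merge at distance 0
  expect_equal(min(cl$hclust$height), 0, tolerance = 1e-12)
  # a profile and its negation sit at Pearson distance 2
  expect_equal(max(as.matrix(cl$dist)["a", "c"]), 2, tolerance = 1e-12)
  # 3-row case against the hand-computed correlation distance matrix
  y <- rbind(p = c(1, 5, 2), q = c(2, 1, 4), r = c(3, 3, 1))
  expected <- 1 - cor(t(y))
  expect_equal(as.matrix(cluster_profiles(y)$dist), expected,
               ignore_attr = TRUE, tolerance = 1e-12)
  # zero-variance profiles are excluded with a warning
  z <- rbind(x, flat = c(1, 1, 1, 1))
  expect_warning(cl2 <- cluster_profiles(z), "zero-variance")
  expect_equal(cl2$excluded, "flat")
  expect_error(suppressWarnings(cluster_profiles(rbind(a = c(1, 1), b = c(1, 2)))),
               "at least two")
})
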