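# 3'-partner association: sample partitioning, expression contrasts,
# fusion/partner correlation, exon-level read-through signature.

make_pdm <- function(manifest, positive_samples, pair = "G5|G3") {
  calls <- fusion_calls(do.call(rbind, lapply(positive_samples, function(s) {
    call_row(sample_id = s)
  })))
  aggregate_gene_pairs(calls, manifest)
}

test_that("sample partition is disjoint and exhaustive", {
  m <- quick_manifest(22)  # 22 tumors, 22 benign
  pdm <- make_pdm(m, c(sprintf("T%02d", 1:14), "B01"))
  part <- partition_samples("G5|G3", pdm)
  expect_equal(length(part$positive_tumor), 14L)
  expect_equal(length(part$negative_tumor), 8L)
  expect_equal(length(part$benign), 22L)
  all_ids <- c(part$positive_tumor, part$negative_tumor, part$benign)
  expect_setequal(all_ids, m$sample_id)
  expect_equal(length(all_ids), nrow(m))
  # absent candidate: empty positive group
  part0 <- partition_samples("NO|PE", pdm)
  expect_equal(length(part0$positive_tumor), 0L)
  expect_equal(length(part0$negative_tumor), 22L)
})

test_that("3'-partner contrast has the exact single-extreme closed form", {
  m <- quick_manifest(22)
  pdm <- make_pdm(m, "T01")
  part <- partition_samples("G5|G3", pdm)
  set.seed(9)
  expr <- matrix(runif(44, 1, 2), 1, 44,
                 dimnames = list("G3", m$sample_id))
  expr["G3", "T01"] <- 100  # single positive tumor with the top value
  res <- three_prime_partner_test(expression_matrix(expr, m), "G3", part)
  # one-sided exact rank-sum, 1 vs 21: p = 1/22
  expect_equal(res$p_pos_vs_neg_tumor, 1 / 22)
  expect_equal(res$n_pos, 1L)
  expect_equal(res$n_neg, 21L)
  # empty positive group: NA p-values, one warning per undefined contrast
  part_empty <- partition_samples("NO|PE", pdm)
  w <- capture_warnings(
    res0 <- three_prime_partner_test(expression_matrix(expr, m), "G3", part_empty))
  expect_length(w, 2L)
  expect_match(w, "empty|undefined", all = TRUE)
  expect_true(is.na(res0$p_pos_vs_neg_tumor))
  expect_true(is.na(res0$p_pos_vs_benign))
})

test_that("planted coupling is detected with high power, null is uniform", {
  set.seed(123)
  n_pos <- 15L; n_neg <- 29L
  p_coupled <- replicate(200, {
    base <- rlnorm(n_pos + n_neg, log(10), 0.5)
    expr <- base * c(rep(2^2, n_pos), rep(1, n_neg))  # +2 log2 units
    unpaired_overexpression_test(expr[1:n_pos], expr[(n_pos + 1):(n_pos + n_neg)])
  })
  expect_gte(mean(p_coupled < 0.05), 0.95)
  p_null <- replicate(500, {
    base <- rlnorm(n_pos + n_neg, log(10), 0.5)
    unpaired_overexpression_test(base[1:n_pos], base[(n_pos + 1):(n_pos + n_neg)])
  })
  expect_gt(suppressWarnings(ks.test(p_null, "punif"))$p.value, 0.01)
})

spearman_oracle <- function(x, y) {
  # exhaustive permutation p for the two-sided Spearman test, n small
  rho_obs <- cor(x, y, method = "spearman")
  n <- length(x)
  perms <- as.matrix(expand.grid(rep(list(1:n), n)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == n), ,
                 drop = FALSE]
  rho_all <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

test_that("fusion/partner correlation matches Spearman conventions", {
  x <- c(0, 1, 3, 7, 9, 20)
  res <- fusion_partner_correlation(x, exp(x))
  expect_equal(res$rho, 1)
  rev <- fusion_partner_correlation(x, -x, log_transform = FALSE)
  expect_equal(rev$rho, -1)
  # two-sided p against the exhaustive n = 6 permutation oracle
  set.seed(77)
  for (i in 1:3) {
    a <- rnorm(6); b <- rnorm(6)
    res <- fusion_partner_correlation(a, b, log_transform = FALSE)
    expect_equal(res$p, spearman_oracle(a, b), tolerance = 1e-8)
  }
  expect_warning(cc <- fusion_partner_correlation(rep(1, 10), rnorm(10)),
                 "constant")
  expect_true(is.na(cc$rho))
  expect_error(fusion_partner_correlation(1:3, 1:4), "length")
})

test_that("estimated correlation is monotone in the planted coupling", {
  set.seed(2025)
  n <- 44L
  detected <- rbinom(n, 1, 0.5) == 1
  fusion_rpkm <- ifelse(detected, rlnorm(n, log(0.5), 0.4), 0)
  rho_by_coupling <- vapply(c(0, 0.5, 1, 2), function(coupling) {
    partner <- rlnorm(n, log(10), 0.4) * 2^(coupling * detected)
    fusion_partner_correlation(fusion_rpkm, partner)$rho
  }, numeric(1))
  expect_equal(cor(rho_by_coupling, c(0, 0.5, 1, 2), method = "spearman"), 1)
})

test_that("label permutation yields uniform association p-values", {
  set.seed(99)
  m <- quick_manifest(22)
  expr <- matrix(rlnorm(44, log(10), 0.5), 1, 44,
                 dimnames = list("G3", m$sample_id))
  expr <- expression_matrix(expr, m)
  tumors <- m$sample_id[m$condition == "tumor"]
  p <- replicate(1000, {
    pos <- sample(tumors, 10)
    part <- list(positive_tumor = pos, negative_tumor = setdiff(tumors, pos),
                 benign = m$sample_id[m$condition == "benign"])
    three_prime_partner_test(expr, "G3", part)$p_pos_vs_neg_tumor
  })
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("exon contrast detects the planted read-through signature", {
  co <- small_cohort(seed = 31, n_pairs = 22L, n_background_pairs = 0L)
  pdm <- aggregate_gene_pairs(co$calls, co$manifest)
  rt1 <- co$truth[co$truth$name == "RT1", ]  # coupling = 2 log2 units
  part <- partition_samples(rt1$pair, pdm)
  info <- co$exon_info[co$exon_info$gene_id == rt1$gene3, ]
  res <- exon_contrast(co$exon_counts, info, rt1$breakpoint3, part, co$manifest)
  expect_true(attr(res, "signature"))
  expect_equal(res$upstream_of_junction, c(TRUE, FALSE, FALSE))
  expect_true(all(res$p[!res$upstream_of_junction] < 0.05))
  expect_gte(res$p[1], 0.05)

  # uncoupled planted fusion: no signature in uniform counts
  rt2 <- co$truth[co$truth$name == "RT2", ]
  part2 <- partition_samples(rt2$pair, pdm)
  info2 <- co$exon_info[co$exon_info$gene_id == rt2$gene3, ]
  res2 <- exon_contrast(co$exon_counts, info2, rt2$breakpoint3, part2, co$manifest)
  expect_false(attr(res2, "signature"))

  # junction upstream of all exons: everything labeled downstream
  res3 <- exon_contrast(co$exon_counts, info, min(info$start) - 10L, part,
                        co$manifest)
  expect_true(all(!res3$upstream_of_junction))
  expect_error(exon_contrast(co$exon_counts, info[0, ], 1L, part, co$manifest),
               "no exon")
})
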