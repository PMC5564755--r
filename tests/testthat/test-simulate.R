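# Synthetic cohort generator: determinism, clean parsing, planted structure.

test_that("identical seeds give byte-identical bundles, different seeds differ", {
  cfg <- function(seed) synthetic_config(
    n_pairs = 8L, n_extra_tumors = 4L, n_background_pairs = 12L, seed = seed)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  d3 <- file.path(tempdir(), "sim_c")
  unlink(c(d1, d2, d3), recursive = TRUE)
  generate_cohort(cfg(5), dir = d1)
  generate_cohort(cfg(5), dir = d2)
  generate_cohort(cfg(6), dir = d3)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  hash <- function(d) vapply(files, function(f) {
    unname(tools::md5sum(file.path(d, f)))
  }, character(1))
  expect_identical(hash(d1), hash(d2))
  expect_false(identical(hash(d1), hash(d3)))
})

test_that("generated files parse cleanly back through the readers", {
  d <- file.path(tempdir(), "sim_parse")
  unlink(d, recursive = TRUE)
  co <- generate_cohort(synthetic_config(
    n_pairs = 6L, n_extra_tumors = 2L, n_background_pairs = 10L, seed = 13),
    dir = d)
  b <- read_cohort_bundle(d)
  # parser accepted every generated row
  expect_equal(nrow(attr(b$calls, "rejected")), 0L)
  expect_equal(nrow(b$calls), nrow(co$calls))
  expect_equal(as.data.frame(b$manifest), as.data.frame(co$manifest))
  # annotation round-trips to identical gene models
  ord_g <- function(g) { g <- g[order(g$gene_id), ]; rownames(g) <- NULL; g }
  ord_e <- function(e) {
    e <- e[order(e$transcript_id, e$exon_number), ]; rownames(e) <- NULL; e
  }
  ord_c <- function(cc) {
    cc <- cc[order(cc$transcript_id, cc$start), ]; rownames(cc) <- NULL; cc
  }
  expect_equal(ord_g(b$annotation$genes), ord_g(co$annotation$genes))
  expect_equal(ord_e(b$annotation$exons), ord_e(co$annotation$exons))
  expect_equal(ord_c(b$annotation$cds), ord_c(co$annotation$cds))
  expect_equal(b$gene_expr, co$gene_expr, ignore_attr = TRUE)
})

test_that("planted frame compatibility round-trips through frame prediction", {
  co <- small_cohort(seed = 17, n_pairs = 6L, n_background_pairs = 0L)
  for (i in seq_len(nrow(co$truth))) {
    tr <- co$truth[i, ]
    if (tr$category == "background" || !tr$splice_concordant) next
    ja <- predict_frame(list(gene5 = tr$gene5, gene3 = tr$gene3,
                             breakpoint5 = tr$breakpoint5,
                             breakpoint3 = tr$breakpoint3),
                        co$annotation, genome = co$genome)
    expect_true(ja$at_splice_sites, label = tr$name)
    expect_equal(ja$in_frame, tr$frame_compatible, label = tr$name)
    if (ja$in_frame) {
      # translated peptide (stop-free planted CDS) matches the arithmetic length
      arith <- predict_frame(list(gene5 = tr$gene5, gene3 = tr$gene3,
                                  breakpoint5 = tr$breakpoint5,
                                  breakpoint3 = tr$breakpoint3),
                             co$annotation)
      expect_equal(ja$peptide_length, arith$peptide_length, label = tr$name)
    }
  }
})

test_that("planted geometries are realized in the annotation", {
  co <- generate_cohort(synthetic_config(
    n_pairs = 4L, n_extra_tumors = 0L, n_background_pairs = 0L,
    planted = list(
      planted_fusion("RT", 0.6, 0.02, "read_through"),
      planted_fusion("FAR", 0.6, 0.02, "distal"),
      planted_fusion("IC", 0.6, 0.02, "interchromosomal")),
    seed = 3))
  g_rt <- classify_pair("RTA", "RTB", co$annotation)
  expect_true(g_rt$read_through_candidate)
  g_far <- classify_pair("FARA", "FARB", co$annotation)
  expect_true(g_far$same_chromosome)
  expect_false(g_far$read_through_candidate)
  expect_gt(g_far$inner_distance_bp, 60000L)
  g_ic <- classify_pair("ICA", "ICB", co$annotation)
  expect_false(g_ic$same_chromosome)
  # infeasible planted rates are rejected at construction
  expect_error(planted_fusion("bad", 1.5, 0), "rates")
  expect_error(planted_fusion("bad", 0.5, 0, multimap_fraction = 2), "multimap")
  expect_error(synthetic_config(), "seed")
})

test_that("truth evaluation scores recovery by category", {
  records <- data.frame(pair = c("A|B", "C|D"), stringsAsFactors = FALSE)
  truth <- data.frame(pair = c("A|B", "C|D", "E|F"),
                      category = c("enriched", "background", "enriched"),
                      stringsAsFactors = FALSE)
  ev <- truth_evaluation(records, truth)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 0.5)
  expect_equal(unname(ev$by_category["background"]), 1L)
  # empty nominations against empty truth: precision = recall = 1
  ev0 <- truth_evaluation(records[0, , drop = FALSE],
                          truth[truth$category == "background", ])
  expect_equal(ev0$precision, 1)
  expect_equal(ev0$recall, 1)
})

test_that("a high-multimap planted pair is removed at the multimap stage", {
  co <- small_cohort(seed = 23, n_pairs = 16L, n_background_pairs = 0L)
  res <- run_cascade(co$calls, co$manifest, co$annotation)
  artifact <- co$truth$pair[co$truth$category == "artifact"]
  expect_equal(res$removed$stage[res$removed$pair == artifact], "multimap")
  expect_false(artifact %in% res$records$pair)
})
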