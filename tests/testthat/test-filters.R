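# Call-level screen, pair aggregation and the individual cascade filters.

test_that("call screen boundaries are inclusive", {
  calls <- make_calls(
    call_row(discordant_pairs = 5, split_reads = 1, probability = 0.05),
    call_row(discordant_pairs = 4, split_reads = 10, probability = 0.99),
    call_row(discordant_pairs = 7, split_reads = 7, probability = 0.9),
    call_row(discordant_pairs = 10, split_reads = 0, probability = 0.9,
             total_spanning = 10),
    call_row(discordant_pairs = 10, split_reads = 5, probability = 0.049))
  expect_equal(call_passes_initial(calls), c(TRUE, FALSE, TRUE, FALSE, FALSE))
})

test_that("aggregation is idempotent and manifest-aware", {
  m <- quick_manifest(3)
  calls <- make_calls(
    call_row(sample_id = "T01", split_reads = 4),
    call_row(sample_id = "T01", split_reads = 9, multimap_spanning = 2),
    call_row(sample_id = "B02", gene5 = "X", gene3 = "Y"))
  pdm <- aggregate_gene_pairs(calls, m)
  # two calls for the same (pair, sample) collapse to one positive cell
  expect_equal(nrow(pdm$support[pdm$support$pair == "G5|G3", ]), 1L)
  # with the max-split-read call's support values
  expect_equal(pdm$support$split_reads[pdm$support$pair == "G5|G3"], 9)
  expect_equal(pdm$support$multimap_spanning[pdm$support$pair == "G5|G3"], 2)
  # pair seen only in benign: tumor count 0
  counts <- positive_counts(pdm)
  expect_equal(counts$n_tumor_pos[counts$pair == "X|Y"], 0L)
  expect_equal(counts$n_benign_pos[counts$pair == "X|Y"], 1L)
  # unknown sample id is an error
  expect_error(aggregate_gene_pairs(make_calls(call_row(sample_id = "ZZ")), m),
               "absent from manifest")
  # reciprocal orientation is a distinct pair
  calls2 <- make_calls(call_row(), call_row(gene5 = "G3", gene3 = "G5"))
  expect_equal(nrow(aggregate_gene_pairs(calls2, m)$pairs), 2L)
})

test_that("recurrence keeps >= 5 tumor positives (inclusive)", {
  m <- quick_manifest(10)
  mk <- function(gene5, tumors, benigns) {
    do.call(rbind, c(
      lapply(tumors, function(s) call_row(sample_id = s, gene5 = gene5)),
      lapply(benigns, function(s) call_row(sample_id = s, gene5 = gene5))))
  }
  calls <- fusion_calls(rbind(
    mk("A", sprintf("T%02d", 1:5), character(0)),
    mk("B", sprintf("T%02d", 1:4), sprintf("B%02d", 1:10))))
  pdm <- aggregate_gene_pairs(calls, m)
  surv <- recurrence_filter(pdm)
  expect_equal(surv, "A|G3")  # 5 tumors kept, 4 tumors + 10 benign removed
})

test_that("multimap ratio pools support and removes strictly above 0.6", {
  m <- quick_manifest(3)
  mk <- function(gene5, mm, tot) {
    call_row(sample_id = "T01", gene5 = gene5, multimap_spanning = mm,
             total_spanning = tot, discordant_pairs = tot)
  }
  calls <- make_calls(mk("CLEAN", 0, 50), mk("DIRTY", 40, 50), mk("EDGE", 30, 50))
  pdm <- aggregate_gene_pairs(calls, m)
  r <- multimap_ratio(pdm)
  expect_equal(unname(r[c("CLEAN|G3", "DIRTY|G3", "EDGE|G3")]), c(0, 0.8, 0.6))
  th <- filter_thresholds()
  kept <- names(r)[r <= th$max_multimap_ratio]
  expect_setequal(kept, c("CLEAN|G3", "EDGE|G3"))  # boundary 0.6 is kept

  # zero total spanning reads: ratio 0 with a warning
  calls0 <- make_calls(call_row(total_spanning = 0, multimap_spanning = 0,
                                discordant_pairs = 5))
  pdm0 <- aggregate_gene_pairs(calls0, m)
  expect_warning(r0 <- multimap_ratio(pdm0), "zero total")
  expect_equal(unname(r0), 0)
})

test_that("biotype/overlap filter enforces allowed classes and disjoint spans", {
  genes <- data.frame(
    gene_id = c("pc1", "pc2", "linc", "pseudo", "nest_out", "nest_in", "mi"),
    gene_name = c("pc1", "pc2", "linc", "pseudo", "nest_out", "nest_in", "mi"),
    chrom = c("1", "1", "1", "1", "2", "2", "1"),
    start = c(100L, 5000L, 9000L, 12000L, 100L, 500L, 20000L),
    end = c(1000L, 6000L, 9500L, 13000L, 2000L, 800L, 20100L),
    strand = "+",
    biotype = c("protein_coding", "protein_coding", "lincRNA",
                "processed_pseudogene", "protein_coding", "protein_coding",
                "miRNA"),
    stringsAsFactors = FALSE)
  exons <- data.frame(gene_id = genes$gene_id,
                      transcript_id = paste0(genes$gene_id, ".t"),
                      exon_number = 1L, chrom = genes$chrom,
                      start = genes$start, end = genes$end, strand = "+",
                      stringsAsFactors = FALSE)
  db <- annotation_db(genes, exons)
  pairs <- data.frame(
    pair = c("a", "b", "c", "d", "e"),
    gene5 = c("pc1", "pc1", "nest_out", "pc1", "pc2"),
    gene3 = c("linc", "pseudo", "nest_in", "missing", "mi"),
    stringsAsFactors = FALSE)
  res <- biotype_overlap_filter(pairs, db)
  expect_equal(res$keep, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_match(res$reason[2], "biotype")
  expect_equal(res$reason[3], "overlapping_genes")
  expect_equal(res$reason[4], "unannotated")
})

test_that("planted detection rates land in the binomial interval", {
  co <- generate_cohort(synthetic_config(
    n_pairs = 44L, n_extra_tumors = 0L, n_background_pairs = 0L,
    planted = list(planted_fusion("RT1", 0.6, 0.02)), seed = 2024))
  pdm <- aggregate_gene_pairs(co$calls, co$manifest)
  counts <- positive_counts(pdm)
  n_pos <- counts$n_tumor_pos[counts$pair == "RT1A|RT1B"]
  bounds <- qbinom(c(0.005, 0.995), 44, 0.6)
  expect_gte(n_pos, bounds[1])
  expect_lte(n_pos, bounds[2])
})
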