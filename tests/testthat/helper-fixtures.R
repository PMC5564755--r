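# Shared fixtures, all built in code.

# Two adjacent "+"-strand genes on one contig with a splice-concordant
# junction at the 5' gene's exon-2 donor (1800) and the 3' gene's exon-2
# acceptor. The 5' side carries 400 coding bases (phase 1) over the
# junction; `l1` is the 3' gene's coding length upstream of the acceptor,
# so the junction is in frame iff l1 %% 3 == 1.
two_gene_db <- function(l1 = 100L, gap = 5000L, strand3 = "+",
                        biotype5 = "protein_coding", biotype3 = "protein_coding",
                        cds5 = TRUE, cds3 = TRUE) {
  s <- 2400L + gap + 1L
  genes <- data.frame(
    gene_id = c("G5", "G3"), gene_name = c("G5", "G3"), chrom = "ctgA",
    start = c(1001L, s), end = c(2400L, s + 1399L),
    strand = c("+", strand3), biotype = c(biotype5, biotype3),
    stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = "G5", transcript_id = "G5.t1", exon_number = 1:3,
               chrom = "ctgA", start = c(1001L, 1501L, 2101L),
               end = c(1200L, 1800L, 2400L), strand = "+",
               stringsAsFactors = FALSE),
    data.frame(gene_id = "G3", transcript_id = "G3.t1", exon_number = 1:3,
               chrom = "ctgA", start = s + c(0L, 500L, 1100L),
               end = s + c(199L, 799L, 1399L), strand = strand3,
               stringsAsFactors = FALSE))
  cds <- NULL
  if (cds5) {
    cds <- data.frame(gene_id = "G5", transcript_id = "G5.t1", chrom = "ctgA",
                      start = c(1101L, 1501L, 2101L), end = c(1200L, 1800L, 2201L),
                      strand = "+", phase = c(0L, 2L, 2L), stringsAsFactors = FALSE)
  }
  if (cds3) {
    l3 <- (3L - (l1 + 300L) %% 3L) %% 3L + 177L  # keep total CDS a codon multiple
    cds <- rbind(cds, data.frame(
      gene_id = "G3", transcript_id = "G3.t1", chrom = "ctgA",
      start = c(s + 200L - l1, s + 500L, s + 1100L),
      end = c(s + 199L, s + 799L, s + 1099L + l3),
      strand = strand3, phase = NA_integer_, stringsAsFactors = FALSE))
  }
  db <- annotation_db(genes, exons, cds)
  attr(db, "junction") <- list(gene5 = "G5", gene3 = "G3",
                               breakpoint5 = 1800L, breakpoint3 = s + 500L)
  db
}

# 5' gene contributing exactly 720 coding bases (240 residues) through the
# donor of its exon 5, fused in frame to a 3' gene (l1 = 99, phase 0).
long5_db <- function() {
  ex_start <- 1000L * (1:6) + 1L
  ex_end <- ex_start + 199L
  genes <- data.frame(
    gene_id = c("L5", "L3"), gene_name = c("L5", "L3"), chrom = "ctgB",
    start = c(ex_start[1], 20001L), end = c(ex_end[6], 21400L),
    strand = "+", biotype = "protein_coding", stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = "L5", transcript_id = "L5.t1", exon_number = 1:6,
               chrom = "ctgB", start = ex_start, end = ex_end, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(gene_id = "L3", transcript_id = "L3.t1", exon_number = 1:3,
               chrom = "ctgB", start = 20001L + c(0L, 500L, 1100L),
               end = 20001L + c(199L, 799L, 1399L), strand = "+",
               stringsAsFactors = FALSE))
  # CDS: 120 bases in exon 2, full exons 3-5 (600), 99 in exon 6 -> 819 total;
  # 720 coding bases lie upstream of the exon-5 donor
  cds <- rbind(
    data.frame(gene_id = "L5", transcript_id = "L5.t1", chrom = "ctgB",
               start = c(ex_start[2] + 80L, ex_start[3:5], ex_start[6]),
               end = c(ex_end[2], ex_end[3:5], ex_start[6] + 98L),
               strand = "+", phase = NA_integer_, stringsAsFactors = FALSE),
    data.frame(gene_id = "L3", transcript_id = "L3.t1", chrom = "ctgB",
               start = c(20001L + 101L, 20501L, 21101L),
               end = c(20200L, 20800L, 21101L + 179L),
               strand = "+", phase = NA_integer_, stringsAsFactors = FALSE))
  db <- annotation_db(genes, exons, cds)
  attr(db, "junction") <- list(gene5 = "L5", gene3 = "L3",
                               breakpoint5 = ex_end[5], breakpoint3 = 20501L)
  db
}

quick_manifest <- function(n_pairs = 6L, n_extra = 0L, lib = 5e7) {
  cohort_manifest(data.frame(
    sample_id = c(sprintf("T%02d", seq_len(n_pairs)),
                  sprintf("B%02d", seq_len(n_pairs)),
                  if (n_extra > 0) sprintf("X%02d", seq_len(n_extra))),
    condition = c(rep("tumor", n_pairs), rep("benign", n_pairs),
                  rep("tumor", n_extra)),
    pair_id = c(sprintf("P%02d", seq_len(n_pairs)),
                sprintf("P%02d", seq_len(n_pairs)),
                rep(NA_character_, n_extra)),
    total_mapped_reads = lib, stringsAsFactors = FALSE))
}

# one canonical call row with overridable fields
call_row <- function(...) {
  base <- list(sample_id = "T01", gene5 = "G5", gene3 = "G3",
               chrom5 = "1", chrom3 = "1",
               breakpoint5 = 1800, breakpoint3 = 7901,
               strand5 = "+", strand3 = "+",
               discordant_pairs = 10, split_reads = 5,
               multimap_spanning = 0, total_spanning = 10,
               probability = 0.9)
  args <- list(...)
  base[names(args)] <- args
  as.data.frame(base, stringsAsFactors = FALSE)
}

make_calls <- function(...) fusion_calls(do.call(rbind, list(...)))

# small fast synthetic cohort for pipeline-level tests
small_cohort <- function(seed = 11, n_background_pairs = 40L, n_pairs = 20L,
                         n_extra_tumors = 0L, planted = default_planted_fusions()) {
  generate_cohort(synthetic_config(
    n_pairs = n_pairs, n_extra_tumors = n_extra_tumors,
    n_background_pairs = n_background_pairs, planted = planted, seed = seed))
}
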