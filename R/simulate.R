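#' Describe a planted fusion for the synthetic cohort
#'
#' A planted fusion is defined by its detection rates in tumor and benign
#' samples, its genomic geometry, the fraction of multimapping spanning
#' reads (high values emulate homology-driven artifacts), the expression
#' coupling between fusion presence and the 3' partner (a log2 shift
#' applied in fusion-positive samples, the read-through signature), and
#' whether its junction lies on annotated splice sites with compatible
#' reading frames.
#'
#' @param name Short identifier used to derive gene names.
#' @param tumor_rate,benign_rate Per-sample detection probabilities.
#' @param geometry `"read_through"` (same strand, gap < 60 kb, 5' gene
#'   upstream), `"distal"` (same contig, gap above the read-through cap) or
#'   `"interchromosomal"`.
#' @param multimap_fraction Expected multimapping fraction of spanning
#'   reads, in \[0, 1\].
#' @param coupling Log2 expression shift of the 3' partner in
#'   fusion-positive samples (>= 0).
#' @param splice_concordant Breakpoints on annotated exon boundaries?
#' @param frame_compatible Reading frames compatible across the junction?
#' @param biotype5,biotype3 Partner gene biotypes.
#' @return An object of class `planted_fusion`.
#' @export
planted_fusion <- function(name, tumor_rate, benign_rate,
                           geometry = c("read_through", "distal", "interchromosomal"),
                           multimap_fraction = 0.05, coupling = 0,
                           splice_concordant = TRUE, frame_compatible = TRUE,
                           biotype5 = "protein_coding", biotype3 = "protein_coding") {
  geometry <- match.arg(geometry)
  if (tumor_rate < 0 || tumor_rate > 1 || benign_rate < 0 || benign_rate > 1) {
    stop("detection rates must lie in [0, 1]")
  }
  if (multimap_fraction < 0 || multimap_fraction > 1) {
    stop("multimap_fraction must lie in [0, 1]")
  }
  if (coupling < 0) stop("coupling must be nonnegative")
  structure(list(name = name, tumor_rate = tumor_rate, benign_rate = benign_rate,
                 geometry = geometry, multimap_fraction = multimap_fraction,
                 coupling = coupling, splice_concordant = splice_concordant,
                 frame_compatible = frame_compatible,
                 biotype5 = biotype5, biotype3 = biotype3),
            class = "planted_fusion")
}

#' Default planted fusions: the validation scenario
#'
#' Three tumor-enriched read-through fusions (per-sample detection 0.6 in
#' tumors, 0.02 in benign) -- one with 3'-partner expression coupling of 2
#' log2 units, one frame-compatible without coupling, one
#' frame-incompatible -- plus one homology artifact (same enrichment,
#' multimapping fraction 0.9) that the multimap filter must remove.
#'
#' @return List of [planted_fusion()] objects.
#' @export
default_planted_fusions <- function() {
  list(
    planted_fusion("RT1", 0.6, 0.02, "read_through", coupling = 2),
    planted_fusion("RT2", 0.6, 0.02, "read_through"),
    planted_fusion("RT3", 0.6, 0.02, "read_through", frame_compatible = FALSE),
    planted_fusion("ART1", 0.6, 0.02, "read_through", multimap_fraction = 0.9)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the study design: 44 matched tumor/benign pairs plus 50
#' unpaired tumors, 200 background gene pairs detected at equal rates in
#' both conditions, and the planted fusions of
#' [default_planted_fusions()].
#'
#' @param n_pairs Number of matched tumor/benign pairs.
#' @param n_extra_tumors Number of unpaired tumor samples.
#' @param n_background_pairs Number of background (null) gene pairs.
#' @param background_rate Detection rate of background pairs in both
#'   conditions.
#' @param planted List of [planted_fusion()] objects.
#' @param read_length Read length in bp.
#' @param mean_split_reads Mean split-read count of a detected call.
#' @param lib_size_range Range of per-sample total mapped reads.
#' @param noise_calls_per_sample Sub-threshold calls added per sample to
#'   exercise the call-level screen.
#' @param seed Mandatory RNG seed; identical seeds give byte-identical
#'   cohorts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_pairs = 44L, n_extra_tumors = 50L,
                             n_background_pairs = 200L, background_rate = 0.05,
                             planted = default_planted_fusions(),
                             read_length = 100L, mean_split_reads = 6,
                             lib_size_range = c(4e7, 6e7),
                             noise_calls_per_sample = 3L, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory for reproducibility")
  stopifnot(n_pairs >= 0, n_extra_tumors >= 0, n_background_pairs >= 0,
            background_rate >= 0, background_rate <= 1, mean_split_reads >= 1)
  if (!all(vapply(planted, inherits, logical(1), "planted_fusion"))) {
    stop("planted must be a list of planted_fusion objects")
  }
  structure(list(n_pairs = as.integer(n_pairs),
                 n_extra_tumors = as.integer(n_extra_tumors),
                 n_background_pairs = as.integer(n_background_pairs),
                 background_rate = background_rate, planted = planted,
                 read_length = as.integer(read_length),
                 mean_split_reads = mean_split_reads,
                 lib_size_range = lib_size_range,
                 noise_calls_per_sample = as.integer(noise_calls_per_sample),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# two-gene model realizing one planted geometry on its own contig(s);
# exon/CDS layout is fixed so that the 5' side contributes 400 coding bases
# to the junction (phase 1); frame-compatible 3' genes carry 100 upstream
# CDS bases (phase 1), incompatible ones 101 (phase 2)
.planted_models <- function(pf, idx) {
  ctg <- paste0("ctg", pf$name)
  g5 <- paste0(pf$name, "A")
  g3 <- paste0(pf$name, "B")
  gap <- switch(pf$geometry, read_through = 5000L, distal = 70000L,
                interchromosomal = NA_integer_)
  # 5' gene: exons [1001,1200] [1501,1800] [2101,2400]; CDS 1101..2201
  # (100 + 300 + 101 = 501 coding bases, a complete ORF; the junction at the
  # exon-2 donor carries over 400 coding bases, phase 1)
  e5 <- data.frame(gene_id = g5, transcript_id = paste0(g5, ".t1"),
                   exon_number = 1:3, chrom = ctg,
                   start = c(1001L, 1501L, 2101L), end = c(1200L, 1800L, 2400L),
                   strand = "+", stringsAsFactors = FALSE)
  c5 <- data.frame(gene_id = g5, transcript_id = paste0(g5, ".t1"), chrom = ctg,
                   start = c(1101L, 1501L, 2101L), end = c(1200L, 1800L, 2201L),
                   strand = "+", phase = NA_integer_, stringsAsFactors = FALSE)
  ctg3 <- if (pf$geometry == "interchromosomal") paste0(ctg, "b") else ctg
  s <- if (pf$geometry == "interchromosomal") 1001L else 2400L + gap + 1L
  # 3' gene carries l1 coding bases upstream of its exon-2 acceptor: phase 1
  # (compatible with the 5' carry-over) or phase 2 (incompatible); the final
  # CDS segment length keeps the total a multiple of 3
  l1 <- if (pf$frame_compatible) 100L else 101L
  l3 <- if (pf$frame_compatible) 179L else 178L
  e3 <- data.frame(gene_id = g3, transcript_id = paste0(g3, ".t1"),
                   exon_number = 1:3, chrom = ctg3,
                   start = s + c(0L, 500L, 1100L), end = s + c(199L, 799L, 1399L),
                   strand = "+", stringsAsFactors = FALSE)
  c3 <- data.frame(gene_id = g3, transcript_id = paste0(g3, ".t1"), chrom = ctg3,
                   start = c(s + 200L - l1, s + 500L, s + 1100L),
                   end = c(s + 199L, s + 799L, s + 1099L + l3),
                   strand = "+", phase = NA_integer_, stringsAsFactors = FALSE)
  for (cd_name in c("c5", "c3")) {  # GTF frame column from cumulative length
    cd <- get(cd_name)
    len <- cd$end - cd$start + 1L
    cd$phase <- as.integer((3L - c(0L, cumsum(len)[-length(len)]) %% 3L) %% 3L)
    assign(cd_name, cd)
  }
  genes <- data.frame(
    gene_id = c(g5, g3), gene_name = c(g5, g3),
    chrom = c(ctg, ctg3),
    start = c(1001L, s), end = c(2400L, s + 1399L),
    strand = "+", biotype = c(pf$biotype5, pf$biotype3),
    stringsAsFactors = FALSE)
  bp5 <- if (pf$splice_concordant) 1800L else 1793L   # donor of 5' exon 2
  bp3 <- if (pf$splice_concordant) s + 500L else s + 507L  # acceptor of 3' exon 2
  list(genes = genes, exons = rbind(e5, e3), cds = rbind(c5, c3),
       gene5 = g5, gene3 = g3, chrom5 = ctg, chrom3 = ctg3,
       breakpoint5 = bp5, breakpoint3 = bp3,
       contig_len = c(stats::setNames(2400L + (if (is.na(gap)) 0L else gap) +
                                        (if (ctg3 == ctg) 1400L + 2000L else 2000L), ctg),
                      if (ctg3 != ctg) stats::setNames(s + 1399L + 2000L, ctg3)))
}

# background gene pairs: simple adjacent two-exon genes, a subset lincRNA
.background_models <- function(n_background_pairs) {
  if (n_background_pairs == 0) {
    return(list(genes = NULL, exons = NULL, pairs = NULL))
  }
  per_ctg <- 25L
  i <- seq_len(2L * n_background_pairs)
  ctg <- paste0("bg", (i - 1L) %/% (2L * per_ctg) + 1L)
  slot <- (i - 1L) %% (2L * per_ctg)
  start <- 1001L + slot * 10000L
  gid <- sprintf("BG%04d", i)
  biotype <- ifelse(i %% 10L == 0L, "lincRNA", "protein_coding")
  genes <- data.frame(gene_id = gid, gene_name = gid, chrom = ctg,
                      start = start, end = start + 1399L, strand = "+",
                      biotype = biotype, stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"), exon_number = 1L,
               chrom = ctg, start = start, end = start + 399L, strand = "+",
               stringsAsFactors = FALSE),
    data.frame(gene_id = gid, transcript_id = paste0(gid, ".t1"), exon_number = 2L,
               chrom = ctg, start = start + 1000L, end = start + 1399L, strand = "+",
               stringsAsFactors = FALSE))
  exons <- exons[order(exons$gene_id, exons$exon_number), , drop = FALSE]
  k <- seq_len(n_background_pairs)
  pairs <- data.frame(
    gene5 = gid[2L * k - 1L], gene3 = gid[2L * k],
    chrom5 = ctg[2L * k - 1L], chrom3 = ctg[2L * k],
    breakpoint5 = start[2L * k - 1L] + 392L,   # mid-exon, not a splice site
    breakpoint3 = start[2L * k] + 1007L,
    stringsAsFactors = FALSE)
  list(genes = genes, exons = exons, pairs = pairs)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# contig sequences with stop-free CDS tracks and a terminator after each CDS
.planted_genome <- function(models) {
  seqs <- list()
  for (m in models) {
    for (ctg in names(m$contig_len)) {
      if (is.null(seqs[[ctg]])) seqs[[ctg]] <- .random_dna(m$contig_len[[ctg]])
    }
    for (tx in unique(m$cds$transcript_id)) {
      cd <- m$cds[m$cds$transcript_id == tx, , drop = FALSE]
      cd <- cd[order(cd$start), , drop = FALSE]
      total <- sum(cd$end - cd$start + 1L)
      track <- paste0("ATG", strrep("GCT", ceiling(total / 3)))
      offset <- 0L
      for (j in seq_len(nrow(cd))) {
        w <- cd$end[j] - cd$start[j] + 1L
        piece <- substr(track, offset + 1L, offset + w)
        substr(seqs[[cd$chrom[j]]], cd$start[j], cd$end[j]) <- piece
        offset <- offset + w
      }
      last <- cd[nrow(cd), ]
      substr(seqs[[last$chrom]], last$end + 1L, last$end + 3L) <- "TAA"
    }
  }
  Biostrings::DNAStringSet(unlist(seqs))
}

#' Generate a complete synthetic cohort with planted ground truth
#'
#' Produces every input the nomination pipeline consumes -- manifest,
#' per-sample fusion calls, gene annotation, contig sequences for the
#' planted fusions, gene-level FPKM and exon-level count matrices -- plus a
#' truth table of what was planted. Detection is Bernoulli per sample at
#' the planted rate; split reads are Poisson (at least 1 when detected);
#' discordant pairs at least match the call-level screen; multimapping
#' spanning reads are Binomial(total, multimap_fraction). Identical seeds
#' give byte-identical cohorts.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Optional directory; when given, the cohort is also written as
#'   a file bundle (`manifest.tsv`, `calls/<sample>.tsv`, `annotation.gtf`,
#'   `genome.fa`, `gene_fpkm.tsv`, `exon_counts.tsv`, `truth.tsv`).
#' @return List: `calls` (a `fusion_calls` frame), `manifest`, `annotation`
#'   (an `annotation_db`), `genome` (DNAStringSet), `gene_expr`,
#'   `exon_counts`, `exon_info`, `truth`, `config`, and `files` (paths or
#'   NULL).
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  # --- samples ---------------------------------------------------------
  np <- cfg$n_pairs
  manifest <- data.frame(
    sample_id = c(sprintf("T%03d", seq_len(np)), sprintf("B%03d", seq_len(np)),
                  if (cfg$n_extra_tumors > 0) sprintf("X%03d", seq_len(cfg$n_extra_tumors))),
    condition = c(rep("tumor", np), rep("benign", np),
                  rep("tumor", cfg$n_extra_tumors)),
    pair_id = c(sprintf("P%03d", seq_len(np)), sprintf("P%03d", seq_len(np)),
                rep(NA_character_, cfg$n_extra_tumors)),
    stringsAsFactors = FALSE)
  manifest$total_mapped_reads <- round(stats::runif(nrow(manifest),
                                                    cfg$lib_size_range[1],
                                                    cfg$lib_size_range[2]))
  manifest <- cohort_manifest(manifest)

  # --- annotation ------------------------------------------------------
  models <- lapply(cfg$planted, .planted_models)
  names(models) <- vapply(cfg$planted, `[[`, character(1), "name")
  bg <- .background_models(cfg$n_background_pairs)
  genes <- do.call(rbind, c(lapply(models, `[[`, "genes"), list(bg$genes)))
  exons <- do.call(rbind, c(lapply(models, `[[`, "exons"), list(bg$exons)))
  cds <- do.call(rbind, lapply(models, `[[`, "cds"))
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  db <- annotation_db(genes, exons, cds)
  genome <- .planted_genome(models)

  # --- detection and calls --------------------------------------------
  pair_specs <- rbind(
    do.call(rbind, lapply(seq_along(cfg$planted), function(i) {
      pf <- cfg$planted[[i]]; m <- models[[i]]
      data.frame(name = pf$name, gene5 = m$gene5, gene3 = m$gene3,
                 chrom5 = m$chrom5, chrom3 = m$chrom3,
                 breakpoint5 = m$breakpoint5, breakpoint3 = m$breakpoint3,
                 tumor_rate = pf$tumor_rate, benign_rate = pf$benign_rate,
                 multimap_fraction = pf$multimap_fraction,
                 coupling = pf$coupling, geometry = pf$geometry,
                 splice_concordant = pf$splice_concordant,
                 frame_compatible = pf$frame_compatible,
                 category = if (pf$multimap_fraction > 0.6) "artifact" else "enriched",
                 stringsAsFactors = FALSE)
    })),
    if (!is.null(bg$pairs)) data.frame(
      name = sprintf("BGP%04d", seq_len(nrow(bg$pairs))), bg$pairs,
      tumor_rate = cfg$background_rate, benign_rate = cfg$background_rate,
      multimap_fraction = 0.05, coupling = 0, geometry = "read_through",
      splice_concordant = FALSE, frame_compatible = FALSE,
      category = "background", stringsAsFactors = FALSE)
  )
  ns <- nrow(manifest)
  calls_list <- vector("list", nrow(pair_specs))
  detected_mat <- matrix(FALSE, nrow(pair_specs), ns,
                         dimnames = list(pair_specs$name, manifest$sample_id))
  for (i in seq_len(nrow(pair_specs))) {
    ps <- pair_specs[i, ]
    pr <- ifelse(manifest$condition == "tumor", ps$tumor_rate, ps$benign_rate)
    det <- stats::rbinom(ns, 1L, pr) == 1L
    detected_mat[i, ] <- det
    nd <- sum(det)
    if (nd == 0) next
    split <- 1L + stats::rpois(nd, cfg$mean_split_reads - 1)
    disc <- split + 5L + stats::rpois(nd, 2)
    mm <- stats::rbinom(nd, disc, ps$multimap_fraction)
    calls_list[[i]] <- data.frame(
      sample_id = manifest$sample_id[det],
      gene5 = ps$gene5, gene3 = ps$gene3,
      chrom5 = ps$chrom5, chrom3 = ps$chrom3,
      breakpoint5 = ps$breakpoint5, breakpoint3 = ps$breakpoint3,
      strand5 = "+", strand3 = "+",
      discordant_pairs = disc, split_reads = split,
      multimap_spanning = mm, total_spanning = disc,
      probability = round(stats::runif(nd, 0.1, 0.99), 4),
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls_list)
  # sub-threshold noise calls (fail the screen; genes deliberately unannotated)
  if (cfg$noise_calls_per_sample > 0) {
    nn <- ns * cfg$noise_calls_per_sample
    noise <- data.frame(
      sample_id = rep(manifest$sample_id, each = cfg$noise_calls_per_sample),
      gene5 = sprintf("NOISE%03dA", sample.int(300, nn, replace = TRUE)),
      gene3 = sprintf("NOISE%03dB", sample.int(300, nn, replace = TRUE)),
      chrom5 = "bg1", chrom3 = "bg1",
      breakpoint5 = sample.int(200000, nn, replace = TRUE),
      breakpoint3 = sample.int(200000, nn, replace = TRUE),
      strand5 = "+", strand3 = "+",
      discordant_pairs = sample.int(4, nn, replace = TRUE),
      split_reads = stats::rpois(nn, 1),
      multimap_spanning = 0L, total_spanning = 0L,
      probability = round(stats::runif(nn, 0.05, 0.9), 4),
      stringsAsFactors = FALSE)
    noise$total_spanning <- noise$discordant_pairs
    calls <- rbind(calls, noise)
  }
  calls <- calls[order(calls$sample_id, calls$gene5, calls$gene3), , drop = FALSE]
  calls <- fusion_calls(calls)

  # --- expression ------------------------------------------------------
  gene_ids <- db$genes$gene_id
  base <- stats::rlnorm(length(gene_ids), log(10), 0.8)
  gene_expr <- matrix(base, nrow = length(gene_ids), ncol = ns) *
    matrix(stats::rlnorm(length(gene_ids) * ns, 0, 0.25), length(gene_ids), ns)
  dimnames(gene_expr) <- list(gene_ids, manifest$sample_id)
  for (i in seq_len(nrow(pair_specs))) {
    ps <- pair_specs[i, ]
    if (ps$coupling > 0) {
      pos <- detected_mat[i, ]
      gene_expr[ps$gene3, pos] <- gene_expr[ps$gene3, pos] * 2^ps$coupling
    }
  }
  gene_expr <- round(gene_expr, 4)

  # exon counts for the planted 3' partners
  exon_rows <- list(); exon_info <- list()
  for (i in seq_along(cfg$planted)) {
    pf <- cfg$planted[[i]]; m <- models[[i]]
    e3 <- db$exons[db$exons$gene_id == m$gene3, , drop = FALSE]
    ids <- sprintf("%s:e%d", m$gene3, e3$exon_number)
    downstream <- e3$start >= m$breakpoint3  # "+" strand planted genes
    lam <- outer(rep(200, nrow(e3)), manifest$total_mapped_reads / 5e7)
    boost <- 1 + outer(downstream, detected_mat[pf$name, ]) * (2^pf$coupling - 1)
    cnt <- matrix(stats::rpois(length(lam), lam * boost), nrow(e3), ns)
    dimnames(cnt) <- list(ids, manifest$sample_id)
    exon_rows[[i]] <- cnt
    exon_info[[i]] <- data.frame(exon_id = ids, gene_id = m$gene3,
                                 start = e3$start, end = e3$end,
                                 strand = e3$strand, stringsAsFactors = FALSE)
  }
  exon_counts <- do.call(rbind, exon_rows)
  exon_info <- do.call(rbind, exon_info)

  truth <- data.frame(pair = paste(pair_specs$gene5, pair_specs$gene3, sep = "|"),
                      pair_specs, stringsAsFactors = FALSE)

  out <- list(calls = calls, manifest = manifest, annotation = db,
              genome = genome, gene_expr = expression_matrix(gene_expr, manifest),
              exon_counts = expression_matrix(exon_counts, manifest, unit = "count"),
              exon_info = exon_info, truth = truth, config = cfg, files = NULL)
  if (!is.null(dir)) out$files <- .write_cohort_bundle(out, dir)
  out
}

.write_cohort_bundle <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  files <- list(manifest = file.path(dir, "manifest.tsv"),
                annotation = file.path(dir, "annotation.gtf"),
                genome = file.path(dir, "genome.fa"),
                gene_expr = file.path(dir, "gene_fpkm.tsv"),
                exon_counts = file.path(dir, "exon_counts.tsv"),
                truth = file.path(dir, "truth.tsv"),
                calls_dir = file.path(dir, "calls"))
  write_manifest(cohort$manifest, files$manifest)
  write_annotation(cohort$annotation, files$annotation)
  Biostrings::writeXStringSet(cohort$genome, files$genome)
  write_expression_matrix(cohort$gene_expr, files$gene_expr, "gene_id")
  write_expression_matrix(cohort$exon_counts, files$exon_counts, "exon_id")
  utils::write.table(cohort$truth, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dialect <- fusion_dialect()
  inv <- stats::setNames(names(dialect$map), unlist(dialect$map))
  for (s in cohort$manifest$sample_id) {
    sub <- as.data.frame(cohort$calls[cohort$calls$sample_id == s, , drop = FALSE])
    sub$sample_id <- NULL
    names(sub) <- unlist(dialect$map)[names(sub)]
    utils::write.table(sub, file.path(dir, "calls", paste0(s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  files
}

#' Score nominated candidates against the planted truth
#'
#' @param records Candidate records (from [run_cascade()]).
#' @param truth Truth table from [generate_cohort()].
#' @return List: `precision`, `recall` (of planted enriched fusions; both
#'   defined as 1 when the corresponding set is empty), and
#'   `by_category` (nominated counts per truth category).
#' @export
truth_evaluation <- function(records, truth) {
  nominated <- records$pair
  enriched <- truth$pair[truth$category == "enriched"]
  tp <- intersect(nominated, enriched)
  by_cat <- table(factor(truth$category[match(nominated, truth$pair)],
                         levels = c("enriched", "artifact", "background")))
  list(
    precision = if (length(nominated) == 0) 1 else length(tp) / length(nominated),
    recall = if (length(enriched) == 0) 1 else length(tp) / length(enriched),
    by_category = by_cat
  )
}
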