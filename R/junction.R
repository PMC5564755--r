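# ---- transcript-model helpers (coordinates 1-based inclusive) -------------

.tx_exons <- function(db, transcript_id) {
  e <- db$exons[db$exons$transcript_id == transcript_id, , drop = FALSE]
  e[order(e$exon_number), , drop = FALSE]
}

.tx_cds <- function(db, transcript_id) {
  db$cds[db$cds$transcript_id == transcript_id, , drop = FALSE]
}

# exon donor (3'-end in transcription direction) / acceptor (5'-start)
.exon_donor <- function(exons) ifelse(exons$strand == "+", exons$end, exons$start)
.exon_acceptor <- function(exons) ifelse(exons$strand == "+", exons$start, exons$end)

# bases of [start, end] lying transcription-upstream of pos (inclusive flag)
.upstream_width <- function(start, end, strand, pos, inclusive) {
  if (strand == "+") {
    hi <- if (inclusive) pos else pos - 1
    pmax(0, pmin(end, hi) - start + 1)
  } else {
    lo <- if (inclusive) pos else pos + 1
    pmax(0, end - pmax(start, lo) + 1)
  }
}

#' Partner-gene geometry and read-through classification
#'
#' Computes the genomic relationship between the 5' and 3' partner genes:
#' chromosome co-localization, the gap between the two gene spans (0 when
#' abutting, undefined for interchromosomal pairs), the strand
#' configuration, and whether the pair is a read-through (cis-SAGe)
#' candidate: same chromosome, same strand, gap at most `distance_cap`
#' (default 60 kb), with the 5' gene transcriptionally upstream of the 3'
#' gene. The distance is symmetric in gene order; the read-through call is
#' not (it is directional).
#'
#' @param gene5,gene3 Gene ids (or names) of the 5' and 3' partners.
#' @param db An [annotation_db()]; both genes must be annotated.
#' @param distance_cap Maximum gap in bp for a read-through candidate.
#' @return An object of class `pair_geometry`: `same_chromosome`,
#'   `inner_distance_bp` (NA when interchromosomal), `strand_config`,
#'   `read_through_candidate`.
#' @export
classify_pair <- function(gene5, gene3, db, distance_cap = 60000L) {
  g5 <- .gene_record(db, gene5)
  g3 <- .gene_record(db, gene3)
  if (is.null(g5)) stop("gene not in annotation: ", gene5)
  if (is.null(g3)) stop("gene not in annotation: ", gene3)
  same_chrom <- g5$chrom == g3$chrom
  dist <- NA_integer_
  if (same_chrom) {
    gap <- max(g5$start, g3$start) - min(g5$end, g3$end) - 1L
    dist <- max(0L, as.integer(gap))
  }
  upstream <- same_chrom && g5$strand == g3$strand &&
    ((g5$strand == "+" && g5$end < g3$start) ||
       (g5$strand == "-" && g5$start > g3$end))
  structure(list(
    same_chromosome = same_chrom,
    inner_distance_bp = dist,
    strand_config = c(g5$strand, g3$strand),
    read_through_candidate = isTRUE(upstream && dist <= distance_cap)
  ), class = "pair_geometry")
}

#' @export
print.pair_geometry <- function(x, ...) {
  cat(sprintf("pair geometry: %s, distance %s bp, strands %s%s, read-through candidate: %s\n",
              if (x$same_chromosome) "same chromosome" else "interchromosomal",
              if (is.na(x$inner_distance_bp)) "NA" else format(x$inner_distance_bp),
              x$strand_config[1], x$strand_config[2],
              x$read_through_candidate))
  invisible(x)
}

# transcripts of `gene` having an exon whose donor/acceptor equals pos
.matching_transcripts <- function(db, gene, pos, side = c("donor", "acceptor")) {
  side <- match.arg(side)
  g <- .gene_record(db, gene)
  if (is.null(g)) return(character(0))
  e <- db$exons[db$exons$gene_id == g$gene_id, , drop = FALSE]
  if (nrow(e) == 0) return(character(0))
  site <- if (side == "donor") .exon_donor(e) else .exon_acceptor(e)
  sort(unique(e$transcript_id[site == pos]))
}

#' Is the fusion junction at annotated splice sites?
#'
#' TRUE iff the 5' breakpoint coincides with an annotated exon 3'-end
#' (splice donor) of some transcript of the 5' gene, and the 3' breakpoint
#' with an annotated exon 5'-start (splice acceptor) of some transcript of
#' the 3' gene, strand-aware. The rule is existential over transcripts.
#'
#' @param call One fusion call: a one-row data frame or list with fields
#'   `gene5`, `gene3`, `breakpoint5`, `breakpoint3`.
#' @param db An [annotation_db()].
#' @return Logical scalar. Unannotated partners give FALSE with a warning.
#' @export
junction_at_splice_sites <- function(call, db) {
  g5 <- .gene_record(db, call$gene5)
  g3 <- .gene_record(db, call$gene3)
  if (is.null(g5) || is.null(g3)) {
    warning("unannotated fusion partner; junction_at_splice_sites is FALSE")
    return(FALSE)
  }
  length(.matching_transcripts(db, call$gene5, call$breakpoint5, "donor")) > 0 &&
    length(.matching_transcripts(db, call$gene3, call$breakpoint3, "acceptor")) > 0
}

# total CDS length of a transcript
.cds_total <- function(db, tx) {
  cd <- .tx_cds(db, tx)
  if (nrow(cd) == 0) 0L else sum(cd$end - cd$start + 1L)
}

#' Reading-frame and fusion-peptide prediction for a candidate junction
#'
#' Models the fusion transcript as the 5' partner's exons through the
#' breakpoint joined to the 3' partner's exons from the breakpoint onward.
#' When both breakpoints are at annotated splice sites, a transcript pair is
#' chosen (the pair maximizing total CDS coverage, ties broken by transcript
#' id) and the junction is in frame iff the number of coding bases
#' contributed by the 5' side is congruent, modulo 3, to the number of
#' coding bases of the 3' transcript lying upstream of the breakpoint --
#' i.e. the reading phase carried over from the 5' CDS equals the native
#' phase of the 3' CDS at the junction. Junctions not at splice sites are
#' not in frame by definition; junctions in the 3' partner's 5' UTR are
#' called in frame only when the CDS starts exactly at the breakpoint.
#' The 5' CDS must be genuinely truncated by the junction (a junction
#' downstream of the complete 5' ORF would translate the native protein,
#' not a chimeric one).
#'
#' @param call One fusion call (fields as in [junction_at_splice_sites()]).
#' @param db An [annotation_db()].
#' @param genome Optional named [Biostrings::DNAStringSet] of contig
#'   sequences; when supplied, the chimeric ORF is translated to its first
#'   stop codon and the peptide is returned.
#' @return An object of class `junction_annotation`: `at_splice_sites`,
#'   `in_frame`, `transcript5`, `transcript3`, `exons5`/`exons3` (retained
#'   exon numbers), `cds5_len`, `aa5` (residues contributed by the 5'
#'   partner), `peptide_length` (NA unless in frame), `peptide` (character
#'   or NA).
#' @export
predict_frame <- function(call, db, genome = NULL) {
  out <- list(at_splice_sites = FALSE, in_frame = FALSE,
              transcript5 = NA_character_, transcript3 = NA_character_,
              exons5 = integer(0), exons3 = integer(0),
              cds5_len = NA_integer_, aa5 = NA_integer_,
              peptide_length = NA_integer_, peptide = NA_character_)
  class(out) <- "junction_annotation"
  if (!junction_at_splice_sites(call, db)) return(out)
  out$at_splice_sites <- TRUE

  tx5_all <- .matching_transcripts(db, call$gene5, call$breakpoint5, "donor")
  tx3_all <- .matching_transcripts(db, call$gene3, call$breakpoint3, "acceptor")
  # canonical-like choice: maximize total CDS coverage, tie-break by id
  tx5 <- tx5_all[order(-vapply(tx5_all, .cds_total, integer(1), db = db), tx5_all)][1]
  tx3 <- tx3_all[order(-vapply(tx3_all, .cds_total, integer(1), db = db), tx3_all)][1]
  out$transcript5 <- tx5
  out$transcript3 <- tx3

  e5 <- .tx_exons(db, tx5)
  e3 <- .tx_exons(db, tx3)
  k5 <- e5$exon_number[.exon_donor(e5) == call$breakpoint5][1]
  m3 <- e3$exon_number[.exon_acceptor(e3) == call$breakpoint3][1]
  out$exons5 <- e5$exon_number[e5$exon_number <= k5]
  out$exons3 <- e3$exon_number[e3$exon_number >= m3]

  cd5 <- .tx_cds(db, tx5)
  cd3 <- .tx_cds(db, tx3)
  strand5 <- e5$strand[1]
  strand3 <- e3$strand[1]

  cds5_len <- if (nrow(cd5) == 0) 0L else {
    as.integer(sum(.upstream_width(cd5$start, cd5$end, strand5,
                                   call$breakpoint5, inclusive = TRUE)))
  }
  total_cds5 <- .cds_total(db, tx5)
  total_cds3 <- .cds_total(db, tx3)
  off3 <- if (nrow(cd3) == 0) 0L else {
    as.integer(sum(.upstream_width(cd3$start, cd3$end, strand3,
                                   call$breakpoint3, inclusive = FALSE)))
  }
  out$cds5_len <- cds5_len
  out$aa5 <- cds5_len %/% 3L

  if (cds5_len == 0L || total_cds3 == 0L) return(out)        # no CDS on one side
  if (cds5_len >= total_cds5) return(out)                    # 5' ORF not truncated
  if (off3 >= total_cds3) return(out)                        # no coding 3' remainder
  if (off3 == 0L) {
    # junction upstream of the 3' CDS: require the CDS to start at the junction
    cds3_start <- if (strand3 == "+") min(cd3$start) else max(cd3$end)
    utr_gap <- sum(.upstream_width(e3$start, e3$end, strand3, cds3_start,
                                   inclusive = FALSE)) -
      sum(.upstream_width(e3$start, e3$end, strand3, call$breakpoint3,
                          inclusive = FALSE))
    if (utr_gap != 0) return(out)
  }
  if ((cds5_len %% 3L) != (off3 %% 3L)) return(out)

  out$in_frame <- TRUE
  out$peptide_length <- as.integer((cds5_len + (total_cds3 - off3)) %/% 3L)
  if (!is.null(genome)) {
    pep <- .translate_fusion(call, db, genome, tx5, tx3, cd5, e3, strand5, strand3)
    if (!is.na(pep)) {
      out$peptide <- pep
      out$peptide_length <- nchar(pep)
    }
  }
  out
}

#' @export
print.junction_annotation <- function(x, ...) {
  cat(sprintf("junction: at splice sites: %s; in frame: %s\n",
              x$at_splice_sites, x$in_frame))
  if (x$at_splice_sites) {
    cat(sprintf("  transcripts %s | %s; retained exons 5' %s / 3' %s\n",
                x$transcript5, x$transcript3,
                paste(range(x$exons5), collapse = "-"),
                paste(range(x$exons3), collapse = "-")))
  }
  if (isTRUE(x$in_frame)) {
    cat(sprintf("  5'-contributed residues: %d; predicted peptide length: %s\n",
                x$aa5, format(x$peptide_length)))
  }
  invisible(x)
}

# spliced sequence of genomic segments in transcription order
.segment_seq <- function(genome, chrom, starts, ends, strand) {
  if (length(starts) == 0) return("")
  if (!chrom %in% names(genome)) return(NA_character_)
  ord <- order(starts)
  segs <- vapply(ord, function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], starts[i], ends[i]))
  }, character(1))
  s <- paste(segs, collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

.translate_fusion <- function(call, db, genome, tx5, tx3, cd5, e3, strand5, strand3) {
  # 5' coding sequence up to the junction (CDS segments truncated at breakpoint)
  keep5 <- .upstream_width(cd5$start, cd5$end, strand5, call$breakpoint5, TRUE) > 0
  c5 <- cd5[keep5, , drop = FALSE]
  if (strand5 == "+") {
    c5$end <- pmin(c5$end, call$breakpoint5)
  } else {
    c5$start <- pmax(c5$start, call$breakpoint5)
  }
  seq5 <- .segment_seq(genome, c5$chrom[1], c5$start, c5$end, strand5)
  # 3' transcribed sequence from the junction to transcript end (CDS + 3' UTR)
  down3 <- .upstream_width(e3$start, e3$end, strand3, call$breakpoint3, FALSE)
  keep3 <- (e3$end - e3$start + 1 - down3) > 0
  x3 <- e3[keep3, , drop = FALSE]
  if (strand3 == "+") {
    x3$start <- pmax(x3$start, call$breakpoint3)
  } else {
    x3$end <- pmin(x3$end, call$breakpoint3)
  }
  seq3 <- .segment_seq(genome, x3$chrom[1], x3$start, x3$end, strand3)
  if (is.na(seq5) || is.na(seq3)) return(NA_character_)
  fus <- paste0(seq5, seq3)
  fus <- substr(fus, 1, nchar(fus) - nchar(fus) %% 3)
  if (nchar(fus) < 3) return(NA_character_)
  aa <- as.character(suppressWarnings(
    Biostrings::translate(Biostrings::DNAString(fus), if.fuzzy.codon = "X")))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) substr(aa, 1, stop_at - 1) else aa
}

#' Domain retention in a predicted fusion protein
#'
#' Given protein-coordinate domain intervals on the native partner
#' proteins, reports for each domain whether it is fully retained in the
#' chimeric protein, truncated by the junction, or lost. A domain is
#' retained iff its interval lies entirely within the translated portion
#' contributed by its source partner.
#'
#' @param ja A `junction_annotation` with `in_frame = TRUE`.
#' @param domains Data frame: `domain` (name), `partner` (`"5prime"` or
#'   `"3prime"`), `start_aa`, `end_aa` (1-based residue interval on the
#'   native protein of that partner).
#' @param db An [annotation_db()] (for native protein lengths).
#' @return Data frame: `domain`, `partner`, `status` in
#'   `{retained, truncated, lost}`. Empty input gives an empty result.
#' @export
domain_retention <- function(ja, domains, db) {
  if (!isTRUE(ja$in_frame)) stop("domain retention requires an in-frame junction")
  domains <- as.data.frame(domains, stringsAsFactors = FALSE)
  if (nrow(domains) == 0) {
    return(data.frame(domain = character(0), partner = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  if (!all(domains$partner %in% c("5prime", "3prime"))) {
    stop("partner must be '5prime' or '3prime'")
  }
  len5 <- .cds_total(db, ja$transcript5) %/% 3L
  len3 <- .cds_total(db, ja$transcript3) %/% 3L
  aa5 <- ja$aa5
  # residues of the native 3' protein lost upstream of the junction
  off3_aa <- len3 - (ja$peptide_length - aa5)
  status <- character(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    s <- domains$start_aa[i]; e <- domains$end_aa[i]
    lim <- if (domains$partner[i] == "5prime") len5 else len3
    if (s < 1 || e < s || e > lim) {
      stop("domain interval outside native protein length: ", domains$domain[i])
    }
    if (domains$partner[i] == "5prime") {
      status[i] <- if (e <= aa5) "retained" else if (s > aa5) "lost" else "truncated"
    } else {
      status[i] <- if (s > off3_aa) "retained" else if (e <= off3_aa) "lost" else "truncated"
    }
  }
  data.frame(domain = domains$domain, partner = domains$partner,
             status = status, stringsAsFactors = FALSE)
}
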