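#' Construct an annotation database from gene/exon/CDS tables
#'
#' In-memory gene-model container used for junction annotation: gene spans
#' with biotypes, ordered exon intervals per transcript, and CDS intervals.
#' All coordinates are 1-based inclusive (GTF convention) on both the
#' interface and internally.
#'
#' @param genes Data frame: `gene_id`, `gene_name`, `chrom`, `start`, `end`,
#'   `strand`, `biotype`.
#' @param exons Data frame: `gene_id`, `transcript_id`, `exon_number`,
#'   `chrom`, `start`, `end`, `strand`.
#' @param cds Data frame (possibly empty): `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `phase`.
#' @param exon_policy What to do with an exon outside its gene span:
#'   `"clamp"` (default) clamps it to the span with a warning, `"reject"`
#'   raises an error.
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(genes, exons, cds = NULL,
                          exon_policy = c("clamp", "reject")) {
  exon_policy <- match.arg(exon_policy)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (is.null(cds)) {
    cds <- data.frame(gene_id = character(0), transcript_id = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), phase = integer(0),
                      stringsAsFactors = FALSE)
  }
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)

  req_g <- c("gene_id", "gene_name", "chrom", "start", "end", "strand", "biotype")
  req_e <- c("gene_id", "transcript_id", "exon_number", "chrom", "start", "end", "strand")
  req_c <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  if (length(setdiff(req_g, names(genes))) > 0) stop("genes table lacks required columns")
  if (length(setdiff(req_e, names(exons))) > 0) stop("exons table lacks required columns")
  if (length(setdiff(req_c, names(cds))) > 0) stop("cds table lacks required columns")
  if (!"phase" %in% names(cds)) cds$phase <- NA_integer_

  for (df_name in c("genes", "exons", "cds")) {
    df <- get(df_name)
    if (nrow(df) > 0 && (any(df$start < 1) || any(df$end < df$start))) {
      stop(df_name, ": coordinates must be positive with start <= end")
    }
  }
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in genes table")

  # exon-within-gene-span check
  if (nrow(exons) > 0) {
    gidx <- match(exons$gene_id, genes$gene_id)
    if (anyNA(gidx)) stop("exon references unknown gene_id")
    outside <- exons$start < genes$start[gidx] | exons$end > genes$end[gidx]
    if (any(outside)) {
      if (exon_policy == "reject") {
        stop(sum(outside), " exon(s) extend outside their gene span")
      }
      warning(sum(outside), " exon(s) extend outside their gene span; clamped")
      exons$start <- pmax(exons$start, genes$start[gidx])
      exons$end <- pmin(exons$end, genes$end[gidx])
    }
  }
  exons$exon_number <- as.integer(exons$exon_number)
  exons <- exons[order(exons$transcript_id, exons$exon_number), , drop = FALSE]

  # CDS within exons of the same transcript
  if (nrow(cds) > 0) {
    for (i in seq_len(nrow(cds))) {
      te <- exons[exons$transcript_id == cds$transcript_id[i], , drop = FALSE]
      if (nrow(te) == 0 ||
          !any(cds$start[i] >= te$start & cds$end[i] <= te$end)) {
        stop("CDS segment not contained in an exon of transcript ",
             cds$transcript_id[i])
      }
    }
  }
  rownames(genes) <- rownames(exons) <- rownames(cds) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat(sprintf("annotation_db: %d genes, %d transcripts, %d exon rows, %d CDS rows\n",
              nrow(x$genes), length(unique(x$exons$transcript_id)),
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

.gene_record <- function(db, gene_id) {
  i <- match(gene_id, db$genes$gene_id)
  if (is.na(i)) {
    i <- match(gene_id, db$genes$gene_name)
  }
  if (is.na(i)) return(NULL)
  db$genes[i, , drop = FALSE]
}

#' Read gene annotation from a GTF file
#'
#' Imports an Ensembl-style GTF (gene/transcript/exon/CDS features with
#' `gene_id`, `transcript_id`, `gene_biotype` attributes) into an
#' [annotation_db()]. Gene spans are taken from `gene` features when
#' present, otherwise derived from the exon extent per gene. A missing
#' `gene_biotype` attribute is recorded as `"unknown"` with a warning (the
#' biotype filter will then reject those genes loudly).
#'
#' @param path GTF file path.
#' @param chrom_prefix Chromosome-name normalization as in
#'   [fusion_dialect()]: `"strip"` (default), `"add"` or `"keep"`.
#' @param exon_policy Passed to [annotation_db()].
#' @return An `annotation_db`.
#' @export
read_annotation <- function(path, chrom_prefix = c("strip", "add", "keep"),
                            exon_policy = c("clamp", "reject")) {
  chrom_prefix <- match.arg(chrom_prefix)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  chrom <- .normalize_chrom(as.character(GenomicRanges::seqnames(gr)), chrom_prefix)
  df <- data.frame(
    type = as.character(m$type),
    chrom = chrom,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(m$gene_id),
    stringsAsFactors = FALSE
  )
  df$transcript_id <- if ("transcript_id" %in% names(m)) {
    as.character(m$transcript_id)
  } else NA_character_
  df$gene_name <- if ("gene_name" %in% names(m)) {
    as.character(m$gene_name)
  } else df$gene_id
  df$gene_name[is.na(df$gene_name)] <- df$gene_id[is.na(df$gene_name)]
  if ("gene_biotype" %in% names(m)) {
    df$biotype <- as.character(m$gene_biotype)
    df$biotype[is.na(df$biotype)] <- "unknown"
  } else {
    warning("GTF lacks gene_biotype attribute; biotypes recorded as 'unknown'")
    df$biotype <- "unknown"
  }
  df$exon_number <- if ("exon_number" %in% names(m)) {
    suppressWarnings(as.integer(as.character(m$exon_number)))
  } else NA_integer_
  df$phase <- if ("phase" %in% names(m)) {
    suppressWarnings(as.integer(as.character(m$phase)))
  } else NA_integer_

  ex <- df[df$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) stop("GTF contains no exon features")
  if (anyNA(ex$exon_number)) {
    # assign exon numbers in transcription order per transcript
    ex <- ex[order(ex$transcript_id, ex$start), , drop = FALSE]
    ex$exon_number <- stats::ave(ex$start, ex$transcript_id, FUN = function(s) {
      seq_along(s)
    })
    neg <- ex$strand == "-"
    ex$exon_number[neg] <- stats::ave(ex$start[neg], ex$transcript_id[neg],
                                      FUN = function(s) rev(seq_along(s)))
  }

  g <- df[df$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) {
    g <- do.call(rbind, lapply(split(ex, ex$gene_id), function(e) {
      data.frame(gene_id = e$gene_id[1], gene_name = e$gene_name[1],
                 chrom = e$chrom[1], start = min(e$start), end = max(e$end),
                 strand = e$strand[1], biotype = e$biotype[1],
                 stringsAsFactors = FALSE)
    }))
  } else {
    g <- g[, c("gene_id", "gene_name", "chrom", "start", "end", "strand", "biotype")]
  }
  cd <- df[df$type == "CDS", , drop = FALSE]
  annotation_db(
    genes = g,
    exons = ex[, c("gene_id", "transcript_id", "exon_number",
                   "chrom", "start", "end", "strand")],
    cds = cd[, c("gene_id", "transcript_id", "chrom", "start", "end",
                 "strand", "phase")],
    exon_policy = exon_policy
  )
}

# GTF frame column from cumulative CDS length in transcription order
.fill_cds_phases <- function(cd) {
  parts <- split(seq_len(nrow(cd)), cd$transcript_id)
  for (idx in parts) {
    ord <- idx[order(if (cd$strand[idx[1]] == "+") cd$start[idx] else -cd$end[idx])]
    len <- cd$end[ord] - cd$start[ord] + 1L
    cum <- c(0L, cumsum(len)[-length(len)])
    cd$phase[ord] <- as.integer((3L - cum %% 3L) %% 3L)
  }
  cd
}

#' Write an annotation database as GTF
#'
#' Emits gene, exon and CDS features; `read_annotation()` on the written
#' file reconstructs the same gene models (round-trip).
#'
#' @param db An `annotation_db`.
#' @param path Output GTF path.
#' @export
write_annotation <- function(db, path) {
  g <- db$genes
  gene_rows <- data.frame(chrom = g$chrom, start = g$start, end = g$end,
                          strand = g$strand, type = "gene", gene_id = g$gene_id,
                          transcript_id = NA_character_,
                          exon_number = NA_integer_, gene_name = g$gene_name,
                          biotype = g$biotype, phase = NA_integer_,
                          stringsAsFactors = FALSE)
  e <- db$exons
  gidx <- match(e$gene_id, g$gene_id)
  exon_rows <- data.frame(chrom = e$chrom, start = e$start, end = e$end,
                          strand = e$strand, type = "exon", gene_id = e$gene_id,
                          transcript_id = e$transcript_id,
                          exon_number = e$exon_number,
                          gene_name = g$gene_name[gidx],
                          biotype = g$biotype[gidx], phase = NA_integer_,
                          stringsAsFactors = FALSE)
  cd <- db$cds
  rows <- rbind(gene_rows, exon_rows)
  if (nrow(cd) > 0) {
    if (anyNA(cd$phase)) cd <- .fill_cds_phases(cd)
    cidx <- match(cd$gene_id, g$gene_id)
    cds_rows <- data.frame(chrom = cd$chrom, start = cd$start, end = cd$end,
                           strand = cd$strand, type = "CDS", gene_id = cd$gene_id,
                           transcript_id = cd$transcript_id,
                           exon_number = NA_integer_,
                           gene_name = g$gene_name[cidx],
                           biotype = g$biotype[cidx],
                           phase = as.integer(cd$phase),
                           stringsAsFactors = FALSE)
    rows <- rbind(rows, cds_rows)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$source <- "fusionNominate"
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$exon_number <- rows$exon_number
  S4Vectors::mcols(gr)$gene_name <- rows$gene_name
  S4Vectors::mcols(gr)$gene_biotype <- rows$biotype
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
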