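#' Nominate recurrent, tumor-enriched fusion transcripts
#'
#' End-to-end pipeline: runs the filter cascade ([run_cascade()]), then for
#' each nominated candidate computes the 3'-partner association statistics
#' (positive-vs-negative and positive-vs-benign rank-sum tests, Spearman
#' correlation of fusion vs partner expression) when a gene expression
#' matrix is supplied, and hierarchically clusters the candidates'
#' normalized differential breakpoint-expression profiles across the
#' matched pairs.
#'
#' @param calls A `fusion_calls` data frame for the whole cohort.
#' @param manifest A [cohort_manifest()].
#' @param annotation An [annotation_db()].
#' @param thresholds A [filter_thresholds()].
#' @param expression Optional gene expression matrix (genes x samples).
#' @param genome Optional contig sequences (for peptide prediction).
#' @param cluster_linkage Linkage for [cluster_profiles()].
#' @return An object of class `fusion_nominations`: elements `records`,
#'   `log`, `removed`, `associations`, `clustering`, `rpkm`, `pdm`,
#'   `thresholds`, `cohort`.
#' @export
nominate_fusions <- function(calls, manifest, annotation,
                             thresholds = filter_thresholds(),
                             expression = NULL, genome = NULL,
                             cluster_linkage = "average") {
  cas <- run_cascade(calls, manifest, annotation, thresholds, genome = genome)
  records <- cas$records

  associations <- NULL
  if (!is.null(expression) && nrow(records) > 0) {
    associations <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
      pair <- records$pair[i]
      gene3 <- records$gene3[i]
      part <- partition_samples(pair, cas$pdm, manifest)
      res <- data.frame(pair = pair, gene3 = gene3,
                        p_pos_vs_neg_tumor = NA_real_, p_pos_vs_benign = NA_real_,
                        spearman_rho = NA_real_, spearman_p = NA_real_,
                        n_pos = length(part$positive_tumor),
                        n_neg = length(part$negative_tumor),
                        stringsAsFactors = FALSE)
      if (gene3 %in% rownames(expression)) {
        tp <- suppressWarnings(three_prime_partner_test(expression, gene3, part))
        res$p_pos_vs_neg_tumor <- tp$p_pos_vs_neg_tumor
        res$p_pos_vs_benign <- tp$p_pos_vs_benign
        tumors <- manifest$sample_id[manifest$condition == "tumor"]
        tumors <- intersect(tumors, colnames(expression))
        co <- suppressWarnings(fusion_partner_correlation(
          cas$rpkm[pair, tumors], expression[gene3, tumors]))
        res$spearman_rho <- co$rho
        res$spearman_p <- co$p
      }
      res
    }))
    rownames(associations) <- NULL
  }

  clustering <- NULL
  paired <- .paired_rpkm(cas$rpkm, manifest)
  if (nrow(records) >= 2 && length(paired$pair_ids) > 0) {
    nd <- normalize_differential(paired$tumor[records$pair, , drop = FALSE],
                                 paired$benign[records$pair, , drop = FALSE])
    clustering <- tryCatch(
      suppressWarnings(cluster_profiles(nd, linkage = cluster_linkage)),
      error = function(e) NULL)
  }

  structure(list(records = records, log = cas$log, removed = cas$removed,
                 associations = associations, clustering = clustering,
                 rpkm = cas$rpkm, pdm = cas$pdm, thresholds = thresholds,
                 cohort = summary(manifest)),
            class = "fusion_nominations")
}

#' @export
print.fusion_nominations <- function(x, ...) {
  print(x$cohort)
  cat("Filter cascade (candidates surviving each stage):\n")
  for (i in seq_len(nrow(x$log))) {
    cat(sprintf("  %-18s %5d -> %5d  %s\n", x$log$stage[i],
                x$log$n_before[i], x$log$n_after[i], x$log$reason[i]))
  }
  cat(sprintf("Nominated fusion transcripts: %d\n", nrow(x$records)))
  if (nrow(x$records) > 0) {
    top <- utils::head(x$records[order(x$records$fisher_p), ], 5)
    cat("  top candidates (by enrichment p):\n")
    for (i in seq_len(nrow(top))) {
      cat(sprintf("    %s-%s  tumor %d, benign %d  Fisher p = %s\n",
                  top$gene5[i], top$gene3[i], top$n_tumor_pos[i],
                  top$n_benign_pos[i], format_pvalue(top$fisher_p[i])))
    }
  }
  invisible(x)
}

#' @export
summary.fusion_nominations <- function(object, ...) {
  out <- list(log = object$log, n_nominated = nrow(object$records),
              records = object$records, associations = object$associations)
  class(out) <- "summary.fusion_nominations"
  out
}

#' @export
print.summary.fusion_nominations <- function(x, ...) {
  cat(sprintf("Nominated fusion transcripts: %d\n", x$n_nominated))
  if (x$n_nominated > 0) {
    df <- x$records[, c("gene5", "gene3", "n_tumor_pos", "n_benign_pos")]
    df$fisher_p <- format_pvalue(x$records$fisher_p)
    df$wilcoxon_p <- format_pvalue(x$records$wilcoxon_p)
    df$in_frame <- .format_yn(x$records$in_frame)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.fusion_nominations <- function(x, ...) {
  if (is.null(x$clustering)) {
    stop("no clustering available (need >= 2 nominated candidates and matched pairs)")
  }
  plot(x$clustering$hclust,
       main = "Candidate fusions: Pearson-distance clustering",
       xlab = "normalized differential breakpoint expression", sub = "", ...)
  invisible(x)
}

#' Load a cohort file bundle
#'
#' Reads the bundle layout written by [generate_cohort()] (or assembled by
#' hand): `manifest.tsv`, `calls/` with one TSV per sample,
#' `annotation.gtf`, and optionally `gene_fpkm.tsv` and `genome.fa`.
#'
#' @param dir Bundle directory.
#' @param dialect A [fusion_dialect()] for the call tables.
#' @return List: `calls`, `manifest`, `annotation`, `gene_expr` (NULL when
#'   absent), `genome` (NULL when absent).
#' @export
read_cohort_bundle <- function(dir, dialect = fusion_dialect()) {
  manifest <- read_manifest(file.path(dir, "manifest.tsv"))
  calls <- read_fusion_tables(file.path(dir, "calls"), dialect = dialect)
  annotation <- read_annotation(file.path(dir, "annotation.gtf"))
  expr_path <- file.path(dir, "gene_fpkm.tsv")
  gene_expr <- if (file.exists(expr_path)) {
    read_expression_matrix(expr_path, manifest)
  } else NULL
  fa <- file.path(dir, "genome.fa")
  genome <- if (file.exists(fa)) Biostrings::readDNAStringSet(fa) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))
  list(calls = calls, manifest = manifest, annotation = annotation,
       gene_expr = gene_expr, genome = genome)
}
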