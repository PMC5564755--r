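# Canonical per-call fields used throughout the package.
.fusion_call_columns <- c(
  "sample_id", "gene5", "gene3", "chrom5", "chrom3",
  "breakpoint5", "breakpoint3", "strand5", "strand3",
  "discordant_pairs", "split_reads", "multimap_spanning", "total_spanning",
  "probability"
)

.fusion_call_numeric <- c("breakpoint5", "breakpoint3", "discordant_pairs",
                          "split_reads", "multimap_spanning", "total_spanning",
                          "probability")

#' Column dialect for fusion-call tables
#'
#' Maps the columns of a caller's output TSV onto the canonical call fields.
#' Fusion callers rename columns between versions, so the mapping is
#' configuration, not code; the default targets deFuse 0.6.1-style headers.
#' Any entry can be overridden, e.g.
#' `fusion_dialect(gene5 = "gene_name_a")`.
#'
#' @param ... Named overrides `canonical_field = "file_column"`.
#' @param chrom_prefix How to normalize chromosome names: `"strip"`
#'   (default) removes a leading `"chr"`, `"add"` ensures one, `"keep"`
#'   leaves names untouched.
#' @return An object of class `fusion_dialect`.
#' @examples
#' fusion_dialect()
#' fusion_dialect(probability = "classifier_prob", chrom_prefix = "keep")
#' @export
fusion_dialect <- function(..., chrom_prefix = c("strip", "add", "keep")) {
  chrom_prefix <- match.arg(chrom_prefix)
  map <- list(
    gene5 = "gene_name1",
    gene3 = "gene_name2",
    chrom5 = "gene_chromosome1",
    chrom3 = "gene_chromosome2",
    breakpoint5 = "genomic_break_pos1",
    breakpoint3 = "genomic_break_pos2",
    strand5 = "genomic_strand1",
    strand3 = "genomic_strand2",
    discordant_pairs = "span_count",
    split_reads = "splitr_count",
    multimap_spanning = "span_count_multi",
    total_spanning = "span_count_total",
    probability = "probability"
  )
  overrides <- list(...)
  if (length(overrides) > 0) {
    bad <- setdiff(names(overrides), names(map))
    if (length(bad) > 0) {
      stop("unknown dialect field(s): ", paste(bad, collapse = ", "))
    }
    map[names(overrides)] <- overrides
  }
  structure(list(map = map, chrom_prefix = chrom_prefix), class = "fusion_dialect")
}

.normalize_chrom <- function(x, chrom_prefix) {
  x <- as.character(x)
  switch(chrom_prefix,
    strip = sub("^chr", "", x),
    add = ifelse(grepl("^chr", x), x, paste0("chr", x)),
    keep = x
  )
}

#' Read one sample's fusion-call table
#'
#' Parses a caller-output TSV into validated canonical calls. Rows whose
#' numeric fields fail coercion are rejected, never silently dropped: the
#' returned object carries a `rejected` attribute with row numbers and
#' reasons, and `count(in) = count(accepted) + count(rejected)`.
#' Invariant violations (negative counts, more multimapping than total
#' spanning reads, probability outside \[0, 1\]) are hard validation errors.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier to attach to every row (caller tables
#'   are per-sample and usually do not carry it).
#' @param dialect A [fusion_dialect()] mapping file columns to call fields.
#' @return A `fusion_calls` data frame (one row per accepted call) with
#'   attribute `rejected` (data frame of row/reason).
#' @export
read_fusion_table <- function(path, sample_id, dialect = fusion_dialect()) {
  if (!file.exists(path)) stop("fusion table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(unlist(dialect$map), names(raw))
  if (length(missing_cols) > 0) {
    stop("fusion table ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    return(fusion_calls(.empty_calls_df()))
  }
  df <- data.frame(sample_id = rep(as.character(sample_id), nrow(raw)),
                   stringsAsFactors = FALSE)
  for (field in names(dialect$map)) df[[field]] <- raw[[dialect$map[[field]]]]

  rejected <- data.frame(row = integer(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (field in .fusion_call_numeric) {
    coerced <- suppressWarnings(as.numeric(df[[field]]))
    bad <- which(is.na(coerced) | !is.finite(coerced))
    if (length(bad) > 0) {
      rejected <- rbind(rejected, data.frame(
        row = bad, reason = paste0("non-numeric ", field), stringsAsFactors = FALSE))
    }
    df[[field]] <- coerced
  }
  rejected <- rejected[!duplicated(rejected$row), , drop = FALSE]
  if (nrow(rejected) > 0) {
    rejected <- rejected[order(rejected$row), , drop = FALSE]
    df <- df[-rejected$row, , drop = FALSE]
  }
  df$chrom5 <- .normalize_chrom(df$chrom5, dialect$chrom_prefix)
  df$chrom3 <- .normalize_chrom(df$chrom3, dialect$chrom_prefix)
  out <- fusion_calls(df)
  attr(out, "rejected") <- rejected
  out
}

.empty_calls_df <- function() {
  df <- data.frame(matrix(nrow = 0, ncol = length(.fusion_call_columns)))
  names(df) <- .fusion_call_columns
  for (f in .fusion_call_numeric) df[[f]] <- numeric(0)
  df$sample_id <- character(0)
  df
}

#' Construct and validate a set of fusion calls
#'
#' Validates an in-memory data frame of canonical call fields (see
#' [read_fusion_table()] for the column set) against the call invariants:
#' nonnegative read counts, `multimap_spanning <= total_spanning`,
#' probability in \[0, 1\], strands in `+`/`-`.
#'
#' @param df Data frame with the canonical call columns.
#' @return The validated data frame with class `fusion_calls`.
#' @export
fusion_calls <- function(df) {
  missing_cols <- setdiff(.fusion_call_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("fusion calls lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    counts <- c("discordant_pairs", "split_reads", "multimap_spanning", "total_spanning")
    for (f in counts) {
      if (any(df[[f]] < 0)) stop("validation error: negative ", f)
    }
    if (any(df$multimap_spanning > df$total_spanning)) {
      stop("validation error: multimap_spanning exceeds total_spanning")
    }
    if (any(df$probability < 0 | df$probability > 1)) {
      stop("validation error: probability outside [0, 1]")
    }
    if (!all(df$strand5 %in% c("+", "-")) || !all(df$strand3 %in% c("+", "-"))) {
      stop("validation error: strands must be '+' or '-'")
    }
    if (any(df$breakpoint5 < 1) || any(df$breakpoint3 < 1)) {
      stop("validation error: breakpoints must be positive 1-based coordinates")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("fusion_calls", "data.frame")
  df
}

#' Read a directory of per-sample fusion-call tables
#'
#' Reads every `<sample_id>.tsv` under `dir` and binds the calls. Rejected
#' rows are accumulated (with the sample id) in the `rejected` attribute.
#'
#' @param dir Directory containing `<sample_id>.tsv` files.
#' @param dialect A [fusion_dialect()].
#' @return A `fusion_calls` data frame covering all samples.
#' @export
read_fusion_tables <- function(dir, dialect = fusion_dialect()) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .tsv fusion tables under ", dir)
  parts <- lapply(files, function(f) {
    read_fusion_table(f, sample_id = sub("\\.tsv$", "", basename(f)),
                      dialect = dialect)
  })
  rejected <- do.call(rbind, lapply(seq_along(parts), function(i) {
    r <- attr(parts[[i]], "rejected")
    if (is.null(r) || nrow(r) == 0) return(NULL)
    r$sample_id <- sub("\\.tsv$", "", basename(files[i]))
    r
  }))
  out <- fusion_calls(do.call(rbind, lapply(parts, as.data.frame)))
  attr(out, "rejected") <- if (is.null(rejected)) {
    data.frame(row = integer(0), reason = character(0), sample_id = character(0))
  } else rejected
  out
}
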