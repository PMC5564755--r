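---
title: "Nominating recurrent tumor-enriched fusion transcripts"
author: "fusionNominate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating recurrent tumor-enriched fusion transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusionNominate)
```

## The problem

RNA-seq fusion callers report thousands of chimeric-RNA candidates per
cohort, most of them stochastic events, alignment artifacts, or chimeras
equally common in benign tissue. In prostate cancer in particular, many
true fusion transcripts are not products of genomic rearrangement but of
transcription-induced mechanisms — above all RNA-polymerase read-through
(cis-SAGe) between same-strand neighboring genes. The analysis implemented
here takes per-sample fusion-call tables (a deFuse-style TSV dialect),
tumor/benign-matched cohort structure, and expression matrices, and
nominates the candidates that are recurrent, enriched and overexpressed in
tumors, annotating each for read-through geometry, splice-site
concordance, reading frame, and the expression signature that read-through
leaves on the 3' partner gene.

## The filter cascade

Calls first pass a per-call screen: at least 5 discordant (spanning) read
pairs, at least 1 junction split read, and caller classifier probability
at least 0.05 — all inclusive bounds. Screened calls are collapsed into a
gene-pair × sample detection matrix; a sample is positive for an ordered
(5', 3') pair if any passing call supports it, and the support retained is
that of the call with most split reads (so aggregation is idempotent).
Reciprocal orientations are distinct candidates: the same two genes fused
in opposite orientation are different transcription events.

Candidates then pass, in order:

1. **Recurrence** — detected in at least 5 tumor samples (inclusive).
2. **Enrichment** — one-sided Fisher exact test on the 2×2 table of
   tumor/benign positives, keep p < 0.05. The alternative is
   *greater in tumors*: enrichment of detection in tumors is the
   directional hypothesis the design asks about, and a two-sided test
   would double every p-value without changing the ranking.
3. **Overexpression gate** — only for candidates present in more than 2
   benign samples: a paired one-sided Wilcoxon signed-rank test of
   breakpoint expression (tumor vs matched benign RPKM), keep p < 0.05.
   Candidates rare in benign tissue skip this test (their `wilcoxon_p`
   is reported as unavailable).
4. **Multimapping ratio** — the ratio of multimapping to total spanning
   reads, *pooled over the candidate's positive samples*, must not exceed
   0.6; removal is strictly `> 0.6`, so a ratio of exactly 0.6 is kept.
   Pooling (rather than averaging per-sample ratios) was chosen because
   per-sample spanning totals are small and their ratios unstable; the
   boundary and the pooling rule each have a dedicated test.
5. **Biotype/overlap** — both partners must be protein-coding, lincRNA or
   miRNA genes (pseudogene biotypes always fail, whatever the allowed
   set), and the two gene spans must not overlap on the same chromosome
   (overlapping-gene "fusions" are usually annotation artifacts).

Every stage logs survivors before/after (the cascade log is monotonically
nonincreasing by construction) and every removed candidate carries exactly
one removal reason. No multiple-testing correction is applied anywhere in
the cascade; a Benjamini–Hochberg column is emitted in the report for
transparency but never used for filtering.

## Statistics

**Fisher enrichment.** `fisher_enrichment(a, b, c, d)` is the exact
hypergeometric upper tail P(X ≥ a) computed via `phyper`; tests verify it
against direct binomial-coefficient enumeration to 1e-12 and against
`fisher.test` for both tails. P-values are kept at full precision
internally and rounded to 2 significant figures in scientific notation
only in the report layer.

**Paired signed-rank.** Zero differences are dropped before ranking (the
classic convention rather than Pratt's; a config option would be easy but
the default matches common practice). With at most 25 nonzero pairs the
exact null is computed by convolution of the doubled ranks over the 2^n
sign assignments — doubling makes tied average ranks integral, so the
exact path covers ties, which `wilcox.test` abandons. Above 25 pairs a
normal approximation with tie correction and continuity correction is
used. Tests compare the exact path against full 2^n sign enumeration and
the approximate path against `wilcox.test`.

**Breakpoint RPKM.** Fusion expression is approximated by split reads per
kilobase of breakpoint region per million mapped reads. The breakpoint
"region" is `2 × read_length` (default 100 bp reads → 200 bp region): a
read can only be a split read if it overlaps the junction, so the window
of eligible read starts spans two read lengths. The choice affects only
the scale of RPKM values, never test ranks, because every candidate uses
the same region length. Undetected samples contribute 0 — treating absence
as zero expression, which is exactly what the downstream rank tests need.

**Differential normalization and clustering.** For candidate *i* and
matched pair *j*,
`value'_ij = (Texp_ij − Nexp_ij) / max_j |Texp_ij − Nexp_ij|`,
so each candidate's profile lies in [−1, 1] and attains |value| = 1 in
some pair unless it is identically zero. Profiles are clustered with
`1 − Pearson r` distance and average linkage (linkage is not dictated by
the method; average is the common default for correlation distances and is
configurable). Zero-variance profiles are excluded with a warning because
Pearson correlation is undefined for them.

**3'-partner association.** For each nominated candidate the cohort is
partitioned into fusion-positive tumors, fusion-negative tumors and benign
samples. The 3' partner's expression is contrasted positive-vs-negative
and positive-vs-benign with one-sided rank-sum tests (one-sided for
consistency with the cascade's directional hypotheses), and fusion
expression (breakpoint RPKM, 0 when undetected) is correlated with partner
expression by Spearman's rank test after `log2(x + 1)` — the pseudocount
because zeros are common in fusion-negative samples, Spearman because the
relationship is monotone, not linear, on expression scales. Correlation
p-values are two-sided (the default convention; a sign prediction is
already captured by rho's sign).

**Exon-level contrast.** The read-through signature is asymmetric: the
fusion adds transcription only downstream of the junction, so downstream
exons of the 3' partner should be higher in fusion-positive tumors while
the most-upstream exon (transcribed only from the wild-type promoter)
should not. `exon_contrast` labels exons relative to the junction
(strand-aware), normalizes counts by library size, and runs a per-exon
one-sided rank-sum test. This deliberately replaces a negative-binomial
differential-exon-usage model: the per-exon rank contrast is the same
logic as the confirmatory exon-level qRT-PCR design (exon upstream vs
downstream of the breakpoint) and needs no dispersion estimation; the cost
is less power at very low counts, which the tests acknowledge by planting
2-log2-unit couplings.

## The synthetic cohort

`generate_cohort()` produces every input the pipeline consumes — manifest,
per-sample call tables in the default dialect, GTF, contig sequences, gene
FPKM and exon count matrices — plus a truth table. Its defaults are the
study conditions the package is validated under: 44 matched tumor/benign
pairs plus 50 unpaired tumors; three planted enriched read-through
fusions with per-sample detection 0.6 in tumors and 0.02 in benign (the
detection profile of a strongly tumor-associated read-through; one
carries a 2-log2-unit 3'-partner expression coupling, one is
frame-compatible without coupling, one frame-incompatible); one homology
artifact with multimapping fraction 0.9 that the cascade must remove at
the multimap stage; and 200 background pairs detected at rate 0.05 in
both conditions. Detection is Bernoulli per sample (only marginal
detection rates are modeled), split reads are Poisson with at least one
read when detected, discordant pairs always satisfy the call screen, and
multimapping reads are Binomial(total, fraction).

The planted gene models are explicit: each planted pair lives on its own
short contig, the 5' gene contributes 400 coding bases (phase 1) through
its exon-2 donor, and the 3' gene carries 100 (compatible) or 101
(incompatible) coding bases upstream of its exon-2 acceptor. Contig
sequences carry stop-free codon runs over the CDS with a terminator right
after each ORF, so peptide translation is literal and the translated
length equals the arithmetic prediction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: expression covariance between genes, GC or
mappability bias, caller-specific error modes beyond the multimapping
fraction, subclonal detection rates, and genuine genomic rearrangements.
It validates the pipeline's logic and calibration, not caller accuracy.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive (GTF convention) everywhere, including
  breakpoints: the 5' breakpoint is the last base of the 5' segment, the
  3' breakpoint the first base of the 3' segment.
* A junction is "at splice sites" iff the 5' breakpoint equals an
  annotated exon 3'-end and the 3' breakpoint an annotated exon 5'-start,
  existentially over each gene's transcripts (partner genes need not agree
  on a single transcript).
* Frame prediction picks, among transcripts matching the junction, the
  pair maximizing total CDS length (canonical-like), breaking ties by
  transcript id. The junction is in frame iff the coding bases carried
  over from the 5' side are congruent mod 3 to the 3' transcript's coding
  bases upstream of the junction. Junctions not at splice sites are not in
  frame by definition; a junction in the 3' partner's 5' UTR is called in
  frame only when the CDS starts exactly at the breakpoint (any UTR gap
  would make frame continuation depend on unverifiable sequence); the 5'
  ORF must be genuinely truncated by the junction, otherwise translation
  would terminate at the native stop and yield no chimeric protein.
* Translation uses the standard nuclear code; no selenocysteine handling.
* A candidate with zero total spanning reads gets multimap ratio 0 with a
  warning (it cannot be removed by a filter whose evidence is absent).
* All-zero paired differences give p = 1 with a warning; constant vectors
  give undefined Spearman rho with a warning, never a silent NA.
* `alpha = 1` disables the two test-based filters, which gives the
  ablation/superset property its test handle.

## Calibration of the enrichment step

The one-sided Fisher exact test is conservative on discrete tables. For a
44 + 44 cohort the exact Type-I error at nominal alpha = 0.05, computed by
summing the hypergeometric tail over the Binomial(44, r)² null, is 0.0089
at detection rate r = 0.05 and rises only to 0.0347 at r = 0.5 — its
maximum over all rates, still below nominal. A calibration experiment that
expects the empirical rejection rate of 2,000 null pairs to fall in a
±3-standard-error band around 0.05 therefore cannot pass with this test at
this cohort size: the acceptance suite runs that experiment at the
background detection rate (0.05) and documents the shortfall rather than
substituting a less conservative statistic (e.g. mid-p), which would
change the method. Validity — the test never rejects *more* than nominal —
holds everywhere and is asserted. Note also that *conditionally* on
passing the recurrence filter the enrichment step can become
anticonservative at low detection rates (selection inflates the tumor
margin); the cascade inherits this two-stage character from its design,
and the planted/background separation in the synthetic cohort is wide
enough that it does not matter for nomination.

## Known limitations

* The multimapping filter sees only the counts the caller reports; it
  cannot detect homology artifacts whose spanning reads align uniquely.
* Distances between partners depend on the annotation release; they are
  reported but not meaningful across annotation versions.
* Domain retention is computed only against user-supplied protein-
  coordinate intervals; the package does not query domain databases.
* With a single benign cohort, "enrichment" and "tumor specificity" are
  not distinguishable from batch differences between the tumor and benign
  libraries; the paired overexpression gate mitigates but does not remove
  this.

## Problem sizes used in the test suite

Unit and property tests run on cohorts of 6–22 pairs with up to 40
background pairs; the end-to-end acceptance cohort uses the full default
conditions (44 pairs, 50 extra tumors, 204 gene pairs); calibration uses
2,000 simulated null pairs; oracle equivalence enumerates all 2×2 tables
with group sizes in {5, 10, 20} and all 2^n sign assignments for n ≤ 10.
These sizes were chosen so each check has the power it needs while the
whole suite stays interactive.
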