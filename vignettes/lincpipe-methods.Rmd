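---
title: "Identifying lincRNAs and their potential targets with lincpipe"
author: "lincpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying lincRNAs and their potential targets with lincpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincpipe)
```

## The problem

Long intergenic non-coding RNAs (lincRNAs) are transcripts longer than
200 nt with no protein-coding capacity that lie *between* protein-coding
genes. In livestock transcriptomics they are candidate regulators of
economically important traits — the motivating design here is a two-breed
pig comparison (a fat-type and a lean-type breed, three longissimus dorsi
muscle RNA-seq libraries each) where lincRNAs are screened for a role in
intramuscular fat (IMF) deposition. Identifying lincRNAs from an assembled
transcriptome is a filtering problem: most assembled transcripts are
fragments, coding isoforms, or noise, and a cascade of negative filters is
the field-standard way to isolate credible non-coding intergenic
transcripts.

`lincpipe` implements that cascade and the downstream association analyses
as a reusable, fully testable pipeline. Everything upstream of the merged
transcriptome (read QC, alignment, assembly) and every external scoring
tool (coding-potential calculators, domain and protein searches) is out of
scope: their outputs enter through a per-transcript *evidence table*, so
the pipeline is coordinate- and evidence-driven, with no sequence handling.

## The identification cascade

Candidates pass six stages in a fixed order; a transcript removed at stage
k is never seen by stage k+1, and the `filter_report` records every
removal with its stage:

1. **Intergenic** — the transcript span must share no genomic position
   with any reference *gene span* (strand-agnostic). Gene spans, not
   transcript spans, are used so that intronic and antisense candidates
   inside a gene locus are excluded; a lincRNA must lie between gene loci.
2. **Structure** — at least `min_exons = 2` exons and exonic length
   `>= 200` nt. Mono-exonic fragments are the classic assembly artifact
   this removes.
3. **Coding potential** — scores computed on *both* strands must be
   `< 0`. A configuration switch (`cpc_rule = "any"`) relaxes this to
   either strand; the default is "both" because a transcript coding on one
   strand is not non-coding, and the stated intent of the stage is to
   remove coding capacity wherever it appears.
4. **Domain homology** — no protein-domain hit with E-value `< 1e-5`
   (strict; a hit at exactly 1e-5 is not significant).
5. **Protein-database homology** — the same rule against any number of
   protein databases (one column per database in the evidence table).
6. **Expression** — FPKM `>= 0.5` in at least one sample; a transcript
   below the floor in *every* sample is discarded.

Missing evidence or a missing FPKM row for a candidate that survives the
intergenic stage is an error, never a silent pass: silent passes would
inflate the lincRNA set in exactly the cases where the evidence pipeline
upstream failed.

Retained lincRNAs are split into **known** and **novel** by exonic-
coordinate overlap with a lincRNA database annotation: a candidate is
known when some database transcript shares at least `min_overlap_fraction`
(default 0.5) of the candidate's exonic length. This replaces a sequence
search (the usual tool is blastn) with a deterministic, database-version-
independent rule; no identity/coverage thresholds for a sequence search
were available to copy, so the overlap fraction is an explicit, configured
choice.

## Differential expression

The DE decision rule is |log2FC| > 1 together with a BH-adjusted p < 0.05,
applied to both lincRNAs and protein-coding genes. The engine behind the
rule is deliberately transparent rather than a negative-binomial GLM:

* size factors are `library size / median library size` — a deterministic
  normalization that is exact under pure library-size scaling;
* `log2FC = log2((mean_A + 1) / (mean_B + 1))` on normalized group means
  (pseudocount 1 stabilizes the estimate at zero counts);
* p-values come from a two-sided Welch unequal-variance test on
  `log2(normalized + 1)`, BH-adjusted over all tested features; features
  with zero counts everywhere are excluded from the family.

The engine is labelled in every output (`engine: welch-log2-normalized`)
and isolated behind `test_differential_expression()`, so a shrinkage-based
engine can be swapped in without touching the decision rule or any
downstream stage. Two numerical corner cases are fixed deterministically:
when both group variances are exactly zero the p-value is 1 for equal
means and 0 otherwise (with continuous-ish counts this event has
vanishing probability), and the Welch degrees of freedom follow the
Welch–Satterthwaite formula per feature. With three samples per group this
test is honest but low-powered; at the generator's default noise level
(dispersion 0.05) pooled sensitivity for |log2FC| = 3 is around 0.85, and
reaches 0.93–0.97 under a low-dispersion condition (0.01). Interpretation
of any real 3 vs 3 comparison should expect similar power limits.

## QTL co-localization

Differentially expressed lincRNAs are intersected with QTL intervals
(read from BED, converted to the package's 1-based inclusive convention
at the boundary; a BED interval `2000 3000` becomes `2001..3000`, so a
locus ending at 2000 does not overlap it). Trait names are classified by
configurable keyword lists — IMF keywords first, then other fat-deposition
keywords, else non-fat. The defaults
(`imf = ["intramuscular fat", "imf"]`,
`fat = ["fat", "backfat", "leaf fat"]`) are declared configuration, not a
claim about any database's trait ontology. Overlaps are counted per
(lincRNA, QTL) pair, so a QTL hit by two lincRNAs counts twice in the
total; `dedupe_qtls = TRUE` gives the alternative (each QTL once,
attributed to its largest overlap). Summary percentages (fat-of-total,
IMF-of-fat) are kept at full precision internally and printed at one
decimal.

## Cis and trans target prediction

Two disjoint modes, both based on Pearson correlation across *all* samples
(n = 6 in the reference design, giving the exact two-sided t test with
df = 4):

* **cis** — protein-coding genes on the same chromosome whose span lies
  within a strict boundary gap of 100 kb of the lincRNA span (gap 0 when
  the spans overlap, else the number of bases strictly between). Every
  neighbour pair is reported with r, p and a BH-adjusted value over the
  cis family; *no correlation cutoff is applied* — physical adjacency is
  the cis hypothesis, and weakly correlated neighbours are still
  reportable results.
* **trans** — every remaining (DE lincRNA, gene) pair is tested;
  cis-eligible genes are excluded so the two families stay disjoint. A
  pair becomes a trans edge exactly when `|r| >= 0.95` (inclusive) and
  its BH-adjusted p over the full tested family is `< 0.05` (strict).
  Constant expression vectors have no defined correlation; such pairs are
  reported with `r = NA` and excluded from the FDR family rather than
  being assigned an arbitrary value.

Edges carry a sign (positive/negative correlation), which is also the
definition of "upregulates"/"downregulates" in the exported network and
in the per-lincRNA DEPTG tallies (targets that are themselves DE, split
into up and down; up + down = total always holds). Networks are exported
as SIF plus edge/node attribute tables for graph tools.

## The synthetic-data generator

`generate_dataset()` emulates the reference study design — two groups of
three samples — and plants ground truth for every stage: true lincRNAs
(default 18 known + 12 novel), two decoys per filter stage failing exactly
that stage, planted DE lincRNAs and coding genes at |log2FC| = 3, cis
neighbour pairs within the 100 kb window, trans pairs, and QTL intervals
over every DE lincRNA plus background intervals that overlap no lincRNA.
Counts are negative-binomial (mean–dispersion parameterization, the
standard bulk RNA-seq noise model; no noise model was given to copy, so
this is the generator's declared assumption) with dispersion 0.05 by
default.

Two design choices deserve emphasis:

* **Exact sample correlations.** At n = 6 the trans threshold
  |r| ≥ 0.95 leaves almost no room for sampling noise: a pair planted "in
  expectation" at r = 0.95 would be recovered roughly half the time. The
  FPKM matrix is therefore built from coordinates in an orthonormal basis
  of the centered sample space: trans-planted lincRNAs get single basis
  directions, cis lincRNAs unit vectors in a reserved two-dimensional
  plane, planted partners exact mixtures (giving *exact* sample
  correlations of ±0.99 for trans and the configured values for cis), and
  every unplanted feature a mixture whose per-direction loadings are
  bounded so that no unplanted pair can reach |r| = 0.95. Planted-truth
  recovery is therefore structural, not a matter of seed luck — which is
  what makes "recovered edge set equals planted set" a meaningful test.
* **Counts and FPKM are generated separately.** The count matrix carries
  the planted fold changes (for the DE stage); the FPKM matrix carries the
  planted correlation geometry (for the target stages). They describe the
  same features consistently in direction but are not numerically linked
  through `fpkm_from_counts()`, which is tested separately against its
  algebraic definition.

What the generator does *not* emulate: read-level noise, alignment and
assembly artifacts, batch effects, length biases in FPKM, or realistic
linkage structure among QTLs. Passing the recovery tests therefore shows
the pipeline's logic is correct under its stated rules — it does not show
that those rules are well-calibrated for any particular real dataset.

## Numerical and policy choices

* Internal coordinates are 1-based inclusive everywhere; BED conversion
  happens only at I/O. Unstranded (`*`) transcripts match either strand
  in overlap operations; all locus-overlap logic is strand-agnostic.
* Statistical primitives are thin validated wrappers over R's own
  `cor`, `pt`, `p.adjust(method = "BH")` and `phyper`; correlations are
  clamped to [−1, 1] against rounding, and `|r| = 1` maps to p = 0.
  Two-sided tests throughout — the worked six-sample examples in the test
  suite confirm two-sided p-values to their printed precision, including
  the significant negative-correlation pair.
* BH ties need no special casing: the cumulative-minimum formulation
  handles them.
* The Fisher enrichment helper uses the one-sided hypergeometric upper
  tail with a Haldane 0.5 correction on the odds ratio when a table cell
  is zero; it is exhaustively checked against explicit combination sums
  for universes up to 30 genes.
* Problem sizes in the test suite are chosen for density of coverage, not
  realism: oracle equivalence runs on ~1,000 random intervals per
  property, FDR control on 200 replicates of 2,000 features, recovery on
  the default bundle (~42 candidates, 120 genes). These sizes exercise
  every code path while keeping the whole suite under a minute.

## Known limitations

* The Welch engine does not share dispersion information across features;
  for real 3 vs 3 data a shrinkage-based engine will be more powerful.
  The package's architecture anticipates swapping one in.
* Known/novel status by coordinate overlap cannot recognise a database
  lincRNA that moved between assembly versions; a sequence-based check
  would.
* Per-pair Pearson correlation at n = 6 makes the trans edge list very
  sensitive to single samples; the 0.95 cutoff controls this only partly.
  Edge lists should be read as hypotheses, not validated regulation.
* QTL co-localization is positional association only; no enrichment test
  is attached because interval overlap counts have complex nulls that raw
  tallies do not address.
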