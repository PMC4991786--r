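---
title: "Quantifying co-transcriptional splicing and Pol II elongation defects"
author: "nascentr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying co-transcriptional splicing and Pol II elongation defects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nascentr)
```

## Scope and model

`nascentr` quantifies two molecular signatures of a broken coupling between
RNA polymerase II and co-transcriptional RNA processing, as they appear in
genomic coverage data from a knockdown-versus-control comparison:

* a **splicing defect**: unspliced signal (cis-introns, and the 5′ outrons
  that trans-splicing normally removes at the SL1 acceptor) persists while
  mature exonic signal falls, raising the per-gene pre-mRNA/mRNA ratio;
* an **elongation defect**: the polymerase's occupancy along gene bodies
  loses its normal 3′ bias.

The package deliberately consumes, rather than produces, upstream results:
read mapping, transcript assembly, differential-expression (DE) calling and
peak calling are external, and their tabular/interval outputs are the input
contracts (GTF/GFF3, bedGraph, BED/broadPeak, DE tables, Ct tables).

## Feature derivation

Annotations are parsed into per-gene models. Transcript isoforms are
collapsed to the union of their exons before introns are derived as the gaps
between consecutive exons; this makes "introns = gaps" an invariant and
counts each feature once per gene. A per-transcript mode
(`collapse_transcripts = FALSE`) is kept because published feature counts do
not always state which convention was used; both modes are first-class.

Internally all coordinates live in `GRanges` (1-based, closed), the standard
container in R genomics; BED and bedGraph conversion happens only at file
boundaries. Exons and introns shorter than `min_length` (default 50 bp) are
excluded from coverage averaging: below about half a read length the mean
coverage of a feature is dominated by reads of its neighbours. Outrons are
never length-filtered — they are located from experimentally defined TSSs
(e.g. GRO-seq), supplied as a BED override, since standard annotations do
not record them.

## Coverage, masking and scaling

Tracks are per-base signal (`Rle` per chromosome). Between-sample comparison
of ChIP signal requires removing the dominant peak regions before computing
a scaling factor, otherwise condition-dependent peak strength leaks into the
genome-wide normalization. `mask_and_scale()` therefore:

1. takes the union of peak intervals from all replicates of both conditions
   as the mask (the conservative reading when replicate-level detail is not
   specified);
2. converts unmasked base coverage to read-equivalents by dividing by the
   nominal read length (default 100 bp);
3. multiplies the whole track by `target / unmasked_total`. Masked bases
   keep their scaled values for inspection but stay excluded from totals.

Defaults are 2 × 10⁶ read-equivalents for ChIP and 10⁷ for RNA. Scaling is
linear, so rescaling to a new target is exactly equivalent to scaling once.

Per-gene feature means are length-weighted (pooled bases across a gene's
retained exons, then divided by pooled length), not per-feature averages —
the flag-free behaviour matches averaging read coverage over a feature
class within a gene. Log2 displays use a pseudocount of 1, chosen because
intronic coverage is sparse and zero-valued features must stay finite.

## Pre-mRNA/mRNA ratios

From coverage, the pre-mRNA proxy is the mean intron (or outron) coverage;
junction-spanning evidence is out of reach of a coverage track and belongs
to the qPCR design, where amplicons target outrons, introns or intron-exon
junctions versus spliced exon-exon junctions. The per-gene ratio change
(treatment ratio / control ratio) is scale-invariant, so it is unaffected
by the global scaling step.

ΔΔCt quantification averages technical replicates on the Ct scale, then
normalizes each target to the reference RNA (default 18S) within each
sample — which cancels per-sample plate offsets exactly — and compares
condition means to the control condition (default the empty-vector RNAi
label L4440). The relative level is 2^−ΔΔCt; the standard deviation across
biological samples of the per-sample relative levels is reported, and no
amplification-efficiency correction is applied. Undetected wells are encoded
as missing Ct, not as a ceiling cycle: a gene whose pre-mRNA never amplifies
(the expected pattern for maternally deposited, already spliced transcripts)
gets ratio 0 with an `undetected` flag rather than a fabricated number.

## Metagene profiles and the travelling ratio

Genes are aligned at their TSS or TES and mean signal is taken in 50 bp
windows from −1 kb to +1 kb, in transcript orientation (minus-strand genes
flipped). Profiles are anchored, not length-rescaled: windows past a short
gene's opposite end read real track signal, and genes are not filtered by
length. Windows running past a chromosome end are dropped for that gene
only, decrementing that window's n.

The confidence interval is the 95% CI of the mean across genes,
`1.96 · sd/√n` per window (normal approximation); with one contributing gene
the half-width is reported as 0. Replicates are profiled separately and
combined as the mean of window means.

The elongation summary is the travelling ratio: mean of the TES-panel
gene-body windows (offsets < 0) over the mean of the TSS-panel gene-body
windows (offsets ≥ 0). It is scale-free, so it can be compared across
conditions regardless of normalization; the ratio of ratios between
conditions is the single number summarizing 3′ depletion.

## Bound genes and enrichment

A gene is called bound when its annotated body (introns included, outron
excluded) overlaps at least one peak — by ≥ 1 bp, with no fractional
threshold — in each of the two replicates of a condition. Peak significance
filtering is the caller's job; an optional score filter is provided.

DE sets are `q ≤ 0.05` and `|log2FC| ≥ 1` (boundary rows are counted and
reported, since published thresholds are sometimes quoted with strict and
sometimes with non-strict inequalities). The test universe is the DE table's
gene list — the genes with sufficient read representation — not the whole
annotation. Class membership is set algebra over published tissue-expression
source lists (roles: germline, neuronal, muscle, gut, somatic-any,
germline-enriched source, strict-maternal, strict-embryonic, chrX, silent,
spermatogenesis); the catalog treats them as inputs, not as computations to
reproduce. Enrichment and depletion are one-sided hypergeometric tails, both
including the point mass `P(X = k)`, computed via `stats::phyper` and
cross-checked in the tests against exhaustive enumeration of all draws for
every universe of size ≤ 12. Raw tiers (`*` ≤ 0.01, `**` ≤ 1e−5, `***` ≤
1e−10) are reported without multiple-testing correction, matching the
display convention of the analysis this package operationalizes.

## The simulator: what it emulates, and what it does not

`simulate_genome()` builds an operon-containing toy genome (default 200
genes, bodies 2.5–6 kb, 2–7 exons) with:

* outrons on a trans-spliced fraction (default 0.70, the reported fraction
  of trans-spliced *C. elegans* mRNAs), abutting the annotated gene start;
* per-class transcription levels and programmed DE status, with
  down-regulation concentrated in zygotically expressed classes and
  up-regulation in germline classes, sharply enough that the programmed
  enrichment is statistically visible at the default cohort size;
* an intron-retention factor per condition (control 1, treatment 3): exon
  coverage tracks the condition's transcription level while intron and
  outron coverage tracks the *control* level times the retention factor —
  unspliced transcripts persist while mature output falls, so for a
  transcriptionally stable gene the measured ratio change equals the
  retention factor, and for a gene at level fraction f it equals r/f;
* a per-condition polymerase 3′/5′ gradient (control 1.5, treatment 0.8),
  realized as a per-gene linear ramp calibrated so that the mean over the
  terminal kilobase divided by the mean over the first kilobase equals the
  programmed ratio exactly — which makes the metagene travelling ratio an
  unbiased estimator of it;
* promoter-proximal peak calls per replicate with positional jitter, so the
  bound-gene rule recovers the expressed gene set;
* Poisson noise per 10 bp tile (per-base Poisson noise would understate the
  autocorrelation of real coverage; 10 bp is a compromise at typical read
  lengths);
* Ct values as `offset − log2(abundance · sample_scale) + N(0, 0.1)`, where
  the per-sample scale exercises the plate-offset invariance of ΔΔCt.

It does **not** emulate mappability artefacts, GC bias, multi-mapping,
spliced-alignment edge effects, amplification-efficiency differences, or
isoform complexity. Tests passing on simulated data therefore demonstrate
the correctness of the estimators under the stated generative model, not
robustness to those real-data complications.

Gene placement leaves ≥ 2.6 kb between bodies so that metagene flanks and
outrons do not bleed into neighbours; intergenic background is zero. All
outputs are byte-identical given a seed: every stochastic step draws from a
sub-seed derived from the master seed and a purpose label, so stages can be
re-run independently without disturbing each other's streams.

## Problem sizes and numerical choices

Defaults were chosen so that a full simulated analysis — genome, two RNA
and four ChIP tracks, peaks, DE table, Ct table, and the complete pipeline —
runs in well under a minute: 200 genes on 3 chromosomes (~1.4 Mb), exon
coverage ~20× per unit expression level. At these depths the median
recovered retention factor and the travelling ratios sit within a few
percent of their programmed values; the test suite asserts 10%.

Degenerate inputs are defined, not special-cased: an empty gene collection
yields an empty catalog with zero counts; a zero-depth track is all zeros;
scaling a track with zero unmasked signal is an error (undefined), as is a
hypergeometric count outside its support; a single-gene metagene reports
zero CI width; undetected qPCR targets propagate as flagged zeros.

## Known limitations

* Coverage-based pre-mRNA proxies cannot separate retained introns from
  overlapping transcription units; operon membership is carried as an
  annotation attribute for reporting, but no operon-aware correction is
  applied (read-through past the TES of upstream operon members will
  inflate 3′ flanks of metagene panels on real data).
* The travelling-ratio CI treats window means as independent across windows,
  which understates correlation along the gene body; it is a display aid,
  and the tests therefore also bound the absolute recovery error.
* BAM input is out of scope; read intervals (BED) or coverage (bedGraph)
  are the contract.
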