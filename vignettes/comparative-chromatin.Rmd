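---
title: "Comparing expression-coupled histone marks within and between yeast species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing expression-coupled histone marks within and between yeast species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chromdiverge)
```

## The scientific question

H3K9 acetylation and H3K4 tri-methylation both track active transcription in
budding yeast, but they occupy different positions along a gene — H3K9ac
concentrates at the +1 (TSS) nucleosome, while H3K4me3 forms a broader
plateau over the +2/+3 nucleosomes — and need not be deployed equally at
every gene. `chromdiverge` implements a complete comparative analysis of the
two marks: per-gene profiles and nucleosome-level signals, a disparity
statistic that ranks genes by their acetylation-to-methylation balance with
gene-class enrichment tests, and an interspecies analysis (*S. cerevisiae*
vs *S. paradoxus* style) that asks which mark's divergence at orthologous
genes tracks expression divergence.

## From reads to tracks

The input unit is a stranded aligned-read position: chromosome, first
sequenced base (0-based), strand. Reverse-strand alignments score their last
interval base (`REV_READ_POS_OFFSET`), since that is the first sequenced
base of a reverse read.

The average sonication fragment length of each sample is estimated from the
data: separate forward and reverse first-base profiles are built, the reverse
profile is slid one base at a time over `[0, 400]` bp, and the shift
maximizing the rank correlation between strands is taken as the fragment
length. Two numerical choices matter here:

* *Correlation flavour.* The default is Spearman, computed as Pearson on
  globally mid-ranked profiles over the fixed overlap window
  `[0, L - max_shift)`. Re-ranking the overlap window separately at each of
  401 shifts would change nothing material while costing an extra
  `O(shifts x L log L)`; the cross-products across all shifts are evaluated
  in a single FFT pass, which is exact to machine precision. Pearson on the
  raw counts is available via `method = "pearson"`.
* *Tie-break.* Ties in the scan resolve to the smaller shift, making the
  estimate deterministic.

The two strand profiles are then shifted towards each other by half the
offset (forward gets `floor(offset/2)`, reverse the remainder — the split is
documented and tie-stable) and summed; signal pushed past a chromosome edge
is dropped and counted in the track's `edge_dropped` field, so read mass is
always accounted for. All samples are scaled to the lowest library total, so
every downstream value is comparable across samples.

## Log scale, pseudocount and H3 normalization

All gene-level summaries are log2-transformed means. A merged track is a
*midpoint density*: at realistic depth (~1000 reads per gene) the per-base
values in even the strongest regions are of order 1. The pseudocount added
before the log is therefore consequential: a pseudocount comparable to the
signal compresses the log scale and suppresses genuine between-sample
differences, most severely at weakly covered regions — exactly the regions
(e.g. promoter H3K4me3) where divergence is largest. The default pseudocount
is 0.1, small relative to typical peak densities; it is an explicit argument
of every function that logs signal, and genes whose region has zero coverage
are flagged invalid rather than silently assigned `log2(pseudocount)` —
the analysis-wide exclusion that removes mostly short or silent genes.

Nucleosome occupancy is controlled for with an H3 track: H3 is smoothed with
a centered 140-base moving window (even windows are widened by one base to
center them; edge windows truncate), log2-transformed, and subtracted from
the log2 modification signal, either per binned position or at region level.
Whether smoothing should happen on the linear or log scale is genuinely
open; the package smooths the log2 track by default and exposes the order of
operations through the individual functions (`log2_track`, `smooth_track`),
so either order is two calls.

## Profiles, regions and the disparity statistic

Gene-anchored matrices use 20-bp bins over TSS (-500..+900) and TTS
(-400..+200) windows, laid out along the direction of transcription; bins
that extend beyond a chromosome are masked rather than truncated, to avoid
biased means. Given a linear track, a bin is `log2(mean + pseudocount)`; a
log2 track contributes its mean directly (the mode is recorded on the
matrix).

Named regions are fixed constants on the same 20-bp grid: `prom`
(TSS -320..-160), `peak_ac` (TSS 0..+140), `peak_me` (TSS +100..+580),
`end` (TTS -260..+60), `orf_broad` (TSS -60..+580) and `peak_ac_h3norm`
(TSS -60..+140). A region mean is the average of its bin values; because the
regions sit on the bin grid, region means are exactly consistent with the
profile matrices (this identity is tested). A gene is invalid for a region
when the region leaves the chromosome, extends past the gene body
(TSS-anchored regions require `length >= end`), or has zero coverage.

The disparity statistic is `ratio = log2(H3K9ac / H3K4me3)` from the two
peak-region means, computed only for genes at least 700 bp long (methylation
occupies several proximal-ORF nucleosomes, so very short genes cannot be
compared fairly). Ranked genes are split into three 1200-gene sectors:
`high_ac` (top), `high_me` (bottom), and `mid`. The placement of the middle
sector is not uniquely defined by "intermediately ranked"; the package
centers it on the median rank, with ties broken by gene id so the partition
is order-invariant. Class enrichment in each sector uses the one-sided
hypergeometric test (enrichment `P[X >= k]`, depletion `P[X <= k]`), with
fold enrichment reported as percent deviation from the expected overlap
`nK/N`. Raw p-values are reported: the analysis applies no multiple-testing
correction, displaying significance as `-log10 p`.

## Interspecies divergence

Orthologous genes are paired through a one-to-one map; all differences are
oriented species A minus species B and computed only for pairs valid in both
species. The analyses are:

* per-bin and overall Pearson correlation of ortholog-paired profile
  matrices;
* exceedance curves — percent of genes with `|d|` above a threshold grid
  (0..2 log2, step 0.1);
* Lowess-residual extraction of the most divergent genes per mark (span 0.3,
  2 robustness iterations, residuals `y - fit(x)`; exact `n_per_side` sets
  with id tie-break);
* change classification at a 0.4 log2 (~1.3-fold) threshold into
  none / only-first / only-second / consistent / opposite;
* threshold-gated correlation and sign-consistency curves of each mark's
  divergence against expression divergence, and the fold enrichment of the
  1000 most expression-divergent over the 1000 least divergent genes across
  modification thresholds;
* a three-way classification (H3K9ac, H3K4me3, expression): `none`,
  `all_consistent`, the three "pair consistent, third not" categories, and a
  residual `other` — the five displayed categories do not exhaust the sign
  combinations, so the residual class keeps the labels a partition.

## What the synthetic generator emulates

No reference dataset ships with the package; instead, a first-class
generator produces data whose defaults *are* the study conditions used by
the tests and the acceptance script:

* ~4 kb gene slots on 4 chromosomes, 2000 genes, gene lengths uniform
  500–2800 bp, random strands; nucleosomes -2..+6 tiled at 165 bp from the
  TSS with 147 bp cores (a consensus nucleosome map is consumed as input in
  a real analysis; the synthetic map is regular by construction);
* log2-normal expression (mean 3, sd 1.5) and positional mark shapes:
  H3K9ac maximal at +1 (with a -1 shoulder at 30% of genes), H3K4me3
  plateauing over +2/+3 and decaying downstream, H3 occupancy dipping at the
  promoter. H3K9ac and H3K4me3 intensities scale with `2^expression`; H3
  does not, because it is the occupancy control — scaling it with expression
  would make H3 normalization subtract the expression coupling away, which
  contradicts how occupancy-corrected profiles behave;
* per-(gene, nucleosome) log2 jitter (sd 0.5) shared between species at
  orthologs, so interspecies differences come only from the planted
  divergence model;
* planted disparity: +0.5 log2 H3K9ac at OPN genes and +0.5 log2 H3K4me3 at
  DPN genes, in both species;
* divergence model: ortholog expression shifts ~ Normal(0, 0.6 log2); the
  shift propagates into H3K4me3 with weight 0.8 and into H3K9ac with weight
  0.1, on top of independent per-gene modification shifts (sd 0.55 for
  H3K9ac, 0.35 for H3K4me3, chosen so each mark's measured divergence
  marginal is comparable, with acetylation changes slightly more prevalent);
* single-end reads: fragment midpoints sampled proportional to nucleosome
  intensity, uniform within the nucleosome, constant fragment length (150 bp
  default), one read per fragment at either fragment end with probability
  0.5; Poisson RNA-seq counts (`length x 2^expression`, two replicates) and
  a 200-condition expression compendium with planted SDs (2.0 responsive,
  0.2 non-responsive);
* sequencing depth defaults to 2e6 reads per ChIP sample, i.e. ~1000 reads
  per gene, proportional to the ~6.5M-read libraries over ~6000 genes that
  motivated the analysis.

The generator deliberately omits several features of real data: sequence
content (no mappability or GC bias), fragment-length dispersion,
overdispersed counts, irregular nucleosome spacing, antibody efficiency
differences, and correlated class structure (TATA status is drawn
independently of OPN/DPN, whereas real promoter classes overlap). Passing
tests therefore demonstrate that the estimators recover planted structure
through a realistic sampling model — not that any biological claim holds in
real yeasts.

## Problem sizes and determinism

The test-suite and acceptance runs use deliberately compact instances: 2000
genes x 1M reads for profile-shape checks, 4000 genes x 2M reads for the
disparity-recovery check, 3334 genes (~3000 ortholog pairs) x 2M reads per
sample for the divergence-coupling contrast, and a 400-gene end-to-end
determinism check. Every random step is a pure function of an integer seed
carried in the config; two runs with the same config are byte-identical.

## Known limitations

* The fragment-length estimator assumes a single characteristic fragment
  size; bimodal sonication profiles would return one of the modes.
* Lowess extraction is not symmetric under swapping the species axes (the
  regression direction changes); the package fixes `y ~ x` with x = species
  A and documents the orientation.
* With very shallow coverage the pseudocount still compresses differences;
  the measured divergence SD is smaller than the planted one, an effect
  shared with any log-of-mean estimator at low counts.
* Hypergeometric enrichment treats gene classes as fixed sets; no
  multiple-testing correction is applied, matching the display convention of
  the analysis it implements.
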