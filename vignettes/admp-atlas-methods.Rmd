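---
title: "Calling tissue-specific age-related DNA methylation changes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling tissue-specific age-related DNA methylation changes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admpatlas)
```

## The problem

DNA methylation at individual CpG sites drifts with chronological age. On
Illumina 450k-style arrays this is measured as a *beta value*, the
methylated fraction in [0, 1]. A CpG whose methylation changes linearly
with age past both an effect-size and a significance cut-off is an
*age-related differentially methylated position* (aDMP): a gain-aDMP if the
slope is positive, a loss-aDMP if negative. The question this package
addresses is whether such positions recur across tissues or are private to
one tissue, and whether the *kind* of genomic region involved (CpG islands,
polycomb-bound chromatin, enhancers) is nevertheless shared.

## The per-probe model

For each probe $j$ in one tissue, the package fits ordinary least squares

$$\beta_{ij} = \alpha_j + b_j \, \mathrm{age}_i + \gamma_j^T z_i + \varepsilon_{ij},$$

with age in years, untransformed, and $z_i$ the tissue's covariates (sex as
0/1, study batch as reference-coded indicators, cell fractions as given
with one column dropped when they form a simplex). The slope $b_j$ is
reported both per year (beta units) and as percent per decade
($1000 \times b_j$ exactly). Two-sided P values come from the t
distribution with $n_j - k$ degrees of freedom, where $n_j$ counts the
samples with a non-missing beta at probe $j$ (complete-case per probe) and
$k$ the model columns. P values are Bonferroni-adjusted over $m$, the
number of probes actually tested in that tissue.

A probe is called under the **dual criterion**:

* $|b_j| \geq$ 2% per 10 years (slope threshold, configurable), and
* $P_{\mathrm{bonf}} \leq 0.05$.

Both comparisons are inclusive; `strict_inequality = TRUE` switches to
strict. The inclusive reading is applied with a $10^{-9}$ numerical
tolerance so a slope that equals the threshold up to floating point rounds
the right way. Two power controls are built in: `effect_only` mode drops
the significance condition entirely, and `subsample_equal_n()` re-draws
every tissue down to a common sample count (96 by default in the worked
analyses, the smallest real cohort) before re-calling, removing
between-tissue power differences.

Degenerate fits follow fixed conventions: zero residual variance reports
`se = 0` and `p = 0` (or `p = 1` when the slope is also exactly zero, the
constant-response case); probes retaining fewer than $k + 2$ samples are
*untested* and excluded from the Bonferroni family $m$; a rank-deficient
global design is an error naming the collinear column rather than a silent
drop.

## Specificity measures

Gain and loss are tabulated separately throughout (a probe gaining in one
tissue and losing in another enters both tables and is flagged
discordant). For a direction, `build_specificity()` maps every called
probe to the set of tissues it was called in; `percent_tissue_specific()`
is the share with exactly one tissue, reported half-up to one decimal.
`overlap_matrix()` gives pairwise intersections with a diagonal counting
probes unique against *all* other tissues (not merely pairwise), which
matches how per-tissue uniqueness is usually displayed. Probes untested in
a tissue count as "not called" there for specificity, but are excluded
from the denominators of `cross_tissue_significance()`, which asks whether
an aDMP shows a same-sign association at a relaxed raw threshold
($P < 0.001$, strict) in the tissues where it was *not* called — the
robustness check that weak shared effects would reveal.

Region-level specificity aggregates probes to CpG islands or nearest
genes: a region's tissue set is the **union** of its member probes' sets,
so region-level sharing can only grow — the invariant asserted in the
tests is that a region's tissue count is at least the maximum over its
member probes, not that region-level uniqueness is bounded by probe-level
uniqueness.

## Annotation and enrichment

Coordinates follow the field's conventions: BED inputs are 0-based
half-open, probe manifest positions 1-based, all internal arithmetic
half-open. CGI classes partition probes into island / shore / non-CGI,
with shores the 2-kb flanks (inclusive at exactly 2000 bp from the island
edge). Chromatin states use the fixed 15-label Roadmap vocabulary; a probe
at an interval boundary belongs to the interval beginning there. The EZH2
track is a single pooled binding track: a probe is EZH2-positive if it
overlaps any interval. Nearest genes minimise the distance to either gene
end (5′ or 3′, strand-aware; a probe inside a gene body is still measured
to the nearer end), with ties broken by distance then lexicographic gene
id so results are deterministic.

Enrichment of an aDMP set in an annotation category is the odds ratio of
the 2×2 table aDMP-status × category over the **tested-probe background of
that tissue** — the standard EWAS choice; both directions' aDMPs remain in
the background. Significance is the 1-df Pearson chi-squared without
continuity correction; the Haldane–Anscombe +0.5 is applied to all cells
only when some cell is zero, and only for the odds ratio (the chi-squared
keeps the raw counts). Within a 15-state profile the significance flag is
Bonferroni-corrected over 15 tests; raw P is always reported. Empty or
universal categories are flagged degenerate rather than forced to a
number.

## The synthetic-data generator

The simulator exists so that every downstream claim can be checked against
planted truth. It emulates the structure of a seven-tissue 450k
compendium:

* **Genome** — probes on a few chromosomes with strictly increasing
  positions (mean spacing 3 kb, minimum 60 bp); CpG islands planted as
  runs of 2–8 neighbouring probes until exactly the target fraction
  (default 0.30) of probes is inside an island, mirroring the array's CGI
  bias; an EZH2 track with odds-tilted binding at CGI probes (default
  odds 4 over a 0.15 base rate); per-tissue 15-state segmentations that
  tile each chromosome (every probe covered exactly once), with
  Quies/TxWk-heavy state frequencies; gene models with strand.
* **Effects** — configurable numbers of gain and loss effects with slope
  magnitudes uniform in 3–8 %/10yr by default and sharing classes
  (tissue-specific / k-shared / universal) realized *exactly* by
  largest-remainder rounding; the universal gain class stands in for the
  handful of CpGs known to track age in every tissue. Placement is
  weighted sampling without replacement: gain effects prefer CGI∩EZH2
  probes with odds 5, loss effects prefer enhancer-state non-CGI probes of
  their home tissue — so the enrichment stages have a known odds ratio to
  recover. Because the draws are sequential without replacement, the
  realized placement odds ratio sits slightly off the nominal odds for
  large draws from small pools; the recovery tests assert interval
  coverage rather than exact equality for this reason.
* **Cohorts** — the default design reproduces the real compendium's
  shape: brain 380 (ages 0–97), buccal 96 (1–28), liver 147 (15–86, three
  study batches), kidney 171 (15–86), subcutaneous fat 648 (39–85, females
  only), monocytes 1202 (44–83) and T-helper cells 214 (45–79), the last
  two with residual cell-fraction covariates. Ages are uniform within each
  range: real cohorts are not uniform, but uniformity maximises design
  clarity for recovery tests. Betas are
  `clip(baseline + slope*age + covariate terms + N(0, sd), [0, 1])` with
  baselines drawn per CGI class (islands 0.10–0.30, shores 0.20–0.60,
  non-CGI 0.50–0.90), additive Gaussian noise on the beta scale (a
  logit-normal option exists, off by default) and completely-at-random
  missingness capped so every probe keeps at least 90% of samples.

One numerical choice deserves emphasis: by default the baseline of each
*planted* probe is clamped so its linear ramp stays inside [0.05, 0.95]
over the cohort's age span (`recoverable_baselines = TRUE`). Without this,
a gain effect placed on a hypermethylated probe saturates at the ceiling
and its age signal is destroyed by clipping — the planted truth would then
be unrecoverable by construction, which would make recovery tests measure
the clipping artefact instead of the pipeline. Null probes are never
adjusted, and clipping still operates everywhere (noise excursions and the
`recoverable_baselines = FALSE` setting exercise it).

Determinism is strict: a single seed fans out to per-stage, per-tissue
seeds through a fixed string hash (`derive_seed`), so the same seed gives
byte-identical genomes, cohorts and reports, and any stage can be re-run
in isolation.

### What the simulator does *not* emulate

Neighbouring CpGs are simulated independently, whereas real 450k data are
locally correlated; there is no probe-type (I/II) chemistry, no SNP-affected
probes, no normalisation artefacts, and no nonlinear age trajectories
(real methylation drifts faster in adolescence). Passing recovery tests
therefore demonstrates that the statistical machinery is correct under the
stated model, not that the model captures every property of real arrays.

## Problem sizes in the shipped analyses

The test-suite and acceptance analyses run at desk scale, chosen as the
smallest sizes at which every claim is still a meaningful statistical
statement: null calibration uses 40 replicate genomes of 5,000 probes at
n = 100; effect recovery uses 20 replicates of a seven-tissue design with
5,200 probes, 700 planted effects and n = 300; enrichment-bias recovery
uses 20 replicates per odds-ratio level at 6,000 probes; interval oracles
are checked on 10,000 random probes. The real catalogue's 428,279-probe,
~2,900-sample scale is linear extra work for the same code paths (the
epigenome-wide fit is a single matrix product per missingness pattern).

## Known limitations

* Covariates are taken as provided: no batch correction, cell-type
  deconvolution or surrogate-variable estimation is performed.
* The Bonferroni family is the per-tissue tested-probe count, not a fixed
  array-wide constant, so $m$ differs between tissues when missingness
  does.
* Region aggregation relies on the provided probe→region mapping;
  unmapped probes are dropped with a logged count rather than imputed.
* The relaxed-threshold cross-tissue check uses raw P values and inherits
  whatever miscalibration the per-tissue fits have under model
  misspecification.
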