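# admpatlas

Tissue-specific analysis of age-related DNA methylation changes.

DNA methylation at individual CpG sites drifts with chronological age. On
Illumina 450k-style arrays methylation is measured as a *beta value* — the
methylated fraction in [0, 1] — and a CpG whose beta changes linearly with
age past fixed effect-size and significance cut-offs is an **age-related
differentially methylated position (aDMP)**: a *gain*-aDMP when methylation
rises with age, a *loss*-aDMP when it falls. `admpatlas` is for
epigeneticists who want to call aDMPs per tissue, ask how often the same
CpG (or the same CpG island, or the same gene) recurs across tissues, and
characterise where in the genome aDMPs accumulate — with power controls
that separate true tissue-specificity from mere sample-size differences.

## The model

For each probe *j* in one tissue, ordinary least squares

&nbsp;&nbsp;&nbsp;&nbsp;β<sub>ij</sub> = α<sub>j</sub> + b<sub>j</sub>·age<sub>i</sub> + γ<sub>j</sub><sup>T</sup> z<sub>i</sub> + ε<sub>ij</sub>

with age in years (untransformed) and z the tissue's covariates (sex,
study batch, cell fractions). A probe is an aDMP under the dual criterion

&nbsp;&nbsp;&nbsp;&nbsp;|b<sub>j</sub>| ≥ 2% / 10 years&nbsp;&nbsp;and&nbsp;&nbsp;P<sub>bonf</sub> ≤ 0.05,

where P<sub>bonf</sub> = min(1, m·p) over the m probes tested in that
tissue. Cross-tissue specificity, sharing histograms, overlap matrices,
relaxed-threshold (P < 0.001) robustness checks, CGI/chromatin-state/EZH2
enrichment (odds ratios with 1-df chi-squared tests over the tested-probe
background) and two power controls — effect-size-only calling and equal-N
subsampling — complete the analysis. A synthetic multi-tissue methylome
generator with planted, annotation-biased ground truth makes the whole
pipeline testable end to end.

## Worked example

Simulate a three-tissue cohort with planted effects, call aDMPs in brain,
and quantify cross-tissue specificity:

```r
library(admpatlas)
tissues <- c("brain", "liver", "kidney")
genome  <- generate_genome(n_probes = 3000, n_genes = 60, tissues, seed = 7)
effects <- plant_effects(genome, effect_design(n_gain = 150, n_loss = 100),
                         seed = 7)
design  <- cohort_design(tissues, n = c(300, 150, 170),
                         age_min = c(20, 15, 15), age_max = c(90, 86, 86))
cohort  <- simulate_cohort(genome, effects, design, seed = 7)

fit <- call_admps(cohort$brain)
fit
#> aDMP calls for 'brain' (300 samples, 3000 probes tested, mode dual)
#>   gain 51 | loss 35 | none 2914 | untested 0
#>   criteria: |slope| >= 2 %/10yr, P_bonf <= 0.05 (m = 3000)
```

51 of the 3000 probes gained and 35 lost methylation with age in brain
under the dual criterion. Across the three tissues:

```r
calls <- lapply(cohort, call_admps)
sp <- build_specificity(calls, "gain")
percent_tissue_specific(sp)
#> [1] 84.7
sharing_histogram(sp)
#>   1   2   3
#> 127  22   1
```

84.7% of gain-aDMPs were called in exactly one tissue (127 of 150; 22 in
two tissues, and the one planted universal effect in all three), matching
the 85% tissue-specific share planted by the generator. The planted
placement bias — gain effects preferring probes that are both CpG island
and EZH2-bound — is recovered as a strong enrichment:

```r
ann <- annotate_probes(genome)
tested <- fit$table$class != "untested"
cgi_ezh2_joint_enrichment(fit$table$probe_id[fit$table$class == "gain"],
                          fit$table$probe_id[tested],
                          ann$cgi_class[tested], ann$ezh2[tested])
#>            category  a b   c   d odds_ratio        p significant
#> 1  both_vs_cgi_only 23 2 354 521       16.9 2.60e-07        TRUE
#> 2 both_vs_ezh2_only 23 2 354 319       10.4 1.04e-04        TRUE
#> 3    both_vs_single 23 4 354 840       13.6 6.53e-10        TRUE
```

23 of the 27 brain gain-aDMPs with either annotation carry both, far above
the background rate among tested probes. `run_pipeline(pipeline_config(...))`
chains all stages (simulate → call → specificity → annotate/enrich →
report) with per-stage TSV outputs and full seed determinism.

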