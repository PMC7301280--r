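# proteoage

Multi-omics analysis of proteostasis decline in the aging vertebrate brain.

Aging brains lose protein homeostasis in a characteristic sequence:
transcript and protein abundances drift apart, the stoichiometry of protein
complexes (ribosome first among them) erodes, insoluble protein aggregates
accumulate, and early-life changes in proteostasis gene expression predict
individual lifespan. proteoage implements the statistical pipeline for
studying this process from matched transcriptomic and proteomic data of an
age-structured cohort (young / adult / old, a few animals per group, as in
short-lived killifish studies), with every stage exercisable on synthetic
cohorts that carry known ground truth. It is written for computational
biologists who want each analysis step as a tested, composable,
data-frame-in / tibble-out function rather than a monolithic script.

## What it computes

| Stage | Core quantity |
|---|---|
| TMT ingestion | PSM filtering; protein groups as channel-wise medians of log2 unique-peptide intensities; iBAQ = split precursor intensity / observable tryptic peptides |
| Differential kernel | moderated t: t = Δmean / (s̃ √(1/nA+1/nB)), s̃² = (d₀s₀² + d s²)/(d₀+d), prior (d₀, s₀²) by moment matching; BH adjustment; Fisher combination; hypergeometric ORA |
| Decoupling | per-sample Pearson r of log₁₀ protein vs log₁₀ transcript + ANOVA across ages; fold-change concordance quadrants; five regulatory-mechanism classes per affected protein |
| Stoichiometry | complex-relative log2 values (per-sample trimmed mean subtracted); affected = ≥ 2 members at adj. p < 0.05 and \|log2 FC\| > 0.5; IQR of member fold changes per complex |
| SEC co-elution | row-normalized elution profiles; within-complex pairwise r vs size-matched random-complex null (rank-sum); median consensus profiles; apex / centre-of-mass elution shifts |
| Aggregates | quantile-normalized pellet vs total-homogenate moderated differential; signed classifier score (−P/0/+P) and coil fraction n_c/N; KS test on enrichment-extreme tails; Fisher set enrichment |
| Survival | per-gene Cox model h(t\|Δ) = h₀(t)·exp(c·Δ), Δ = log2 g(t₂)/g(t₁), Breslow partial likelihood with left truncation; extreme-group log-rank at k = 32 |

Synthetic generators (`generate_omics_cohort()`, `generate_psm_table()`,
`generate_sec_profiles()`, `generate_aggregate_experiment()`,
`generate_longitudinal_survival()`) produce every input with recorded truth
and are first-class, tested code. Fitted results carry broom-style `tidy()` /
`glance()` methods and ggplot2 `autoplot()` methods; `run_pipeline()` drives
an end-to-end synthetic run with a reproducibility manifest.

## Worked example

Generate a cohort whose per-group transcript-protein correlations are
steered to 0.48 / 0.43 / 0.33 (young / adult / old), then recover them:

```r
library(proteoage)

co <- generate_omics_cohort(cohort_design(n_genes = 5000, seed = 1),
        decoupling_targets = c(young = 0.48, adult = 0.43, old = 0.33))
pc <- per_sample_correlation(co$proteins, co$transcripts, co$samples)
glance(pc)
#> # A tibble: 1 × 5
#>   n_samples n_excluded anova_f  anova_p group_means
#>       <int>      <int>   <dbl>    <dbl> <list>
#> 1        15          0    196. 6.86e-10 <dbl [3]>
glance(pc)$group_means[[1]]
#>     adult       old     young
#> 0.4281139 0.3400300 0.4847950
```

The recovered group means sit within 0.01 of their targets and the ANOVA
confirms the age trend (F = 196, p = 6.9e-10 across the 15 samples):
decoupling increases with age exactly as injected. `autoplot(pc)` draws the
per-sample boxplot.

A longitudinal cohort where decreasing expression of a 50-gene
"proteasome" set raises mortality (per-gene Cox coefficient −0.8):

```r
lon <- generate_longitudinal_survival(n_fish = 159, n_genes = 200, seed = 2,
         risk_sets = list(proteasome = sprintf("gene_%04d", 1:50)),
         coefficients = c(proteasome = -0.8))
cx <- genewise_cox(lon$delta, lon$surv)
lr <- extreme_group_logrank(lon$delta, lon$surv,
         gene_set = sprintf("gene_%04d", 1:50), k = 32)
c(chisq = lr$chisq, p = lr$p)
#>        chisq            p
#> 7.486115e+01 5.060132e-18
```

The 32 fish with the strongest proteasome decrease die substantially
earlier than the 32 with the strongest increase (log-rank χ² = 74.9,
p = 5.1e-18); `plot_extreme_survival(lr, lon$surv)` shows the two survival
curves.

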