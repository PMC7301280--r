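---
title: "Models and methods: multi-omics analysis of proteostasis decline in brain aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: multi-omics analysis of proteostasis decline in brain aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

proteoage implements, as a tested and reusable pipeline, the statistical core
of a multi-omics study of proteostasis loss in the aging vertebrate brain
(the short-lived killifish *Nothobranchius furzeri*, three age groups --
young, adult, old -- with about five animals per group). This vignette is
the package's own account of the models it fits, the parameters that matter,
what the synthetic-data generators do and do not emulate, and the design
choices made where the methodology was genuinely open.

```{r setup, message = FALSE}
library(proteoage)
library(dplyr)
```

## 1. TMT quantification and iBAQ

PSM-level reporter-ion processing follows the standard reporter-ion TMT
workflow: PSMs mapping to reverse or contaminant hits are discarded, as are
PSMs with a search score below 15 or reporter intensities below 10^3^ in all
channels (`filter_psms()`, both thresholds configurable). Retained
intensities are log2-transformed, median-centred per channel, and
summarized into protein groups by the median over unique (proteotypic)
peptides quantified in every channel; at least two unique peptides are
required per protein (`summarize_protein_groups()`).

Channel "normalization" is under-specified in this field's processing
descriptions; we use per-channel median-centring in log2 space because it is
scale-robust and leaves fold changes untouched.

The iBAQ route exploits that a peptide's precursor (MS1) area is the sum of
its TMT channels: per peptide, the channel ratio vector is the median over
its PSMs of `reporter / sum(reporters)`, renormalized to sum to one, and the
precursor total is split by these ratios (`split_precursor_to_channels()`).
Renormalizing the medians is our choice; it preserves the conservation
property (pre-correction split intensities sum exactly to the precursor
total), which is enforced by tests at 10^-9^ relative tolerance. The
per-channel median-ratio correction for sampling aberrations is applied
after splitting. iBAQ then divides summed unique-peptide intensities by the
count of potentially observable tryptic peptides -- fully tryptic
(cleavage C-terminal to K/R, suppressed before proline, the canonical rule),
no missed cleavages, length 8--25 (`digest_and_count_observable()`).
Unknown residues (X/B/Z/U/O) are treated as non-cleaving. Median
normalization of the final scores divides each channel by its median, so
rescaling any single channel cancels exactly.

## 2. Moderated differential abundance

Every differential step in the pipeline uses one statistical kernel
(`moderated_t_test()`): a two-group t-test whose per-feature variance is
shrunk toward a common prior by closed-form moment matching on the log
sample variances. Writing $s^2_g$ for the pooled residual variance with $d$
df, the prior $(d_0, s_0^2)$ solves

$$\mathrm{Var}[\log s_g^2] - \psi'(d/2) = \psi'(d_0/2),$$

with the digamma-corrected mean giving $s_0^2$; the moderated variance is
$\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ and the statistic is
referred to a t-distribution with $d + d_0$ df. When the observed variances
are *less* dispersed than pure chi-square noise the prior df is infinite and
all features share $s_0^2$. Setting `prior_df = 0` recovers the ordinary
pooled t-test exactly (a limiting case the tests assert at 10^-9^), and on
heterogeneous-variance data the estimates agree with limma's
moment-matching to machine precision, which the suite uses as an
independent cross-check.

Supporting operations: Benjamini-Hochberg adjustment (`bh_adjust()`, a thin
wrapper over `p.adjust()` with NA entries excluded from the test count),
Fisher's p-value combination (`fisher_combine()`,
$X = -2\sum \ln p_k \sim \chi^2_{2k}$), hypergeometric over-representation
(`ora_test()`) and a two-sample t set test on per-feature scores
(`coefficient_set_test()`, Welch variance). One caveat worth stating:
Fisher combination of $k$ copies of the same p-value is *not* monotone
decreasing in $k$ for moderate p (two copies of 0.3 combine to 0.307); the
monotonicity property holds for small p and is tested at p = 0.05.

Transcript counts take a single generic route -- log2(CPM + 0.5) followed by
the moderated t -- because the downstream logic needs only a fold change and
an adjusted p per gene; count-model dispersion estimation is deliberately
out of scope.

## 3. Transcript-protein decoupling and mechanism classes

Global decoupling is measured per sample as the Pearson correlation of
log10 protein versus log10 transcript abundance over features positive in
both layers (at least 100 shared features, or the sample is excluded), with
a one-way ANOVA of the per-sample correlations across age groups
(`per_sample_correlation()`). The log10 scale is our choice -- the standard
for abundance-abundance correlation and the scale on which the reported
magnitudes (about 0.3--0.5) live.

Proteins differentially abundant at the protein level are assigned to five
mutually exclusive regulatory classes in a fixed decision order
(`classify_mechanism()`): transcript not detected; transcript significant
with the same fold-change sign; transcript consistent (same sign) but not
significant; protein down-regulated and targeted by an up-regulated miRNA
(the canonical repressive direction -- only up-regulated miRNAs are
considered); all remainder, attributed to other post-transcriptional
mechanisms. "Consistent" additionally requires the transcript fold change
to reach `min_consistent_fc` (default 0.3 log2 units): for a genuinely flat
transcript the fold-change *sign* is a coin flip, so a sign-only rule would
misassign half of the post-transcriptionally regulated proteins. This
magnitude floor is the package's interpretation of an ambiguity (whether
"consistent changes" required any minimal size) and is configurable.

```{r mechanism, eval = FALSE}
co <- generate_omics_cohort(cohort_design(n_genes = 2000, seed = 1),
                            protein_noise_sd = 0.1, effect_size = 2,
                            dispersion = 0.02)
grp <- split(co$samples$sample_id, co$samples$group)
prot <- matrix_as_omics(log2(omics_as_matrix(co$proteins)))
de <- moderated_t_test(prot, grp$old, grp$young)
tr <- transcript_de(co$transcripts, grp$old, grp$young)
classify_mechanism(de, tr, co$transcripts$feature_id,
                   co$mirna_de, co$mirna_targets)
```

## 4. Protein-complex stoichiometry

Member abundances are expressed relative to their complex: per sample and
complex, the trimmed mean of the member log2 intensities is subtracted from
each member (`normalize_to_complex()`). The trim fraction is 20% total
(10% per tail) with at least one value dropped per tail at the 5-member
floor -- a robustness/efficiency compromise chosen once, since the original
method states only "trimmed mean". Complexes need at least five quantified
members everywhere. Member-level differential analysis then runs on the
complex-relative values, and a complex is *affected* when at least two
members change significantly (BH-adjusted p < 0.05 and |log2 FC| > 0.5,
`call_affected()`).

Known limitation: because the trim is computed per sample, one member with
a very large shift changes *which* co-members survive the trim, dragging
the complex centre by a common offset. For small complexes (about six
members) with wide between-member spread this drag can push unaffected
co-members past the 0.5 fold-change threshold and call the complex on the
strength of a single true outlier. At realistic effect sizes (about 1
log2 unit) and for mid-size complexes the drag is absorbed and the
two-member rule behaves as intended; the tests exercise both regimes.

Stoichiometry dispersion is summarized per complex as the interquartile
range of member log2 fold changes (`complex_iqr()`), using type-7
linear-interpolation quantiles (documented so tests can be exact: the IQR
of {1,2,3,4} is 1.5). Contrasts are compared by a two-sided Wilcoxon
rank-sum test on the per-complex IQR vectors (`compare_iqr()`), and
complexes are ranked by their late-minus-early IQR difference
(`rank_iqr_difference()`), ties contributing one half to the
fraction-increased summary.

## 5. SEC co-elution

Elution profiles over 39 fractions are normalized to unit row sums
(`normalize_sec_profiles()`); correlations use all fractions, zeros
included, since absence from a fraction is informative. Within-complex
pairwise Pearson correlations (5-member floor) are compared to a null of
randomly drawn protein sets matching the real complex size multiset --
1000 seeded draws by default, self-draws excluded -- via a two-sided
rank-sum test (`random_complex_null()`). Consensus complex profiles are
per-fraction medians over members scaled to max 1 (`complex_profile()`).

Elution shifts between conditions are quantified by two statistics
(`detect_elution_shift()`): the apex (argmax, earliest fraction on ties)
shift and the intensity-weighted centre-of-mass shift, with the flagging
decision on the centre of mass at a default threshold of 2 fractions. The
centre of mass is preferred for flagging because it is robust to peak
splitting; the threshold is a configurable default, not a claim about
biology. Positive shifts mean later elution, i.e. lower apparent molecular
weight. Replicates are analyzed independently; no cross-replicate averaging
is applied by default.

## 6. Aggregate enrichment and biophysical scores

Pellet versus total-homogenate analysis retains proteins quantified in at
least two replicates per label, quantile normalizes the log2 matrix, and
applies the moderated t (`aggregate_enrichment()`). Quantile normalization
maps every column to the mean of the column-sorted values; ties receive the
interpolated target at their average rank, and missing values are excluded
from the reference distribution and re-inserted by interpolated rank.
Enrichment is called volcano-style on the *raw* p (< 0.05) with
|log2 FC| > 0.5, matching how such cutoff lines are conventionally drawn.

Biophysical classifier outputs are reduced to two scores:
`clever_score()` maps a (label, probability) pair to a signed probability
(-P / 0 / +P for negative / indeterminate / positive), and `s2d_score()` is
the random-coil residue fraction $n_c/N$. Enrichment-extreme tails (top
versus bottom 20% by default) are compared on any score by a two-sample
two-sided Kolmogorov-Smirnov test (`compare_extremes()`). Set enrichment
among aggregate-enriched proteins uses a two-sided Fisher exact test per
set (the sidedness is our default; the original description does not state
it) plus a ranking of complexes by median member enrichment with a
3-member floor (`set_enrichment_in_aggregates()`).

## 7. Longitudinal expression change and lifespan

For each fish $j$ and gene $i$, the covariate is the expression change
between the two samplings, $\Delta_{ij} = \log_2 g_{ij}(t_2)/g_{ij}(t_1)$,
computed on median-of-ratios normalized counts with a 0.5 pseudo-count
(`compute_delta()`; the size factors are the geometric-mean-reference
formula, re-implemented directly). The hazard model is

$$h(t \mid \Delta_{ij}) = h_0(t)\, e^{c_i \Delta_{ij}},$$

fitted per gene by Newton-Raphson on the Breslow partial likelihood
(`cox_fit_single()`, `genewise_cox()`), with left truncation at the second
sampling time because the analyzed cohort conditions on surviving to it.
$c_i > 0$ means mortality increases with $\Delta_{ij}$. Constant covariates
are reported as degenerate with $c = 0$, $p = 1$; monotone likelihoods
(risk perfectly ordered by the covariate) are flagged divergent with no
finite estimate. Ties would be handled by Breslow's approximation, adequate
for continuous lifespans. The fitted coefficients feed
`coefficient_set_test()` to find risk-gene sets (raw $\Delta$, not
standardized, is used -- the coefficient scale then refers to log2 units of
expression change).

The extreme-group comparison summarizes each fish by the mean $\Delta$ over
a gene set (mean by default; median and first-PC summaries are available),
takes the `k = 32` most extreme fish on each side, and compares lifespans
with the two-group log-rank test (`extreme_group_logrank()`, via
`survival::survdiff`). Ties at the k-th rank break deterministically by
fish id.

## 8. The synthetic-data generators

Every analysis stage can be driven by generators that record their ground
truth, under the study's structural conditions: three age groups with five
animals each, negative-binomial transcript counts (gene dispersion 0.1 by
default) around log-normal gene means (log2 mean 8, sd 2; median depth a
few hundred counts per gene), and log-normal protein intensities linked to
transcripts through the per-gene mechanism class
(`generate_omics_cohort()`). Default class proportions (30% concordant,
15% transcript-consistent, 10% no-transcript, 10% miRNA-explained, 35%
other post-transcriptional over the affected fraction of 20%) reflect the
qualitative picture that most age-affected proteins are regulated
post-transcriptionally.

Two features deserve comment:

* **Correlation targets.** When per-group transcript-protein correlation
  targets are supplied (the reported group means 0.48 / 0.43 / 0.33 serve
  as simulation parameters), the per-sample protein noise variance is
  solved analytically from the realized transcript values, so the achieved
  log-log Pearson correlation lands within ±0.05 of the target for 2000 or
  more genes. Targets that are unreachable (negative solved variance)
  produce a warning and the achievable value in the truth record. Noise at
  these realistic decoupling levels is large compared with aging fold
  changes, so mechanism recovery is instead assessed under a
  strong-effect / low-noise condition (protein noise sd 0.1, effect size 2,
  transcript dispersion 0.02), where the classifier recovers over 90% of
  true labels.
* **Consistent-but-not-significant genes.** Genes of the
  transcript-consistent class receive half the protein fold change plus
  inflated per-sample biological scatter (sd 0.8 log2 by default), which is
  what keeps a real trend below the significance threshold -- without the
  extra scatter, any detectable trend at low noise would be significant and
  the class would be unrecoverable by construction.

The PSM generator (`generate_psm_table()`) emits tryptic peptides of the
supplied sequences with reporter intensities consistent with per-channel
protein abundances, a search-score mixture with a controlled fraction below
the filter cutoff, decoy and contaminant records, and precursor intensities
equal to reporter sums times a per-PSM scale. The SEC generator
(`generate_sec_profiles()`) gives complex members a shared Gaussian elution
apex (member jitter sd 0.5 fractions, peak width 1.5 fractions) and
displaces selected complexes in the old condition, clipping (with a
warning) shifts that leave the fraction axis. The aggregate generator
draws pellet shifts around +1 log2 for the enriched set and couples the
biophysical scores to the true enrichment through a controllable latent
correlation. The survival generator inverts the proportional-hazards model
by inverse-transform sampling on an exponential baseline (rate 0.03 per
week), conditional on surviving to the 20-week entry -- exact because the
exponential is memoryless.

What the generators do **not** emulate: spectrum-level structure (m/z,
retention time, isotope impurities), razor-peptide ambiguity, realistic
chromatogram shapes, batch effects, and the long-tailed
sample-to-sample variability of real RNA-seq. Passing tests therefore
certify the statistical machinery against data that satisfy the model
assumptions, not performance on any real dataset.

All generators are deterministic given (configuration, seed); the pipeline
driver `run_pipeline()` derives one seed per stochastic stage from a single
master seed and writes a JSON manifest sufficient to reproduce a run
byte-identically.

## 9. Numerical choices and problem sizes

Degenerate inputs have defined behaviour throughout: constant features give
p = 1; flat SEC profiles break apex ties to the earliest fraction with a
warning; all-zero SEC rows are dropped; zero p-values are clipped to the
smallest positive double before log-combination; empty selections give
empty enrichment tables. Wilcoxon tests use `wilcox.test()`'s conventions
(exact where feasible, normal approximation with continuity correction
otherwise); the KS test is asymptotic for tails above 25.

The calibration and recovery checks in the test suite use problem sizes
chosen to estimate each rate with adequate precision while keeping the
default test run light: 1000 null features/genes for type-I rates
(binomial se about 0.7%), 5000 genes for correlation-target recovery,
20--40 seeds for detection-rate properties, 100--200 seeds for
p-uniformity checks. The same sizes are used by `scripts/acceptance.R`.

## 10. Known limitations

* The mechanism classifier's class boundaries depend on the significance
  threshold and the consistency floor; near-threshold genes move between
  classes (i)/(ii)/(v) under resampling.
* The per-sample trimmed-mean drag described in section 4.
* The empirical-Bayes prior is estimated by moment matching, which is
  slightly less efficient than ML for very small feature counts; below
  about 20 features the prior is noisy (the implementation falls back to
  no shrinkage below 2 usable variances).
* Cox fits assume proportional hazards on a single covariate; no
  multivariate adjustment, penalization, or censoring-heavy designs are in
  scope (censoring itself is supported).
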