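---
title: "Methods: exposure-scheme transcriptomics with schemeDE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exposure-scheme transcriptomics with schemeDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`schemeDE` analyses blocked bulk RNA-seq experiments that contrast acute
(short, high-concentration) with chronic (long, low-concentration)
pesticide exposure in bumble bee microcolonies. This vignette is the
package's own account of the models it fits, the parameters that matter,
what the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open. Every number a
test asserts is computed by the test itself or by
`scripts/acceptance.R`; nothing here reports an empirical result the code
does not produce.

## The study design being modelled

Seven treatments — a control plus three compounds (acetamiprid,
clothianidin, sulfoxaflor) crossed with two exposure schemes — are applied
to microcolonies of six workers. Microcolonies are drawn from ten source
colonies, so genetic background is a blocking factor shared across
treatments. The default design has ten replicates for the control and each
chronic treatment and eight for each acute treatment: 64 samples. Chronic
exposure runs from day 2 to day 14 at a low concentration (5 µg/L of
feeding solution, 4.4 ppb by mass at a solution density of 1130 g/L);
acute exposure covers only the final two days at five times the
concentration (25 µg/L, 22.1 ppb). Those conversions are implemented in
`ppb_concentration()` with half-up rounding to one decimal, matching how
such concentrations are conventionally printed.

## Differential expression engine

For gene $g$ in sample $j$, counts are modelled as negative binomial with
mean $\mu_{gj} = s_j \exp(x_j^\top \beta_g)$ and variance
$\mu + \alpha_g \mu^2$. The engine is a deliberately transparent
simplification of the mature shrinkage-based packages used in this field;
the downstream statistics need a *calibrated* Wald engine, not
bit-compatibility with any particular implementation. Its parts:

* **Filtering.** A gene is kept when it shows at least `min_count` (10)
  counts in at least `min_samples` (8) samples, both thresholds inclusive.
* **Normalization.** Median-of-ratios size factors; the lower median is
  taken on ties across an even number of usable genes, and when no gene is
  expressed in every sample the geometric means fall back to positive
  entries only. A single sample receives factor 1.
* **Dispersion.** A pooled within-treatment method-of-moments estimate
  $\max\{(s^2-\bar m)/\bar m^2, \text{floor}\}$ with
  degrees-of-freedom weights, clamped to `[0.01, 10]`. No empirical-Bayes
  shrinkage. The floor of 0.01 reflects the residual biological
  coefficient of variation (about 10%) below which single-study data
  cannot discriminate dispersions; the cap guards against degenerate
  moment estimates at tiny means.
* **Fitting and testing.** Per-gene IRLS for the log-link NB GLM with
  fixed dispersion, design `~ treatment + colony` (control and colony 1 as
  references), log size factors as offset, at most 50 iterations and a
  coefficient-change tolerance of 1e-6. Non-converged genes carry missing
  statistics and are excluded from the BH adjustment, which otherwise runs
  across all retained genes. Rank-deficient designs abort with the aliased
  columns named.
* **VST and PCA.** The variance-stabilizing transform is the shifted log
  $\log_2(\text{count}/s_j + 1)$ — adequate for standard-deviation
  contrasts and PCA once counts are a few hundred, which the generator's
  default library sizes ensure. PCA centres genes and decomposes samples
  by SVD.

Calibration is checked, not assumed: on global-null synthetic data the raw
p-values must pass a Kolmogorov–Smirnov uniformity test and the count of
FDR-significant genes must stay within 1.5 times the nominal budget
(`tests/testthat/test-acceptance.R`).

## Overlap statistics

DE gene sets from several treatments are compared on the pool of retained
genes. "Random" sets are drawn uniformly without replacement — the
uniqueness in the sampling scheme refers to genes within one draw, not to
deduplication of whole iterations, which would be measure-zero at these
pool sizes. The add-one p-value $(1+\#\{\text{sim} \ge \text{obs}\})/(B+1)$
counts the observed configuration as one null draw and is therefore
conservative by construction (a property test verifies stochastic
dominance over uniform). Fold enrichment uses the simulation mean, with
the analytic expectation $N\prod_i(n_i/N)$ reported alongside and
substituted if the simulation mean is zero; both the simulation-scale and
expected-overlap-scale standard errors are available because printed
enrichment SEs are ambiguous between the two.

## Scheme-contrast statistics

* **Amplitude.** The `k = 20` significant genes with the largest
  $|\log_2$ fold change$|$ per contrast (selection by adjusted p-value is
  available; extreme-change selection is the default) are compared with a
  Welch *t* test; the ratio of mean absolute fold changes is the amplitude
  ratio. $k = 1$ is refused — the Satterthwaite degrees of freedom are
  undefined.
* **Fourfold proportions.** Among significant genes, the fraction at or
  above a fourfold change (2 on the log2 scale) is contrasted between
  schemes with an uncorrected Pearson chi-square by default; the Yates
  variant is exposed because reports of such tests rarely state whether a
  continuity correction was applied. A zero column margin (e.g. threshold 0) means the
  proportions are equal by construction and is reported as
  $\chi^2 = 0,\ p = 1$ rather than an error.
* **Direction.** The up/down split of a shared DE set is tested against
  50:50 with a goodness-of-fit chi-square; a 56:5 split gives
  $\chi^2 = 39.4$. Smaller statistics quoted for comparable splits imply
  a different, unstated null; the operation implements only the standard
  formula and leaves the null proportions explicit in its interface.
* **Replicate variance.** The field's usual approach fits a gamma GLMM of
  per-gene, per-treatment standard deviations on scheme and DE status with
  gene as a random effect. `variance_contrast()` estimates the same
  scheme-by-status interaction without mixed-model machinery: the per-gene
  difference of scheme-mean log SDs eliminates the gene effect exactly
  (differencing instead of estimating), and the interaction is the mean
  difference among DE genes minus that among the rest, with a Welch test.
  SDs are computed per treatment and averaged on the log scale within
  scheme — pooling samples across treatments would fold
  between-treatment differences of compound-specific genes into the
  "replicate" SD. Constant genes are excluded and counted.

## Resampling diagnostics

**Replicate balance.** Acute groups have eight replicates, chronic groups
ten. The diagnostic redraws unique joint subsets of eight control and
eight chronic samples (uniqueness enforced on the joint pair via a
canonical signature; infeasible requests abort with the combinatorial
bound), reruns the full DE pipeline per subset, and locates each acute
contrast's DE count in that distribution with an add-one permutation
p-value. Fifty iterations, the default, balance the p-value floor (1/51)
against runtime.

**Colony confounding.** In mismatched mode, control samples come from one
random half of the colonies and treatment samples from the complementary
half, so genetic background is perfectly confounded with the comparison
and the colony covariate cannot be fitted; the model drops it. In matched
mode both arms come from the same colonies; the analysis then *keeps*
colony as a blocking factor and estimates dispersion from full-design
residuals, because that is precisely what a matched design lets an analyst
do. This asymmetry is deliberate: dropping colony in both modes makes the
mismatched mode detect *more* genes (colony differences masquerade as
treatment effects), inverting the phenomenon the diagnostic exists to
demonstrate — that controlling genetic background yields more
discoveries. The two DE-count distributions are summarized (median,
skewness) and compared with an asymptotic two-sample KS test; ties across
the discrete counts make the p-value approximate, which is acceptable for
a diagnostic.

## Survival and dose accounting

Pairwise Cox proportional-hazards fits compare each treatment with the
control: one binary covariate, Breslow tie handling, Newton–Raphson with
damped steps. Chronic comparisons use the whole 14 days; acute comparisons
restrict both arms to individuals alive when the exposure window opens
(day 12) and re-zero time there — deaths before day 12 in acute arms
precede any exposure. Monotone likelihoods are flagged, the coefficient
reported non-finite, and the p-value taken from the score test, which at
$\beta = 0$ equals the log-rank chi-square (asserted against an
independent implementation in the tests). Kaplan–Meier mortality at a
horizon equals the plain death fraction without prior censoring.

Food intake is modelled by OLS of average daily intake per bee on source
colony, day, treatment, and day-by-treatment interaction; the acute
variant uses only days 12 and 14. Cumulative dose per bee multiplies the
solution volume consumed over the exposure window by the mass
concentration; records may be per-bee daily averages (the generator's
convention, each covering a two-day interval) or microcolony totals.

## What the generator emulates — and what it does not

Counts are generated directly at the gene level (transcript-level
quantification is out of scope): library size times a relative abundance
$2^{b_g + c_{g,k} + \lambda_{g,t}}$, with NB dispersion
$\alpha(\mu) = \alpha_0 + \alpha_1/\mu$. Key defaults, chosen once:

| parameter | default | units / rationale |
|---|---|---|
| `n_genes` | 2000 | desk-scale; large enough for calibration tests |
| `library_size_range` | 0.5–2 million | log-uniform; median gene counts of a few hundred keep the shifted-log VST in its variance-stable regime |
| `baseline_log2_mean` | N(5, 2) | log2 relative abundance; yields realistic count spread |
| `dispersion_trend` | α₀ = 0.01, α₁ = 0.5 | mild mean–dispersion trend typical of pooled-sample bulk data |
| `colony_effect_sd` | 0.3 | log2; moderate genetic-background block effects |
| `shared_acute_set_size`, `acute_up_fraction` | 61, 0.91 | the shared acute response, 91% upregulated; the upregulated count rounds half up (56 of 61) |
| `shared_chronic_set_size` | 20, of which 4 at −5 log2 | a few strongly (32-fold) downregulated immune-like genes plus milder shared repression |
| `amplitude_ratio_acute_over_chronic` | 2.7 | mean shared-acute amplitude is exactly 2.7× the shared-chronic mean, by rescaling at construction |
| `acute_specific_sizes` | 100 / 220 / 8 | per-compound extra responders; clothianidin ≫ acetamiprid ≫ sulfoxaflor, giving an acute/chronic clothianidin DE-count ratio near 3.5 |
| `chronic_specific_sizes` | 12 / 60 / 8 | smaller chronic responses |
| `acute_extra_sd_factor` | 1.2 | acute-responder replicate SD is 1.2× the chronic side on the VST scale |

Three construction details matter for interpretation:

* **Amplitude encoding is exact.** Shared-acute magnitudes are a tight
  (±5%) distribution rescaled so their mean is exactly
  `amplitude_ratio × mean(|shared chronic lfc|)`; the top-20 estimator
  then recovers the ratio within a few percent plus selection noise.
  Strongly induced genes start from lower baselines and strongly
  repressed genes from higher ones, keeping both ends estimable.
* **Replicate-variance inflation is a gene property of acute
  responders.** A gene that truly responds to any acute treatment is
  noisier across the whole acute scheme: in each acute treatment,
  log-normal noise on the log2 mean is calibrated — using exact NB
  moments of $\log_2(X+1)$, plus the colony-effect variance — so the
  gene's total replicate variance is `factor²` times what its *baseline*
  expression would show in the same sample context. Anchoring to the
  baseline keeps non-responding genes' composition effects common to both
  groups of the contrast, so the interaction estimand is the configured
  `log(factor)`. Where a mean shift alone already exceeds the target
  (strong repression at low counts), the extra noise clamps at zero and a
  small upward residual remains; the recovery tolerance (±0.05 on
  log 1.2) covers it.
* **Survival and intake are generative, not fitted.** Exponential event
  times with treatment hazards (acute elevation only inside the two-day
  window, chronic elevation after the two-day adjustment); defaults put
  acute clothianidin mortality near 54% and chronic near 29% at a 5%
  control. Intake is linear in exposure day (baseline 1.6 mL per bee per
  day, chronic clothianidin slope −0.063, acute −0.51) with Gaussian
  noise; zero-noise runs recover the interaction coefficients exactly.

Not emulated: read-level artefacts (sequencing, mapping, transcript
structure), correlated gene modules, sparse or heavy-tailed colony
effects, dominance physiology, or dose–response nonlinearity. Passing
tests therefore demonstrate that the *statistical machinery* is correct
and calibrated under the declared generative model — not that any
biological conclusion transfers to real data.

## Numerical choices and degenerate inputs

Half-up rounding for printed concentrations and the up-regulated gene
count; lower median on even-length ratio vectors; IRLS linear steps
damped by capping the linear predictor at 30; Newton steps in the Cox fit
capped at ±2 per iteration with |β| > 15 declared monotone; Welch tests
on numerically constant samples resolved by closed-form limits (equal
means: undefined with a warning; unequal: infinite t, zero p); euler
tabulation refuses more than 10 sets; KS on tied counts uses the
asymptotic approximation. One global seed expands into fixed per-stage
offsets so any stage can be rerun in isolation; all table output uses
`%.6g` floats and LF newlines so manifests hash identically across runs.

## Problem sizes used by the tests

The test suite runs the full seven-treatment design at 2000 genes for
calibration and recovery checks (10 seeds each), 300-gene versions for
the resampling diagnostics (20 seeds; 50 subsampling iterations, 25
confounding iterations per mode), and small hand-built fixtures for every
closed-form oracle. The complete suite finishes in roughly ten minutes on
one core; `scripts/acceptance.R` takes under a minute.

## Known limitations

The engine's method-of-moments dispersions are noisier than shrinkage
estimators, so at very small replicate numbers its Wald tests are less
powerful than the field's standard tools (the balanced-subsampling
diagnostic inherits this). The shifted-log VST does not remove the
mean–variance trend at low counts, which is why the variance contrast is
interpreted on scheme differences rather than absolute SDs. The Cox
module handles a single binary covariate — by design, since the analyses
are pairwise against the control — and offers no frailty or cluster
terms. Dose accounting assumes intake measurements cover the exposure
window on a fixed grid.
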