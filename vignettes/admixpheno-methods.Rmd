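---
title: "Models and methods: supervised admixture and ancestry-phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: supervised admixture and ancestry-phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixpheno)
```

## The admixture model

For a biallelic marker $j$ with counted-allele frequency $p_{kj}$ in source
population $k$ ($k = 1,\dots,K$; here AFR/EUR/NAM), an individual with
ancestry vector $q$ on the $K$-simplex has expected allele frequency
$f_j = \sum_k q_k p_{kj}$, and under Hardy–Weinberg and linkage equilibrium
the dosage $g_j \in \{0,1,2\}$ is $\mathrm{Binomial}(2, f_j)$. The
log-likelihood over markers is

$$\ell(q) = \sum_{j\ \mathrm{observed}} \big[\, g_j \log f_j + (2-g_j)\log(1-f_j) \,\big],$$

the likelihood shared by STRUCTURE and ADMIXTURE. Missing genotypes
contribute no terms (the likelihood factorises over markers, so dropping a
marker is the maximum-likelihood treatment of ignorable missingness; no
imputation is attempted).

`estimate_q_fixedP()` maximises $\ell$ with the multiplicative EM update

$$q_k \leftarrow \frac{q_k}{2J'} \sum_j \Big[\, g_j \frac{p_{kj}}{f_j} +
(2-g_j)\frac{1-p_{kj}}{1-f_j} \,\Big],$$

over the $J'$ observed markers. The update preserves
$\sum_k q_k = 1$ identically and never decreases $\ell$; both properties
are enforced as tests (monotonicity to $10^{-10}$, simplex sum to
$10^{-8}$), and the converged solution is checked against an exhaustive
simplex grid search at step 0.005 on small instances.

### Supervision and the two fitting modes

No genotyped Native American reference panel is assumed: reference
individuals are *simulated* as $\mathrm{Binomial}(2, p_{kj})$ draws from
published-style frequencies (`simulate_reference_panel()`), which is all
the likelihood ever sees of a reference individual. Their ancestry is
fixed at unit vectors. `supervised_admixture()` then offers:

* **`joint` (default).** Block relaxation alternating (a) one EM update of
  every cohort individual's $q$ and (b) an EM update of $P$ using all
  individuals, where a reference individual of population $k$ contributes
  its genotypes to row $k$ only. This is the supervised ADMIXTURE
  analysis: the cohort genotypes sharpen the frequency estimates.
  Convergence is declared on the relative change of the *total*
  log-likelihood.
* **`fixed_P`.** $P$ frozen at the panel's empirical frequencies;
  individuals solved independently. With 1000 reference individuals per
  population the two modes agree to about 0.02–0.03 in the ancestry
  proportions (a tested invariant), and `fixed_P` is faster for large
  cohorts.

Numerical choices: frequencies are clipped to
$[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 10^{-6}$ so log terms
stay finite when simulated panels produce empirical frequencies of 0 or 1;
$q$ starts uniform at $1/K$ (which also makes the fit equivariant under
relabelling of populations, a tested property); convergence is a relative
log-likelihood change below $10^{-6}$ with a 2000-iteration cap —
non-convergence is flagged on the returned object, not raised. An
individual whose observed markers carry identical frequencies in all
populations is non-identifiable; the single-individual interface refuses
such input with an explicit error, and the cohort interface flags the
individual. The default tolerance is sized for cohort analysis; tests that
compare against the grid-search oracle tighten it to $10^{-12}$ so the
comparison sees the converged optimum rather than the stopping rule.

With 87 ancestry-informative markers the per-individual estimation error
is genuinely non-negligible: mean absolute error of the Native American
proportion is about 0.06, and components whose true value is near the
simplex boundary (African ancestry, mean 0.07) acquire a small upward
bias because estimates cannot be negative. Both effects shrink as the
panel grows (error decreases monotonically over 20 → 87 → 500 markers, a
tested property) and both are visible in the acceptance report.

## Quality control

Marker QC removes indels, markers with missing rate above 5%, markers
never called, and markers failing an exact Hardy–Weinberg test at
$p \le 5\times10^{-8}$. The HWE threshold is deliberately loose: admixture
itself (the Wahlund effect) displaces genotype frequencies at
ancestry-informative markers, so a conventional threshold would discard
exactly the informative markers; only gross genotyping artifacts should
fail. The exact test enumerates heterozygote counts conditional on the
allele counts, two-sided by probability mass (the Wigginton–Cutler–
Abecasis construction); a chi-square variant is available via
`method = "chisq"`. Marker missingness is computed on the full matrix
while the HWE statistic excludes individuals above the individual
missingness cap, so a handful of badly genotyped individuals cannot fail
an otherwise sound marker; the QC report records a reason per removed
marker. Individual QC removes individuals with more than 5% missing
genotypes. Marker filtering is idempotent (tested).
`pairwise_r2()` summarises same-chromosome squared correlations as a
linkage-equilibrium check.

## The synthetic cohort generator

`cohort_config()` holds every generator parameter; its defaults describe
the study conditions the package is exercised under, and they are fixed
once here rather than tuned per analysis:

* **Ancestry.** Dirichlet with method-of-moments parameters: means
  (NAM, EUR, AFR) = (0.502, 0.427, 0.071); the concentration is the mean
  of the per-component values implied by target SDs (0.164, 0.168,
  0.062). A single Dirichlet concentration cannot honour three arbitrary
  SDs, so the realised SDs land near 0.146/0.145/0.075 — slightly
  tighter than the targets for the two major components. One visible
  consequence: ancestry-extreme subgroups (NAM below 20% or above 80%)
  are somewhat rarer than in real admixed cohorts, whose estimated
  ancestries also carry measurement-error spread.
* **Demographics.** 72.7% women; age normal by sex
  (men 40.1 ± 16.8, women 39.2 ± 14.5, truncated to 18–90).
* **Covariates** (declared, configurable placeholders — marginals only):
  daily exercise 25%, high blood pressure 17%, at-least-high-school
  education 45%, acculturation score normal 2.0 ± 0.9 truncated to the
  instrument's 1–4 range, fraction of life in the US Beta-matched to
  0.55 ± 0.25, alcohol never/past/current 45/20/35%, smoking 60/20/20%.
  Covariates are drawn independently of ancestry, so crude and adjusted
  contrasts nearly coincide in synthetic data — unlike real cohorts,
  where ancestry-correlated environment inflates crude contrasts. This
  is the main feature of real data the generator deliberately does not
  emulate.
* **BMI.** Gaussian linear model, residual SD 6.5 kg/m², truncated below
  at 12 kg/m² to exclude physiologically absurd values; ancestry effects
  −1.34 (NAM) and +4.31 (AFR) kg/m² per unit ancestry; intercept 28.2
  placing the mean near 30.5 kg/m².
* **Diabetes.** Logistic model with merged-BMI-category main effects and
  *category-specific* Native American ancestry slopes — the generative
  form of an ancestry×BMI interaction: per-10% odds ratios 0.951
  (BMI < 25), 1.190 ([25, 35)), 1.033 (≥ 35). Category main effects
  (−0.316, 1.028 on the log scale) are placed so the cohort-level odds
  ratios versus normal weight are near 2.2 and 4.2, and the intercept
  (−4.6, set once against the ~13% prevalence target) yields ≈13%
  diabetes prevalence. Age (0.05/yr), high blood pressure (0.8),
  exercise (−0.3), acculturation (−0.15) and small smoking/alcohol terms
  complete the linear predictor.
* **Diet.** Scores 1–5 with 46% non-response, independent of ancestry by
  default ($r^2 \approx 0$); `diet_ancestry_weight` loads the latent
  score on standardised NAM ancestry for confounding experiments.

All draws flow from one seed; equal configurations give byte-identical
cohorts (tested). Genotypes, when requested, are
$\mathrm{Binomial}(2, \sum_k q_{ik} p_{kj})$ — the generative counterpart
of the estimation likelihood, with no linkage disequilibrium, family
structure or genotyping-batch structure; passing tests therefore
demonstrate correctness of the estimators under the model's own
assumptions, not robustness to LD or cryptic relatedness.

### What the cohort table represents

The per-individual table mirrors a study analysis file in which the
ancestry columns are themselves admixture *estimates*. The generator's
phenotype models act directly on the table's ancestry columns, so
refitting on that table recovers the generating coefficients (tested at
n = 20000). Re-estimating ancestry from synthetic genotypes and fitting
on the re-estimates instead adds a second layer of measurement error and
attenuates coefficients — a real errors-in-variables phenomenon worth
studying, but not the configuration under which the generating values
are recoverable. The acceptance script therefore reports association
quantities from the cohort table and quantifies the genotype round trip
separately (mean ancestry proportions and recovery MAE); the
`run_pipeline()` orchestration, by contrast, is strictly end-to-end and
feeds re-estimated ancestries downstream.

## Association models

* **BMI** (`fit_bmi_model`): OLS of BMI on per-unit NAM and AFR ancestry
  plus daily exercise, age, acculturation, education, fraction of life in
  the US, and alcohol and smoking (indicator-coded, reference "never").
  The combined stratum also adjusts for sex. European ancestry never
  enters any model: in a three-way admixed cohort with a small African
  component it is nearly collinear with Native American ancestry
  ($q_{EUR} \approx 1 - q_{NAM}$), and a model containing both is
  uninterpretable.
* **Diabetes** (`fit_diabetes_model`): maximum-likelihood logistic
  regression (IRLS) on per-unit NAM ancestry plus daily exercise, age,
  high blood pressure and acculturation; BMI only when `control_bmi`;
  strata involving men add alcohol and smoking. Quasi-complete separation
  and IRLS non-convergence raise explicit errors — Wald intervals from a
  separated fit would be meaningless, and silent penalisation would
  change the estimand.
* Every fit reports complete-case `n_used`, Wald 95% intervals
  ($\hat\beta \pm 1.96\,\mathrm{SE}$, exponentiated for odds ratios),
  two-sided p-values, and exact collinearity is an error naming the
  offending terms. Odds ratios are reported per 10% ancestry via
  $\exp(0.1\beta)$ (`or_per_increment`), the convention that makes
  per-unit coefficients readable.

Descriptive operations use the field-standard tests: two-sided Wilcoxon
rank-sum (normal approximation with continuity and tie correction) for
continuous contrasts, two-sided Fisher exact tests (probability-mass
definition, delegated to `stats::fisher.test`, with the cross-product
odds ratio reported) for binary ones; `gender_descriptives()` renders the
conventional first-table layout with percentages at one decimal.

## Interaction and power

`interaction_lrt()` compares nested logistic models in women: merged BMI
category (normal / overweight–obese / severe) plus ancestry and
covariates, versus the same model plus ancestry×category terms for the
two non-reference categories. The statistic $-2(\ell_0-\ell_1)$ is
referred to $\chi^2_2$. Design choices: the merge of overweight and obese
is an explicit, configuration-level decision justified by
`wald_equality_test()` on the category coefficients (the data-driven
merge is reproducible but not silently automatic); the reference category
is normal weight; interactions involve Native American ancestry only by
default (2 df), with African-ancestry interactions behind `include_afr`
(4 df) since the evidence for which variables to interact is equivocal.
Under a no-interaction generator the test's type-I error is 0.05 ± 0.02
at 1000 replicates (tested).

`bootstrap_power()` estimates power at a smaller sample size by
resampling individuals with replacement from the observed cohort,
refitting, and recording the rejection frequency for the monitored term.
Replicates that fail (separation, lost cases in a small resample) are
counted as non-significant and tallied separately — discarding them would
bias power upward. The estimate is conditional on the realised cohort:
its replicate-to-replicate mean tracks the closed-form z-test power at
the same effect and n (tested within 0.05 in the one-covariate linear
case), but across regenerated cohorts it inherits the sampling
variability of the realised effect size, which is visible across
acceptance-script seeds.

`coefficient_equality_z()` with `se_from_ci()` reproduces
between-stratum coefficient comparisons directly from printed estimates
and Wald intervals (log scale for odds ratios).

## Problem sizes

The test suite exercises the estimators at the sizes where their
guarantees are sharpest per CPU-second: exhaustive oracle enumeration for
the exact tests (all HWE configurations to n = 50, all 2×2 tables to
n = 20), grid-search comparison on K ≤ 3, J ≤ 12 instances, round-trip
recovery on 500 × 87 cohorts, coefficient recovery at n = 20000, 1000
type-I replicates for the interaction LRT at n = 1200, and 400–500
bootstrap replicates for power calibration. The acceptance script runs
the pipeline at the full study scale (N = 4662, 87 markers, 3 × 1000
reference individuals, 500 power replicates).

## Known limitations

* No linkage disequilibrium, relatedness or genotyping-batch effects in
  the generator; QC code paths for failed calls and indels are exercised
  with constructed defects.
* Small-proportion ancestry components are estimated with upward bias at
  87 markers (boundary effect); the acceptance report shows it on the
  African component.
* Wald intervals only; profile-likelihood intervals and penalised
  logistic fits are out of scope, as are permutation interaction tests
  and spline/continuous-BMI interaction surfaces.
* Covariate marginals are declared placeholders, not estimates of any
  real cohort's distributions; conclusions about covariate behaviour in
  real data should not be read off the generator.
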