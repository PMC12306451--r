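---
title: "Methods: gene-smoking interaction analysis for AMD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-smoking interaction analysis for AMD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`amdgxe` implements a pipeline for asking whether smoking modifies the
genetic risk of age-related macular degeneration (AMD): GWAS meta-analysis,
Bayesian fine-mapping, polygenic scoring, Cox interaction models on both the
additive and multiplicative scales, risk-prediction increment metrics,
per-variant contingency analysis, and complement-protein group contrasts.
This vignette explains the statistical models, the defaults and why they were
chosen, and what the synthetic cohort generator does and does not emulate.

## Meta-analysis

Per-study summary statistics are harmonized to a common effect-allele coding
(sign flips for swapped alleles, strand complements resolved where
unambiguous, palindromic A/T and C/G variants dropped as conservative
practice) and combined with the sample-size-weighted fixed-effect scheme:
$z_{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}$ with $w_i =
\sqrt{n_{eff,i}}$ and $n_{eff} = 4/(1/\text{cases} + 1/\text{controls})$,
the standard effective size of a case-control study. Per-variant $z$ is
$\hat\beta/se$. We deliberately do not compute inverse-variance weights or
heterogeneity statistics; the sample-size scheme is robust to
study-specific effect scales, which is why it is the convention for
case-control consortia with heterogeneous phenotyping.

Independent loci are extracted by greedy distance clumping (default
significance $5\times10^{-8}$, suppression window $\pm 500$ kb). Distance
clumping needs no LD reference panel; it is a coarser notion of independence
than LD clumping or conditional analysis, and the locus count it yields
should be read with that in mind.

## Fine-mapping

Within each locus we compute Wakefield's approximate Bayes factor from the
marginal estimate and its standard error,
$$\log ABF = \tfrac12\log\frac{V}{V+W} + \frac{z^2}{2}\frac{W}{V+W},
\qquad V = se^2,$$
with prior effect variance $W = 0.04$ (prior SD 0.2 on the log-odds scale,
the standard choice for binary traits). Posterior probabilities assume a
single causal variant per locus with a uniform prior:
$pp_j = ABF_j / \sum_k ABF_k$, evaluated in the log domain with a
logsumexp normalization because real AMD loci reach $|z| \approx 40$, far
beyond the range where $\exp(z^2/2)$ is representable.

Multi-signal methods (stochastic-search and sum-of-single-effects samplers)
are not reimplemented; their per-variant posterior files can be read with
`read_pp_file()` and intersected with the ABF posteriors by
`consensus_causal()`, which designates a variant causal only when its
posterior exceeds the threshold (default 0.8, strict) in **every** supplied
method.

## Polygenic score

`qc_filter()` retains panel variants with INFO > 0.9, MAF ≥ 0.01 and an
allele-frequency discrepancy below 0.2 against a reference panel. The MAF
rule is written as *excluding* rare variants; a published description of
this filter can be read in the opposite direction, but retaining only
sub-1% variants would contradict both the panel restriction and all
polygenic-score practice, so exclusion of rare variants is the default and
the direction is configurable.

The raw score is the *sum* of effect-allele dosages weighted by per-variant
effects (not the per-variant average; the choice affects only the raw
scale). Scores are standardized to mean 0, SD 1 over the scored cohort, so
downstream hazard ratios are per SD of PRS. For fully synthetic runs a
clump-and-threshold weight deriver stands in for external
continuous-shrinkage weights: index variants at the significance threshold
keep their meta-analysis effects.

## Cox interaction models

The central model is a Cox proportional-hazards regression with smoking
(ever/never), standardized PRS, their product, and an adjustment set. Ties
use the Efron approximation. With $b_1$ (smoking), $b_2 c$ (PRS times the
modifier contrast $c$, default 1 SD) and $b_3 c$ (product), the joint
hazard ratios $HR_{10}=e^{b_1}$, $HR_{01}=e^{b_2 c}$,
$HR_{11}=e^{b_1+b_2c+b_3c}$ give the additive-scale statistics

* $RERI = HR_{11}-HR_{10}-HR_{01}+1$ (zero under additive excess hazards),
* $AP = RERI/HR_{11}$,
* $SI = (HR_{11}-1)/((HR_{10}-1)+(HR_{01}-1))$ (one under additivity),

and the multiplicative interaction is $e^{b_3}$ with its Wald test.
Confidence intervals come from the multivariate delta method on
$(b_1, b_2, b_3)$ with the fitted covariance (the Hosmer–Lemeshow
approach); the SI interval is computed on the log scale, and SI is flagged
undefined when its denominator or numerator is non-positive (e.g. at the
global null, where SI is 0/0). The per-SD contrast is a genuine design
choice: published interaction tables rarely state whether additive
statistics were evaluated per SD or on a dichotomized score, so the
contrast is an explicit argument.

`run_model_ladder()` fits a nested adjustment ladder (unadjusted; + age,
sex; + BMI; + alcohol for the synthetic covariates) on one shared
complete-case analysis set determined from the fullest model, so
coefficients are comparable across rows. Events within six months of
baseline are excluded by default — early conversions are plausibly
prevalent disease — and retained under `include_short_followup` as a
sensitivity analysis. Diagnostics per fit: Harrell's C with SE and the
global Schoenfeld-residual test of proportional hazards.

## Prediction metrics

AUCs use the Mann–Whitney estimator (ties count one half) with DeLong
structural-component variances; `delong_compare()` implements the paired
DeLong test of the AUC increment. The bootstrap interval for the increment
resamples cases and controls separately (percentile interval; the simplest
defensible choice, and the method flag allows revisiting). NRI comes in
continuous form (any risk movement) and categorical form; the categorical
cut-offs are a *required* argument with no default, because a categorical
NRI without its categories is irreproducible. IDI is the difference of
discrimination slopes. The prevalence-by-PRS-percentile curve bins the
standardized score into equal-count bins per exposure stratum with binomial
standard errors; empty bins are NA, never zero.

## Variant-level analysis

`contingency_2x2()` compares exposed risk-genotype carriers with unexposed
non-carriers: OR $= ad/bc$ with a Wald log-scale interval, and Pearson's
chi-squared **with** Yates continuity correction — the default behavior of
the base-R test; on the published count sets the corrected statistic
reproduces the printed values where the uncorrected one does not. Zero
cells fall back to the Haldane–Anscombe 0.5 correction, flagged. The Cox
scan fits the interaction model per variant with per-allele dosage coding
and a one-allele contrast; non-convergent variants are flagged, not fatal.

## Protein contrasts

Proteins are standardized cohort-wide and modelled as the predictor in a
covariate-adjusted logistic regression of group membership (per-SD odds
ratios), across five comparisons built from the median-PRS split crossed
with smoking. Bonferroni correction is applied within each contrast family
(0.05/28 = 0.0018 for the packaged 28-protein complement panel); whether
the five contrasts should instead share one family is genuinely open, and
the per-contrast choice is the more conservative reporting unit here since
each contrast answers a distinct question. Perfect separation falls back to
a weak ridge-penalized Newton fit with the interval suppressed and a flag —
a pragmatic alternative to Firth regression that keeps the estimate finite
without overstating certainty.

## The synthetic cohort generator

Generators are pure functions of a scenario and a seed. Genotypes are
Binomial(2, MAF) under Hardy–Weinberg equilibrium, independent by default,
with an optional AR(1) haplotype correlation for fine-mapping tests. Event
times are exponential with hazard
$\lambda_0\exp(\beta_P P + \beta_S S + \beta_{PS} PS + \text{covariates})$
and fixed administrative censoring: a constant baseline hazard makes
proportional hazards hold exactly, matching the setting in which the
interaction statistics are interpretable. A two-component option
($\exp(\beta_P P) + \exp(\beta_S S) - 1$) produces additive excess hazards
— nonzero RERI with a null product term — for testing the additive
statistics specifically.

Defaults are the conditions of the motivating cohort analysis: hazard
ratio 1.35 per SD of PRS, 1.12 for ever smoking, 1.08 for the
multiplicative interaction, 60% smoking prevalence, 16.7 years of
follow-up, and a baseline hazard of 0.00074/year calibrated so cumulative
incidence is about 2%. Covariate effects (0.09/year of age, 0.26 for
female sex, 0.02/BMI unit) reproduce the case–control age, sex and BMI
contrasts typical of an AMD cohort and give the baseline risk model
realistic discrimination. Summary statistics are drawn
$\hat\beta \sim N(\beta, se^2)$ with $se = 1/\sqrt{n_{eff}\cdot 2f(1-f)}$.
Proteins are standard normal plus group-specific latent shifts.

The generator does **not** emulate linkage disequilibrium maps, biobank
ascertainment, array QC artifacts, age-varying hazards, or non-linear PRS
effects. Tests passing on synthetic cohorts therefore validate the
estimators and their calibration under the assumed model, not robustness to
those real-data complications.

## Numerical and testing choices

Simulation-based checks in the test suite use cohort sizes of
20,000–50,000 with 100–1000 replicates — large enough that delta-method
intervals are in their asymptotic regime while the whole suite stays
quick to run; the acceptance script's single end-to-end run uses the full
331,281-individual cohort size. Quantile stratification breaks ties by a
stable sort on individual ID so group sizes are deterministic. p-values of
exactly zero in input summary statistics are clamped to the smallest
positive double rather than rejected, since underflow is routine in large
GWAS. All Bayes-factor arithmetic stays in the log domain.

## Known limitations

Distance clumping is a stand-in for LD-aware independence; the ABF model
assumes one causal variant per locus; the clump-and-threshold weights are a
fallback, not a substitute for shrinkage-based weights on real data;
competing risks, time-varying effects and sex-specific interactions are out
of scope.
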