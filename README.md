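# amdgxe

Gene–smoking interaction analysis for age-related macular degeneration
(AMD), packaged as a reusable, fully tested R pipeline.

Smoking is the leading modifiable risk factor for AMD, and genetic
predisposition — dominated by complement-pathway loci such as *CFH* and
*CFI* — is the strongest fixed one. The question this package addresses is
whether the two *interact*: does smoking multiply the hazard of high
polygenic risk beyond what either factor contributes alone? Answering it
requires a chain of standard but fiddly machinery, each piece of which is
implemented and unit-tested here:

1. **Meta-analysis** of per-study GWAS summary statistics, sample-size
   weighted in the METAL convention:
   `z_meta = Σ wᵢ zᵢ / √(Σ wᵢ²)`, `wᵢ = √n_eff,i`,
   `n_eff = 4/(1/cases + 1/controls)`, with allele harmonization and
   distance clumping of independent loci.
2. **Fine-mapping** by Wakefield's approximate Bayes factor,
   `log ABF = ½ log(V/(V+W)) + z²W/(2(V+W))`, single-causal-variant
   posteriors, and a strict cross-method consensus filter (PP > 0.8 in
   every method).
3. **Polygenic scoring**: variant QC (panel / INFO / MAF / frequency
   discrepancy), dosage-weighted sums with allele alignment, per-SD
   standardization, quantile stratification.
4. **Cox interaction models** with additive-scale statistics
   `RERI = HR₁₁ − HR₁₀ − HR₀₁ + 1`, `AP = RERI/HR₁₁`,
   `SI = (HR₁₁−1)/((HR₁₀−1)+(HR₀₁−1))` and the multiplicative product-term
   HR, all with delta-method confidence intervals, over a nested covariate
   ladder with PH diagnostics and Harrell's C.
5. **Prediction metrics**: Mann–Whitney AUC with DeLong variances, the
   paired DeLong test, bootstrap ΔAUC, continuous/categorical NRI, IDI,
   and the prevalence-by-PRS-percentile curve.
6. **Per-variant analysis**: genotype×smoking 2×2 tables (Wald OR, Yates
   corrected χ²) and a per-variant Cox interaction scan.
7. **Protein contrasts**: covariate-adjusted logistic regressions of
   28 complement-pathway proteins across PRS/smoking groups with
   Bonferroni control (0.05/28 = 0.0018).

A synthetic cohort generator (`simulation_scenario()`, `simulate_*()`)
reproduces the statistical structure the analysis assumes — HWE genotypes,
an exponential proportional-hazards event model with a PRS×smoking term,
administrative censoring, covariates, protein shifts — so the whole
pipeline is testable without individual-level biobank data.

## Worked example

```r
library(amdgxe)

scenario <- simulation_scenario(n_individuals = 20000, n_variants = 20, seed = 42)
res <- run_pipeline(scenario)

res$ladder_table[2, c("hr_smoke", "hr_prs", "reri", "ap", "si", "hr_mult", "p_mult")]
#>    hr_smoke   hr_prs      reri         ap      si  hr_mult    p_mult
#> 2 0.9827026 1.422054 0.1287734 0.08397187 1.31815 1.097373 0.3764828
```

Model 1 (age- and sex-adjusted) on this cohort estimates a PRS hazard
ratio of 1.42 per SD and a positive additive interaction — RERI 0.13 means
the joint smoking-plus-high-PRS hazard ratio exceeds the sum of the two
separate excess hazards by 0.13, with a synergy index of 1.32. The
multiplicative interaction HR of 1.10 is not significant here (p = 0.38):
with 20,000 individuals and ~390 events only large product terms are
detectable, and the generator's true interaction HR is 1.08. The smoking
main-effect estimate (0.98 against a true 1.12) shows the sampling noise
at this event count.

```r
res$auc_comparison[c("auc_base", "auc_full", "delta_auc", "p")]
#> $auc_base  0.6947504
#> $auc_full  0.7220047
#> $delta_auc 0.02725434
#> $p         0.0001930719
```

Adding the PRS to an age/sex/smoking risk model raises the AUC by 0.027, a
decisive paired DeLong test even at this scale.

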