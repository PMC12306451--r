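# End-to-end synthetic pipeline: generate a cohort and per-study summary
# statistics, meta-analyze, fine-map, derive weights, score, fit the
# interaction ladder, compute prediction metrics, scan variants, and contrast
# proteins. Exercises every stage the way a real-data run would.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates per-study summary statistics and an individual-level cohort from
#' one scenario, then runs: sample-size-weighted meta-analysis; distance
#' clumping; ABF fine-mapping with the consensus filter; clump+threshold
#' weight derivation and PRS scoring; the Cox interaction model ladder;
#' DeLong / bootstrap / NRI-IDI prediction metrics (logistic risk models with
#' and without the PRS); the per-variant interaction scan and contingency
#' tables; and the protein panel contrasts.
#'
#' @param scenario A \code{\link{simulation_scenario}}.
#' @param n_studies Number of discovery studies to simulate.
#' @param per_study_n 2-column matrix of per-study (cases, controls).
#' @param config A \code{\link{run_config}}.
#' @param nri_cuts Risk-category cut-offs for the categorical NRI.
#' @param n_scan_variants Number of top variants carried into the per-variant
#'   scan (default 4).
#' @param bootstrap_iters Bootstrap iterations for the delta-AUC interval.
#' @return List with elements \code{cohort}, \code{meta}, \code{loci},
#'   \code{posteriors}, \code{causal}, \code{weights}, \code{scores},
#'   \code{ladder}, \code{ladder_table}, \code{auc_comparison},
#'   \code{bootstrap_delta}, \code{reclassification}, \code{variant_scan},
#'   \code{contingency}, \code{protein_results}, \code{seed}.
#' @export
run_pipeline <- function(scenario,
                         n_studies = 4,
                         per_study_n = cbind(c(16144, 6631, 3685, 11690),
                                             c(17832, 272817, 52952, 430340)),
                         config = run_config(seed = scenario$seed),
                         nri_cuts = c(0.01, 0.05),
                         n_scan_variants = 4,
                         bootstrap_iters = 200) {
  seed <- config$seed
  studies <- simulate_summary_stats(scenario, n_studies, per_study_n,
                                    seed = seed)
  meta <- meta_analyze(studies)
  # per-variant meta SE back-derived from z and the weighted beta
  meta$se_meta <- ifelse(meta$z_meta != 0, abs(meta$beta_meta / meta$z_meta), NA)
  loci <- significant_loci(meta, threshold = config$significance_threshold)

  posteriors <- if (nrow(loci)) {
    finemap_loci(meta, loci, beta_col = "beta_meta", se_col = "se_meta")
  } else list()
  abf_pp <- unlist(lapply(posteriors, function(lp)
    stats::setNames(lp$pp, lp$variant_ids)))
  causal <- if (length(abf_pp))
    consensus_causal(list(abf = abf_pp), threshold = config$pp_threshold)
  else character(0)

  weights <- clump_threshold_weights(meta,
                                     p_cut = config$significance_threshold)
  cohort <- simulate_survival(scenario)
  dosage_cols <- scenario$variant_ids
  dos <- as.matrix(cohort[, dosage_cols, drop = FALSE])
  rownames(dos) <- cohort$individual_id
  scores <- if (nrow(weights)) compute_prs(dos, weights) else NULL
  if (!is.null(scores)) cohort$prs <- scores$z_score

  ladder <- run_model_ladder(cohort, config = config)
  ltab <- ladder_table(ladder)

  # prevalent-risk logistic models: baseline covariates vs + PRS
  base_fit <- stats::glm(event ~ age + female + smoking, data = cohort,
                         family = stats::binomial())
  full_fit <- stats::glm(event ~ age + female + smoking + prs, data = cohort,
                         family = stats::binomial())
  risk_base <- stats::fitted(base_fit)
  risk_full <- stats::fitted(full_fit)
  auc_cmp <- delong_compare(risk_base, risk_full, cohort$event)
  boot <- bootstrap_delta_auc(risk_base, risk_full, cohort$event,
                              iters = bootstrap_iters, seed = seed)
  reclass <- nri_idi(risk_base, risk_full, cohort$event, cuts = nri_cuts)

  scan_vars <- if (length(causal)) utils::head(causal, n_scan_variants)
               else utils::head(weights$variant_id, n_scan_variants)
  scan <- variant_interaction_scan(cohort, scan_vars)
  contingency <- contingency_table_scan(cohort, scan_vars)

  groups <- build_groups(cohort)
  effects <- scenario$protein_effects
  prot <- simulate_proteins(cohort, effects, seed = seed + 7L)
  prot_res <- run_panel(prot, groups,
                        covariate_table = cohort[, c("age", "female", "bmi",
                                                     "alcohol")],
                        alpha = config$alpha)

  list(cohort = cohort, meta = meta, loci = loci, posteriors = posteriors,
       causal = causal, weights = weights, scores = scores, ladder = ladder,
       ladder_table = ltab, auc_comparison = auc_cmp, bootstrap_delta = boot,
       reclassification = reclass, variant_scan = scan,
       contingency = contingency, protein_results = prot_res, seed = seed)
}
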