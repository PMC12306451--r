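# Cox proportional-hazards interaction analysis: model fitting with
# diagnostics, additive (RERI / AP / SI) and multiplicative interaction
# statistics with delta-method confidence intervals, the nested covariate
# ladder, stratified train/test splitting, and cumulative incidence curves.

#' Define a covariate-adjustment model
#'
#' @param level Integer ladder level (0-3 in the standard ladder).
#' @param covariates Character vector of adjustment covariate names.
#' @return List of class \code{model_spec}.
#' @export
model_spec <- function(level, covariates = character(0)) {
  structure(list(level = as.integer(level), covariates = covariates),
            class = "model_spec")
}

#' Default nested model ladder for synthetic cohorts
#'
#' Model 0 is unadjusted; Model 1 adds age and sex; Model 2 adds BMI;
#' Model 3 adds alcohol status. The sets are nested, mirroring the
#' increasing-adjustment design of biobank interaction analyses.
#'
#' @return List of four \code{\link{model_spec}} objects.
#' @export
default_model_ladder <- function() {
  list(model_spec(0L),
       model_spec(1L, c("age", "female")),
       model_spec(2L, c("age", "female", "bmi")),
       model_spec(3L, c("age", "female", "bmi", "alcohol")))
}

#' Fit a Cox proportional-hazards model
#'
#' Wraps \code{survival::coxph} (Efron tie handling) and attaches the
#' diagnostics the interaction analysis reports: Harrell's C with its
#' standard error and the global Schoenfeld-residual test of the
#' proportional-hazards assumption.
#'
#' @param cohort Cohort data.frame with \code{time} (> 0) and \code{event}
#'   columns.
#' @param formula_terms Character vector of right-hand-side terms, e.g.
#'   \code{c("smoking", "prs", "smoking:prs", "age")}.
#' @return Object of class \code{cox_fit}: \code{coefficients},
#'   \code{covariance}, \code{loglik}, \code{c_index}, \code{c_index_se},
#'   \code{ph_global_p}, \code{n}, \code{n_events}, and the underlying
#'   \code{fit}.
#' @export
fit_cox <- function(cohort, formula_terms) {
  if (any(cohort$time <= 0)) stop("all follow-up times must be positive")
  if (sum(cohort$event) < 1) stop("no events in cohort")
  vars <- unique(unlist(strsplit(formula_terms, ":", fixed = TRUE)))
  for (v in vars) {
    col <- cohort[[v]]
    if (is.null(col)) stop("covariate not found: ", v)
    if (length(unique(col)) < 2) stop("constant covariate: ", v)
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(formula_terms, collapse = " + ")))
  fit <- survival::coxph(f, data = cohort, ties = "efron")
  if (any(is.na(stats::coef(fit))))
    stop("Cox model did not yield estimates for: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  conc <- fit$concordance
  zph <- tryCatch(survival::cox.zph(fit), error = function(e) NULL)
  ph_p <- if (is.null(zph)) NA_real_ else zph$table["GLOBAL", "p"]
  structure(list(coefficients = stats::coef(fit), covariance = stats::vcov(fit),
                 loglik = fit$loglik[2],
                 c_index = unname(conc["concordance"]),
                 c_index_se = unname(conc["std"]),
                 ph_global_p = ph_p, n = fit$n, n_events = fit$nevent,
                 fit = fit),
            class = "cox_fit")
}

#' Additive and multiplicative interaction statistics from a Cox fit
#'
#' With \eqn{b_1} the exposure coefficient, \eqn{b_2} the modifier
#' coefficient times the contrast, and \eqn{b_3} the product-term coefficient
#' times the contrast, the joint hazard ratios are \eqn{HR_{10} = e^{b_1}},
#' \eqn{HR_{01} = e^{b_2}}, \eqn{HR_{11} = e^{b_1+b_2+b_3}}, and
#' \deqn{RERI = HR_{11} - HR_{10} - HR_{01} + 1,\quad AP = RERI / HR_{11},}
#' \deqn{SI = (HR_{11} - 1) / ((HR_{10} - 1) + (HR_{01} - 1)).}
#' Confidence intervals use the multivariate delta method on
#' \eqn{(b_1, b_2, b_3)} with the fit covariance (Hosmer-Lemeshow approach);
#' the SI interval is computed on the log scale. The multiplicative
#' interaction is \eqn{e^{b_3}} with its Wald interval and p-value. When the
#' SI denominator's sign is ambiguous (crosses 0) SI is flagged undefined.
#'
#' @param fit A \code{\link{fit_cox}} result.
#' @param term_exposure,term_modifier,term_product Coefficient names of the
#'   exposure, modifier, and product term.
#' @param contrast_sd Modifier contrast in modifier units (default 1, i.e.
#'   1 SD of a standardized PRS).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class \code{interaction_result}: \code{hr_exposure},
#'   \code{hr_modifier}, \code{hr11}, \code{reri}, \code{ap}, \code{si},
#'   \code{hr_multiplicative} (each a vector \code{estimate/lower/upper}),
#'   \code{p_multiplicative}, \code{si_defined}, \code{contrast_sd}.
#' @export
additive_interaction <- function(fit, term_exposure = "smoking",
                                 term_modifier = "prs",
                                 term_product = "smoking:prs",
                                 contrast_sd = 1, conf_level = 0.95) {
  stopifnot(contrast_sd > 0)
  terms <- c(term_exposure, term_modifier, term_product)
  miss <- setdiff(terms, names(fit$coefficients))
  if (length(miss)) stop("term(s) not in fit: ", paste(miss, collapse = ", "))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  scale <- c(1, contrast_sd, contrast_sd)
  b <- unname(fit$coefficients[terms]) * scale
  sigma <- fit$covariance[terms, terms] * tcrossprod(scale)

  h10 <- exp(b[1]); h01 <- exp(b[2]); h11 <- exp(sum(b))
  reri <- h11 - h10 - h01 + 1
  ap <- reri / h11

  ci_wald <- function(est, se) c(estimate = est, lower = est - zq * se,
                                 upper = est + zq * se)
  # RERI gradient wrt (b1, b2, b3)
  g_reri <- c(h11 - h10, h11 - h01, h11)
  se_reri <- sqrt(drop(t(g_reri) %*% sigma %*% g_reri))
  # AP = 1 - (h10 + h01 - 1) * exp(-(b1+b2+b3))
  e <- exp(-sum(b))
  g_ap <- c(-h10 * e + (h10 + h01 - 1) * e,
            -h01 * e + (h10 + h01 - 1) * e,
            (h10 + h01 - 1) * e)
  se_ap <- sqrt(drop(t(g_ap) %*% sigma %*% g_ap))

  denom <- h10 + h01 - 2
  si_defined <- denom > 0 && h11 > 1
  if (si_defined) {
    si <- (h11 - 1) / denom
    # log SI = log(h11 - 1) - log(h10 + h01 - 2)
    g_lsi <- c(h11 / (h11 - 1) - h10 / denom,
               h11 / (h11 - 1) - h01 / denom,
               h11 / (h11 - 1))
    se_lsi <- sqrt(drop(t(g_lsi) %*% sigma %*% g_lsi))
    si_ci <- c(estimate = si, lower = si * exp(-zq * se_lsi),
               upper = si * exp(zq * se_lsi))
  } else {
    si_ci <- c(estimate = NA_real_, lower = NA_real_, upper = NA_real_)
  }

  hr_ci <- function(logest, se) c(estimate = exp(logest),
                                  lower = exp(logest - zq * se),
                                  upper = exp(logest + zq * se))
  se_b <- unname(sqrt(diag(sigma)))
  p_mult <- unname(2 * stats::pnorm(-abs(b[3] / se_b[3])))

  structure(list(hr_exposure = hr_ci(b[1], se_b[1]),
                 hr_modifier = hr_ci(b[2], se_b[2]),
                 hr11 = h11,
                 reri = ci_wald(reri, se_reri),
                 ap = ci_wald(ap, se_ap),
                 si = si_ci,
                 hr_multiplicative = hr_ci(b[3], se_b[3]),
                 p_multiplicative = p_mult,
                 si_defined = si_defined,
                 contrast_sd = contrast_sd),
            class = "interaction_result")
}

#' Drop events occurring within a short-followup window
#'
#' Removes individuals whose event occurred within \code{months} of baseline
#' (default 6), the primary-analysis exclusion; the sensitivity analysis
#' retains them.
#'
#' @param cohort Cohort data.frame.
#' @param months Exclusion window in months.
#' @return Filtered cohort; the number of removed rows is attached as
#'   attribute \code{"n_excluded"}.
#' @export
exclude_short_followup <- function(cohort, months = 6) {
  drop <- cohort$event == 1 & cohort$time < months / 12
  out <- cohort[!drop, , drop = FALSE]
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' Run the nested covariate model ladder
#'
#' Fits one Cox interaction model per specification. Complete cases are
#' determined once on the fullest model's covariate set, so every ladder
#' level is fitted on the same analysis rows. Unless
#' \code{config$include_short_followup}, events within 6 months of baseline
#' are excluded first.
#'
#' @param cohort Cohort data.frame.
#' @param specs List of \code{\link{model_spec}}s (default
#'   \code{\link{default_model_ladder}}).
#' @param exposure,modifier Column names of the exposure and modifier.
#' @param contrast_sd Modifier contrast for the interaction statistics.
#' @param config A \code{\link{run_config}}.
#' @return List of class \code{model_ladder}: per spec, a list with
#'   \code{spec}, \code{fit} (\code{cox_fit}) and \code{interaction}
#'   (\code{interaction_result}).
#' @export
run_model_ladder <- function(cohort, specs = default_model_ladder(),
                             exposure = "smoking", modifier = "prs",
                             contrast_sd = 1, config = run_config()) {
  all_cov <- unique(unlist(lapply(specs, `[[`, "covariates")))
  missing_cov <- setdiff(all_cov, names(cohort))
  if (length(missing_cov))
    stop("ladder covariate(s) absent from cohort: ",
         paste(missing_cov, collapse = ", "))
  if (!config$include_short_followup) cohort <- exclude_short_followup(cohort)
  use <- stats::complete.cases(cohort[, c("time", "event", exposure, modifier,
                                          all_cov), drop = FALSE])
  analysis <- cohort[use, , drop = FALSE]
  product <- paste(exposure, modifier, sep = ":")
  res <- lapply(specs, function(sp) {
    terms <- c(exposure, modifier, product, sp$covariates)
    fit <- fit_cox(analysis, terms)
    list(spec = sp, fit = fit,
         interaction = additive_interaction(fit, exposure, modifier, product,
                                            contrast_sd = contrast_sd))
  })
  structure(res, class = "model_ladder", n_analysis = nrow(analysis))
}

#' Summarize a model ladder as a results table
#'
#' One row per model with the hazard ratios, additive and multiplicative
#' interaction statistics, PH test p-value and C-index.
#'
#' @param ladder A \code{\link{run_model_ladder}} result.
#' @param block Label for the cohort block (e.g. "full", "train", "test").
#' @return Data.frame, one row per model.
#' @export
ladder_table <- function(ladder, block = "full") {
  rows <- lapply(ladder, function(r) {
    ir <- r$interaction
    data.frame(block = block, model = paste0("Model ", r$spec$level),
               hr_smoke = ir$hr_exposure[["estimate"]],
               hr_smoke_lo = ir$hr_exposure[["lower"]],
               hr_smoke_hi = ir$hr_exposure[["upper"]],
               hr_prs = ir$hr_modifier[["estimate"]],
               reri = ir$reri[["estimate"]], reri_lo = ir$reri[["lower"]],
               reri_hi = ir$reri[["upper"]],
               ap = ir$ap[["estimate"]], ap_lo = ir$ap[["lower"]],
               ap_hi = ir$ap[["upper"]],
               si = ir$si[["estimate"]], si_lo = ir$si[["lower"]],
               si_hi = ir$si[["upper"]],
               hr_mult = ir$hr_multiplicative[["estimate"]],
               hr_mult_lo = ir$hr_multiplicative[["lower"]],
               hr_mult_hi = ir$hr_multiplicative[["upper"]],
               p_mult = ir$p_multiplicative,
               ph_p = r$fit$ph_global_p,
               c_index = r$fit$c_index, c_index_se = r$fit$c_index_se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a cohort into train and test sets, stratified on event status
#'
#' @param cohort Cohort data.frame.
#' @param train_fraction Fraction assigned to the training set, in (0, 1).
#' @param seed Integer seed.
#' @return List with \code{train} and \code{test} data.frames (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(cohort, train_fraction = 0.5, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(as.integer(seed))
  idx_train <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$event),
                             function(i) sample(i, round(train_fraction * length(i)))))
  train <- cohort[sort(idx_train), , drop = FALSE]
  test <- cohort[-sort(idx_train), , drop = FALSE]
  list(train = train, test = test)
}

#' Per-group cumulative incidence curves
#'
#' One minus the Kaplan-Meier survivor function per group, with Greenwood
#' standard errors, evaluated on a common time grid.
#'
#' @param cohort Cohort data.frame (\code{time}, \code{event}).
#' @param group_labels Factor or character vector, one label per row.
#' @param time_grid Numeric vector of evaluation times.
#' @return Data.frame: \code{group}, \code{time}, \code{incidence},
#'   \code{se}.
#' @export
cumulative_incidence <- function(cohort, group_labels, time_grid) {
  if (nrow(cohort) == 0) stop("empty group")
  groups <- split(seq_len(nrow(cohort)), group_labels)
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  rows <- lapply(names(groups), function(g) {
    sub <- cohort[groups[[g]], , drop = FALSE]
    km <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    sm <- summary(km, times = time_grid, extend = TRUE)
    data.frame(group = g, time = sm$time, incidence = 1 - sm$surv,
               se = sm$std.err, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
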