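# Discrimination and reclassification metrics for the PRS increment:
# Mann-Whitney AUC with DeLong structural-component variances, the paired
# DeLong test, stratified bootstrap delta-AUC, categorical/continuous NRI and
# IDI, and the prevalence-by-PRS-percentile curve.

# DeLong structural components. Returns AUC, per-case components V10 and
# per-control components V01, computed with midranks so ties count 1/2.
.delong_components <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  m <- length(cases); n <- length(controls)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(cases, controls), ties.method = "average")
  r_cases <- rank(cases, ties.method = "average")
  r_controls <- rank(controls, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_cases) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_controls) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Mann-Whitney AUC with DeLong standard error
#'
#' The AUC is the Mann-Whitney estimator (ties count one half); the standard
#' error comes from the DeLong structural components.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary outcome (1 = case).
#' @return List with \code{auc} and \code{se}.
#' @export
auc <- function(scores, labels) {
  d <- .delong_components(scores, labels)
  se <- sqrt(stats::var(d$v10) / d$m + stats::var(d$v01) / d$n)
  list(auc = d$auc, se = se)
}

#' DeLong test comparing two paired AUCs
#'
#' Compares the AUCs of a baseline and an augmented risk model evaluated on
#' the same individuals, using the paired DeLong variance of the AUC
#' difference and a two-sided normal p-value.
#'
#' @param scores_base,scores_full Paired risk scores for the two models.
#' @param labels Binary outcome (1 = case).
#' @param conf_level Confidence level for the per-model AUC intervals.
#' @return List of class \code{auc_comparison}: \code{auc_base},
#'   \code{auc_full}, \code{delta_auc}, \code{z}, \code{p}, \code{ci_base},
#'   \code{ci_full}, \code{degenerate} (TRUE when the paired variance is
#'   zero, in which case p is reported as 1).
#' @export
delong_compare <- function(scores_base, scores_full, labels,
                           conf_level = 0.95) {
  stopifnot(length(scores_base) == length(scores_full),
            length(scores_base) == length(labels))
  a <- .delong_components(scores_base, labels)
  b <- .delong_components(scores_full, labels)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  s <- s10 / a$m + s01 / a$n
  var_delta <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- b$auc - a$auc
  degenerate <- var_delta <= .Machine$double.eps
  z <- if (degenerate) 0 else delta / sqrt(var_delta)
  p <- if (degenerate) 1 else 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc_base = a$auc, auc_full = b$auc, delta_auc = delta,
                 z = z, p = p,
                 ci_base = a$auc + c(-1, 1) * zq * sqrt(s[1, 1]),
                 ci_full = b$auc + c(-1, 1) * zq * sqrt(s[2, 2]),
                 degenerate = degenerate),
            class = "auc_comparison")
}

#' Bootstrap the AUC increment
#'
#' Stratified case/control resampling of the paired scores; reports the mean
#' bootstrap AUC difference and its percentile confidence interval.
#'
#' @param scores_base,scores_full Paired risk scores.
#' @param labels Binary outcome (1 = case).
#' @param iters Bootstrap iterations (>= 100; default 1000).
#' @param seed Integer seed.
#' @param conf_level Confidence level of the percentile interval.
#' @return List with \code{mean_delta} and \code{ci} (length-2 vector).
#' @export
bootstrap_delta_auc <- function(scores_base, scores_full, labels,
                                iters = 1000, seed = 1L, conf_level = 0.95) {
  stopifnot(iters >= 100)
  set.seed(as.integer(seed))
  idx_case <- which(labels == 1)
  idx_ctrl <- which(labels == 0)
  deltas <- vapply(seq_len(iters), function(i) {
    idx <- c(sample(idx_case, replace = TRUE), sample(idx_ctrl, replace = TRUE))
    .delong_components(scores_full[idx], labels[idx])$auc -
      .delong_components(scores_base[idx], labels[idx])$auc
  }, 0)
  alpha <- 1 - conf_level
  list(mean_delta = mean(deltas),
       ci = unname(stats::quantile(deltas, c(alpha / 2, 1 - alpha / 2))))
}

#' Net reclassification improvement and integrated discrimination improvement
#'
#' Categorical NRI uses the supplied risk-category cut-offs (no default:
#' published NRIs are irreproducible without their categories, so they must
#' be stated); continuous NRI counts any upward/downward risk change. IDI is
#' the difference of discrimination slopes. Standard errors are asymptotic;
#' event and non-event components are retained and sum to the totals.
#'
#' @param risk_base,risk_full Predicted risks in [0, 1] from the baseline and
#'   augmented models, paired.
#' @param labels Binary outcome (1 = case).
#' @param cuts Strictly increasing category cut-offs in (0, 1), or NULL for
#'   continuous NRI only.
#' @param conf_level Confidence level.
#' @return List of class \code{reclassification_result} with elements
#'   \code{nri_categorical}, \code{nri_continuous}, \code{idi} (each a list:
#'   estimate, se, ci, p, event_component, nonevent_component) and
#'   \code{category_cuts}.
#' @export
nri_idi <- function(risk_base, risk_full, labels, cuts = NULL,
                    conf_level = 0.95) {
  stopifnot(length(risk_base) == length(risk_full),
            length(risk_base) == length(labels))
  if (!is.null(cuts) && is.unsorted(cuts, strictly = TRUE))
    stop("cuts must be strictly increasing")
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ev <- labels == 1

  nri_from_moves <- function(up, down) {
    comp <- function(sel, pos, neg) {
      pu <- mean(pos[sel]); pd <- mean(neg[sel])
      est <- pu - pd
      se <- sqrt((pu + pd - est^2) / sum(sel))
      c(est, se)
    }
    e <- comp(ev, up, down)
    ne <- comp(!ev, down, up)
    est <- e[1] + ne[1]
    se <- sqrt(e[2]^2 + ne[2]^2)
    list(estimate = est, se = se, ci = est + c(-1, 1) * zq * se,
         p = if (se == 0) NA_real_ else 2 * stats::pnorm(-abs(est / se)),
         event_component = e[1], nonevent_component = ne[1])
  }

  up_c <- risk_full > risk_base
  down_c <- risk_full < risk_base
  nri_cont <- nri_from_moves(up_c, down_c)

  nri_cat <- NULL
  if (!is.null(cuts)) {
    cat_base <- findInterval(risk_base, cuts)
    cat_full <- findInterval(risk_full, cuts)
    nri_cat <- nri_from_moves(cat_full > cat_base, cat_full < cat_base)
  }

  delta <- risk_full - risk_base
  idi_est <- mean(delta[ev]) - mean(delta[!ev])
  idi_se <- sqrt(stats::var(delta[ev]) / sum(ev) +
                   stats::var(delta[!ev]) / sum(!ev))
  idi <- list(estimate = idi_est, se = idi_se,
              ci = idi_est + c(-1, 1) * zq * idi_se,
              p = if (idi_se == 0) NA_real_
                  else 2 * stats::pnorm(-abs(idi_est / idi_se)),
              event_component = mean(delta[ev]),
              nonevent_component = -mean(delta[!ev]))

  structure(list(nri_categorical = nri_cat, nri_continuous = nri_cont,
                 idi = idi, category_cuts = cuts),
            class = "reclassification_result")
}

#' Outcome prevalence by PRS percentile and exposure stratum
#'
#' Splits the standardized PRS into equal-count percentile bins and reports
#' outcome prevalence per bin separately for the exposed and unexposed, with
#' binomial standard errors. Empty bins yield NA (flagged), not zero.
#'
#' @param prs Numeric standardized PRS (or a \code{\link{compute_prs}} result,
#'   from which \code{z_score} is taken).
#' @param outcome Binary outcome vector.
#' @param exposure Binary exposure vector (1 = ever exposed).
#' @param n_bins Number of percentile bins (>= 2).
#' @return Data.frame: \code{bin}, \code{percentile} (bin midpoint),
#'   \code{exposure}, \code{n}, \code{prevalence}, \code{se}.
#' @export
prevalence_risk_curve <- function(prs, outcome, exposure, n_bins = 10) {
  stopifnot(n_bins >= 2)
  if (is.data.frame(prs)) prs <- prs$z_score
  qs <- stats::quantile(prs, probs = seq(0, 1, length.out = n_bins + 1))
  bin <- cut(prs, breaks = unique(qs), include.lowest = TRUE, labels = FALSE)
  rows <- expand.grid(bin = seq_len(n_bins), exposure = c(0, 1))
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sel <- !is.na(bin) & bin == rows$bin[i] & exposure == rows$exposure[i]
    n <- sum(sel)
    prev <- if (n == 0) NA_real_ else mean(outcome[sel])
    se <- if (n == 0) NA_real_ else sqrt(prev * (1 - prev) / n)
    data.frame(bin = rows$bin[i],
               percentile = (rows$bin[i] - 0.5) / n_bins * 100,
               exposure = rows$exposure[i], n = n, prevalence = prev, se = se)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
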