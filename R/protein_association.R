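# Covariate-adjusted logistic-regression contrasts of normalized protein
# levels across disease / PRS / smoking groups, with Bonferroni control over
# the protein panel. The protein level is the predictor (per-SD odds ratios)
# and group membership the outcome, matching the OR-per-protein presentation
# of biobank proteomics contrasts.

#' The packaged complement-pathway protein panel
#'
#' Names of the 28 complement cascade proteins used by the panel contrasts.
#' The list is a synthetic reconstruction compiled from the KEGG complement
#' cascade (see \code{inst/extdata/complement_panel_synthetic.txt}); it is
#' used for naming only.
#'
#' @return Character vector of 28 protein names.
#' @export
complement_panel <- function() {
  path <- system.file("extdata", "complement_panel_synthetic.txt",
                      package = "amdgxe")
  readLines(path)
}

#' Joint PRS / smoking group labels
#'
#' Median-splits the standardized PRS and crosses it with smoking status into
#' four joint labels. Rows with missing smoking are excluded and counted.
#'
#' @param cohort Cohort data.frame with a \code{smoking} column (0/1).
#' @param scores \code{\link{compute_prs}} result aligned to the cohort rows;
#'   if NULL the cohort's \code{prs} column is used.
#' @return Factor with levels \code{low_never}, \code{low_ever},
#'   \code{high_never}, \code{high_ever} (NA where smoking is missing);
#'   attribute \code{"n_missing_smoking"} counts exclusions. Ties at the
#'   median are resolved by the stable \code{\link{stratify_prs}} rule.
#' @export
build_groups <- function(cohort, scores = NULL) {
  z <- if (is.null(scores)) cohort$prs else scores$z_score
  ids <- if (is.null(scores)) cohort$individual_id else scores$individual_id
  prs_grp <- stratify_prs(data.frame(individual_id = ids, z_score = z,
                                     stringsAsFactors = FALSE),
                          quantiles = c(0.5, 0.5))
  smoke <- cohort$smoking
  lab <- paste(ifelse(prs_grp == "high", "high", "low"),
               ifelse(smoke == 1, "ever", "never"), sep = "_")
  lab[is.na(smoke)] <- NA
  out <- factor(lab, levels = c("low_never", "low_ever", "high_never",
                                "high_ever"))
  attr(out, "n_missing_smoking") <- sum(is.na(smoke))
  out
}

#' Define a group contrast
#'
#' @param name Contrast label.
#' @param group_a,group_b Character vectors of joint group labels forming the
#'   two sides (group_a coded 1 in the logistic model).
#' @param covariates Adjustment covariate names.
#' @return List of class \code{contrast_spec}.
#' @export
contrast_spec <- function(name, group_a, group_b,
                          covariates = c("age", "female", "bmi", "alcohol")) {
  if (length(intersect(group_a, group_b)))
    stop("contrast groups must be disjoint")
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 covariates = covariates), class = "contrast_spec")
}

#' The five standard PRS / smoking comparisons
#'
#' Ever vs never smoked; high vs low PRS; low PRS ever vs low PRS never;
#' high PRS never vs low PRS never; high PRS ever vs low PRS never.
#'
#' @param covariates Adjustment covariates for every contrast.
#' @return List of five \code{\link{contrast_spec}}s.
#' @export
default_contrasts <- function(covariates = c("age", "female", "bmi", "alcohol")) {
  list(
    contrast_spec("ever_vs_never", c("low_ever", "high_ever"),
                  c("low_never", "high_never"), covariates),
    contrast_spec("high_vs_low_prs", c("high_never", "high_ever"),
                  c("low_never", "low_ever"), covariates),
    contrast_spec("low_ever_vs_low_never", "low_ever", "low_never", covariates),
    contrast_spec("high_never_vs_low_never", "high_never", "low_never",
                  covariates),
    contrast_spec("high_ever_vs_low_never", "high_ever", "low_never",
                  covariates))
}

# Minimal ridge-penalized logistic fallback for separated fits: Newton
# iterations on the penalized log-likelihood with a weak quadratic penalty.
.ridge_logistic <- function(x, y, lambda = 1e-2, iters = 50) {
  beta <- rep(0, ncol(x))
  pen <- diag(lambda, ncol(x)); pen[1, 1] <- 0  # intercept unpenalized
  for (i in seq_len(iters)) {
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(x, y - mu) - pen %*% beta
    h <- crossprod(x * w, x) + pen
    step <- solve(h, g)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  beta
}

#' Covariate-adjusted contrast of one protein across two groups
#'
#' Logistic regression of group membership (group_a = 1 vs group_b = 0) on
#' the standardized protein level plus covariates; reports the per-SD odds
#' ratio with Wald interval and p-value. Perfect separation is detected
#' (diverging coefficient or standard error) and replaced by a
#' ridge-penalized point estimate with the interval suppressed and a flag
#' set.
#'
#' @param protein_levels Numeric vector of normalized protein levels for the
#'   whole analysis table.
#' @param groups Factor of joint group labels (from
#'   \code{\link{build_groups}}).
#' @param contrast A \code{\link{contrast_spec}}.
#' @param covariate_table Data.frame of covariates aligned to
#'   \code{protein_levels}.
#' @param standardize Standardize the protein level cohort-wide before
#'   modelling (default TRUE, giving per-SD ORs).
#' @return List of class \code{protein_association}: \code{protein} (NA
#'   unless set by the caller), \code{contrast}, \code{odds_ratio},
#'   \code{ci}, \code{p}, \code{separation_flag}, \code{n_a}, \code{n_b}.
#' @export
protein_contrast <- function(protein_levels, groups, contrast,
                             covariate_table = NULL, standardize = TRUE) {
  in_a <- groups %in% contrast$group_a
  in_b <- groups %in% contrast$group_b
  if (sum(in_a, na.rm = TRUE) < 2) stop("contrast group_a has fewer than 2 members")
  if (sum(in_b, na.rm = TRUE) < 2) stop("contrast group_b has fewer than 2 members")
  sel <- (in_a | in_b) & !is.na(groups)
  y <- as.integer(in_a[sel])
  x <- protein_levels[sel]
  if (standardize) {
    mu <- mean(protein_levels, na.rm = TRUE)
    sdv <- stats::sd(protein_levels, na.rm = TRUE)
    x <- (x - mu) / sdv
  }
  dat <- data.frame(y = y, protein = x)
  covs <- character(0)
  if (!is.null(covariate_table)) {
    covs <- intersect(contrast$covariates, names(covariate_table))
    dat <- cbind(dat, covariate_table[sel, covs, drop = FALSE])
  }
  f <- stats::as.formula(paste("y ~ protein",
                               if (length(covs)) paste("+", paste(covs, collapse = " + "))
                               else ""))
  fit <- suppressWarnings(stats::glm(f, data = dat, family = stats::binomial()))
  est <- stats::coef(fit)["protein"]
  se <- sqrt(diag(stats::vcov(fit)))["protein"]
  separated <- !fit$converged || abs(est) > 10 || se > 10
  if (separated) {
    mm <- stats::model.matrix(f, dat)
    beta <- .ridge_logistic(mm, dat$y)
    est <- beta[which(colnames(mm) == "protein")]
    or <- exp(est); ci <- c(NA_real_, NA_real_); p <- NA_real_
  } else {
    or <- exp(unname(est))
    ci <- exp(unname(est) + c(-1, 1) * stats::qnorm(0.975) * unname(se))
    p <- 2 * stats::pnorm(-abs(unname(est) / unname(se)))
  }
  structure(list(protein = NA_character_, contrast = contrast$name,
                 odds_ratio = unname(or), ci = ci, p = p,
                 separation_flag = separated,
                 n_a = sum(y == 1), n_b = sum(y == 0)),
            class = "protein_association")
}

#' Run every protein-by-contrast association in a panel
#'
#' Fits \code{\link{protein_contrast}} for each protein and contrast, applies
#' the Bonferroni threshold alpha / n_proteins within each contrast, and
#' tallies significant proteins per contrast.
#'
#' @param protein_table Data.frame: \code{individual_id} plus one column per
#'   protein (rows aligned with \code{groups}).
#' @param groups Joint group factor from \code{\link{build_groups}}.
#' @param contrasts List of \code{\link{contrast_spec}}s (default the five
#'   standard comparisons).
#' @param covariate_table Optional covariate data.frame aligned with rows.
#' @param alpha Family-wise level (default 0.05).
#' @return Data.frame, one row per protein x contrast: \code{protein},
#'   \code{contrast}, \code{odds_ratio}, \code{ci_lo}, \code{ci_hi},
#'   \code{p}, \code{significant_bonferroni}, \code{separation_flag};
#'   attributes \code{"bonferroni_threshold"} and \code{"summary"} (count of
#'   significant proteins per contrast).
#' @export
run_panel <- function(protein_table, groups, contrasts = default_contrasts(),
                      covariate_table = NULL, alpha = 0.05) {
  proteins <- setdiff(names(protein_table), "individual_id")
  if (length(proteins) == 0) stop("empty protein panel")
  threshold <- alpha / length(proteins)
  rows <- list()
  for (ct in contrasts) {
    for (p in proteins) {
      r <- protein_contrast(protein_table[[p]], groups, ct, covariate_table)
      rows[[length(rows) + 1]] <-
        data.frame(protein = p, contrast = ct$name, odds_ratio = r$odds_ratio,
                   ci_lo = r$ci[1], ci_hi = r$ci[2], p = r$p,
                   significant_bonferroni = !is.na(r$p) & r$p < threshold,
                   separation_flag = r$separation_flag,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_threshold") <- threshold
  attr(out, "summary") <- tapply(out$significant_bonferroni, out$contrast, sum)
  out
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param n_tests Number of tests in the family.
#' @param digits Rounding used for reporting (default 4, matching the
#'   convention of quoting 0.05/28 as 0.0018).
#' @return Named list with \code{threshold} (exact) and \code{reported}
#'   (rounded).
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests = 28, digits = 4) {
  t <- alpha / n_tests
  list(threshold = t, reported = round(t, digits))
}
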