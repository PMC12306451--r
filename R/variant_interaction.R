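# Per-variant genotype-by-smoking analysis: Wald odds ratios and Pearson
# chi-squared tests on 2x2 contingency tables comparing exposed risk-allele
# carriers with unexposed non-carriers, plus a per-variant Cox interaction
# scan over a causal-variant list.

#' Odds ratio and chi-squared test for a 2x2 table
#'
#' The table compares cases/controls in an exposed-carrier group (a, b)
#' against a reference group (c, d). The odds ratio is ad/bc with a Wald
#' normal-approximation confidence interval on the log scale; the chi-squared
#' statistic is Pearson's with Yates continuity correction by default (the
#' base-R convention for 2x2 tables). Zero cells trigger the
#' Haldane-Anscombe 0.5 correction for the OR and interval, flagged in the
#' result.
#'
#' @param a,b Cases and controls in the exposed-carrier group.
#' @param c_,d Cases and controls in the reference group.
#' @param conf_level Confidence level (default 0.95).
#' @param continuity Apply Yates continuity correction (default TRUE).
#' @return List of class \code{contingency_result}: the four counts,
#'   \code{odds_ratio}, \code{ci}, \code{chi2}, \code{p},
#'   \code{zero_cell_corrected}.
#' @export
contingency_2x2 <- function(a, b, c_, d, conf_level = 0.95,
                            continuity = TRUE) {
  counts <- c(a = a, b = b, c = c_, d = d)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (a + b == 0 || c_ + d == 0) stop("both table rows must be non-empty")
  corrected <- any(counts == 0)
  cc <- if (corrected) counts + 0.5 else counts
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + c(-1, 1) * zq * se)
  ct <- suppressWarnings(
    stats::chisq.test(matrix(counts, 2, 2, byrow = TRUE),
                      correct = continuity))
  structure(list(a = a, b = b, c = c_, d = d,
                 odds_ratio = unname(or), ci = unname(ci),
                 chi2 = unname(ct$statistic), p = ct$p.value,
                 zero_cell_corrected = corrected),
            class = "contingency_result")
}

#' Build genotype-by-exposure 2x2 tables
#'
#' Constructs the two comparisons of the variant-level contingency analysis:
#' homozygous risk-allele carriers who were exposed versus homozygous
#' non-carriers who were unexposed, and heterozygous exposed versus the same
#' reference. Individuals outside the two compared groups are excluded from
#' each table. If a comparison group is empty the table is skipped with a
#' flag.
#'
#' @param dosages Integer vector in \{0, 1, 2\}, coded for the risk allele.
#' @param exposure Binary exposure vector (1 = ever).
#' @param outcome Binary outcome vector (1 = case).
#' @return List with elements \code{hom} and \code{het}; each either a
#'   \code{\link{contingency_2x2}} result or \code{NULL} (with names in
#'   \code{skipped}) when a group is empty.
#' @export
genotype_exposure_groups <- function(dosages, exposure, outcome) {
  stopifnot(length(dosages) == length(exposure),
            length(exposure) == length(outcome))
  ref <- dosages == 0 & exposure == 0
  c_ <- sum(outcome[ref] == 1); d <- sum(outcome[ref] == 0)
  make <- function(sel) {
    a <- sum(outcome[sel] == 1); b <- sum(outcome[sel] == 0)
    if (a + b == 0 || c_ + d == 0) return(NULL)
    contingency_2x2(a, b, c_, d)
  }
  hom <- make(dosages == 2 & exposure == 1)
  het <- make(dosages == 1 & exposure == 1)
  skipped <- c(if (is.null(hom)) "hom", if (is.null(het)) "het")
  list(hom = hom, het = het, skipped = skipped)
}

#' Per-variant Cox interaction scan
#'
#' For each variant, fits a Cox model with per-allele dosage, exposure, their
#' product, and the model's adjustment covariates, then computes the additive
#' and multiplicative interaction statistics at a one-allele modifier
#' contrast. Non-convergent variants are flagged and the scan continues.
#'
#' @param cohort Cohort data.frame containing one dosage column per variant.
#' @param variants Character vector of variant (dosage column) names.
#' @param spec A \code{\link{model_spec}} choosing the adjustment set.
#' @param exposure Exposure column name (default \code{"smoking"}).
#' @return Data.frame, one row per variant: \code{variant_id}, \code{reri},
#'   \code{reri_lo}, \code{reri_hi}, \code{ap}, \code{ap_lo}, \code{ap_hi},
#'   \code{hr_mult}, \code{hr_mult_lo}, \code{hr_mult_hi}, \code{p_mult},
#'   \code{converged}.
#' @export
variant_interaction_scan <- function(cohort, variants,
                                     spec = model_spec(1L, c("age", "female")),
                                     exposure = "smoking") {
  empty_row <- function(v, ok = FALSE) {
    data.frame(variant_id = v, reri = NA_real_, reri_lo = NA_real_,
               reri_hi = NA_real_, ap = NA_real_, ap_lo = NA_real_,
               ap_hi = NA_real_, hr_mult = NA_real_, hr_mult_lo = NA_real_,
               hr_mult_hi = NA_real_, p_mult = NA_real_, converged = ok,
               stringsAsFactors = FALSE)
  }
  if (length(variants) == 0) return(empty_row("x")[0, ])
  rows <- lapply(variants, function(v) {
    if (!v %in% names(cohort)) stop("dosage column missing: ", v)
    product <- paste(exposure, v, sep = ":")
    res <- tryCatch({
      fit <- fit_cox(cohort, c(exposure, v, product, spec$covariates))
      ir <- additive_interaction(fit, exposure, v, product, contrast_sd = 1)
      data.frame(variant_id = v,
                 reri = ir$reri[["estimate"]], reri_lo = ir$reri[["lower"]],
                 reri_hi = ir$reri[["upper"]],
                 ap = ir$ap[["estimate"]], ap_lo = ir$ap[["lower"]],
                 ap_hi = ir$ap[["upper"]],
                 hr_mult = ir$hr_multiplicative[["estimate"]],
                 hr_mult_lo = ir$hr_multiplicative[["lower"]],
                 hr_mult_hi = ir$hr_multiplicative[["upper"]],
                 p_mult = ir$p_multiplicative, converged = TRUE,
                 stringsAsFactors = FALSE)
    }, error = function(e) empty_row(v))
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Table of genotype-by-exposure contingency results
#'
#' Runs \code{\link{genotype_exposure_groups}} for each variant and stacks
#' the results in the shape of a published variant-by-smoking risk table.
#'
#' @param cohort Cohort data.frame with dosage columns.
#' @param variants Character vector of dosage column names.
#' @param exposure,outcome Column names for exposure and outcome
#'   (\code{"smoking"} and \code{"event"} by default).
#' @return Data.frame: \code{variant_id}, \code{comparison} ("hom"/"het"),
#'   counts a-d, \code{odds_ratio}, \code{ci_lo}, \code{ci_hi}, \code{chi2},
#'   \code{p}.
#' @export
contingency_table_scan <- function(cohort, variants, exposure = "smoking",
                                   outcome = "event") {
  rows <- list()
  for (v in variants) {
    g <- genotype_exposure_groups(cohort[[v]], cohort[[exposure]],
                                  cohort[[outcome]])
    for (cmp in c("hom", "het")) {
      r <- g[[cmp]]
      if (is.null(r)) next
      rows[[length(rows) + 1]] <-
        data.frame(variant_id = v, comparison = cmp, a = r$a, b = r$b,
                   c = r$c, d = r$d, odds_ratio = r$odds_ratio,
                   ci_lo = r$ci[1], ci_hi = r$ci[2], chi2 = r$chi2, p = r$p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
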