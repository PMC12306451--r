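# Shared fixture builders; everything is generated in code at test time.

make_sumstats <- function(n = 5, beta = 0.2, se = 0.05, eaf = 0.3, info = 1,
                          chrom = "1", spacing = 1e6L) {
  data.frame(variant_id = paste0("rs", seq_len(n)), chrom = chrom,
             pos = seq_len(n) * spacing, effect_allele = "A",
             other_allele = "G", beta = rep_len(beta, n),
             se = rep_len(se, n),
             pvalue = 2 * pnorm(-abs(rep_len(beta, n) / rep_len(se, n))),
             n_cases = 1000L, n_controls = 1000L, eaf = rep_len(eaf, n),
             info = rep_len(info, n), stringsAsFactors = FALSE)
}

# a cox_fit-shaped stub with chosen coefficients and a tiny diagonal
# covariance, for closed-form interaction-statistic checks
fake_cox_fit <- function(b1, b2, b3, var = 1e-4) {
  nm <- c("smoking", "prs", "smoking:prs")
  structure(list(coefficients = stats::setNames(c(b1, b2, b3), nm),
                 covariance = diag(var, 3, 3) |>
                   (\(m) {dimnames(m) <- list(nm, nm); m})(),
                 loglik = NA_real_, c_index = NA_real_, c_index_se = NA_real_,
                 ph_global_p = NA_real_, n = 0L, n_events = 0L, fit = NULL),
            class = "cox_fit")
}

# exhaustive concordant-pair AUC oracle (ties count one half)
brute_force_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (x in cs) for (y in ct) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cs) * length(ct))
}

# uncorrected / Yates-corrected Pearson chi-squared, from the closed form
brute_force_chi2 <- function(a, b, c, d, correct = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (correct) num <- max(num - n / 2, 0)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
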