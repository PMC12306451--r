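test_that("AUC equals the exhaustive concordant-pair oracle", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc(rep(0.5, 10), rep(c(1, 0), 5))$auc, 0.5)

  set.seed(51)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))       # both classes guaranteed
    scores <- round(rnorm(n), 1)                    # rounding induces ties
    expect_equal(auc(scores, labels)$auc, brute_force_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(auc(1:5, rep(1, 5)), "both classes")
})

test_that("AUC and DeLong variance agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(52)
  labels <- rbinom(300, 1, 0.3)
  labels[1:2] <- c(0, 1)
  s1 <- rnorm(300) + labels
  s2 <- rnorm(300) + 0.5 * labels
  r1 <- pROC::roc(labels, s1, quiet = TRUE, direction = "<")
  got <- auc(s1, labels)
  expect_equal(got$auc, as.numeric(pROC::auc(r1)), tolerance = 1e-12)
  expect_equal(got$se^2, pROC::var(r1), tolerance = 1e-10)

  cmp <- delong_compare(s2, s1, labels)
  ref <- pROC::roc.test(pROC::roc(labels, s2, quiet = TRUE, direction = "<"),
                        r1, method = "delong", paired = TRUE)
  expect_equal(cmp$p, ref$p.value, tolerance = 1e-9)
})

test_that("DeLong comparison handles degenerate and powered cases", {
  set.seed(53)
  labels <- rbinom(500, 1, 0.3); labels[1:2] <- c(0, 1)
  s <- rnorm(500)
  same <- delong_compare(s, s, labels)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)

  # strong signal vs pure noise: decisive p
  n <- 2000
  labels2 <- rbinom(n, 1, 0.3); labels2[1:2] <- c(0, 1)
  noise <- rnorm(n)
  signal <- labels2 + rnorm(n, sd = 0.1)
  strong <- delong_compare(noise, signal, labels2)
  expect_lt(strong$p, 1e-6)
  expect_equal(strong$delta_auc, strong$auc_full - strong$auc_base,
               tolerance = 1e-12)
})

test_that("DeLong p-values are uniform under the null", {
  set.seed(54)
  reps <- 300
  ps <- vapply(seq_len(reps), function(i) {
    labels <- rep(c(1, 0), c(30, 70))
    delong_compare(rnorm(100), rnorm(100), labels)$p
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bootstrap delta-AUC is deterministic and tracks the truth", {
  set.seed(55)
  labels <- rbinom(800, 1, 0.3); labels[1:2] <- c(0, 1)
  s_base <- rnorm(800)
  b1 <- bootstrap_delta_auc(s_base, s_base + 0.01, labels, iters = 200,
                            seed = 9)
  b2 <- bootstrap_delta_auc(s_base, s_base + 0.01, labels, iters = 200,
                            seed = 9)
  expect_identical(b1, b2)

  same <- bootstrap_delta_auc(s_base, s_base, labels, iters = 200, seed = 9)
  expect_equal(same$mean_delta, 0)
  expect_true(same$ci[1] <= 0 && same$ci[2] >= 0)
  expect_lt(diff(same$ci), 1e-12)
})

test_that("NRI and IDI match hand-counted reclassification moves", {
  # events: base (0.2, 0.3, 0.4) -> full (0.3, 0.2, 0.5)
  # nonevents: base (0.2, 0.1, 0.3, 0.4) -> full (0.1, 0.2, 0.2, 0.3)
  rb <- c(0.2, 0.3, 0.4, 0.2, 0.1, 0.3, 0.4)
  rf <- c(0.3, 0.2, 0.5, 0.1, 0.2, 0.2, 0.3)
  y <- c(1, 1, 1, 0, 0, 0, 0)
  out <- nri_idi(rb, rf, y)
  # events: 2 up, 1 down of 3 -> 1/3; nonevents: 3 down, 1 up of 4 -> 1/2
  expect_equal(out$nri_continuous$estimate, 1 / 3 + 1 / 2, tolerance = 1e-12)
  # IDI: mean event delta 0.1/3 minus mean nonevent delta (-0.2/4)
  expect_equal(out$idi$estimate, 0.1 / 3 + 0.05, tolerance = 1e-12)

  # identical risks: all zero
  out0 <- nri_idi(rb, rb, y)
  expect_equal(out0$nri_continuous$estimate, 0)
  expect_equal(out0$idi$estimate, 0)

  # component sums are exact
  expect_equal(out$nri_continuous$event_component +
                 out$nri_continuous$nonevent_component,
               out$nri_continuous$estimate, tolerance = 1e-12)
  # IDI equals the difference of discrimination slopes
  slope <- function(r) mean(r[y == 1]) - mean(r[y == 0])
  expect_equal(out$idi$estimate, slope(rf) - slope(rb), tolerance = 1e-12)

  # categorical NRI with one cut at 0.25: events 0.2->0.3 up and 0.3->0.2
  # down cancel (0); nonevents have one down (0.3->0.2) of four -> 1/4
  cat_out <- nri_idi(rb, rf, y, cuts = 0.25)
  expect_equal(cat_out$nri_categorical$estimate, 0 + 1 / 4,
               tolerance = 1e-12)
  expect_error(nri_idi(rb, rf, y, cuts = c(0.3, 0.2)), "increasing")
})

test_that("prevalence-risk curve shows interaction-driven divergence", {
  set.seed(56)
  n <- 20000
  prs <- rnorm(n)
  exposure <- rbinom(n, 1, 0.5)
  # logistic outcome with positive PRS x exposure term
  p <- plogis(-3 + 0.4 * prs + 0.2 * exposure + 0.5 * prs * exposure)
  outcome <- rbinom(n, 1, p)
  curve <- prevalence_risk_curve(prs, outcome, exposure, n_bins = 10)
  expect_equal(nrow(curve), 20)
  gap <- curve$prevalence[curve$exposure == 1] -
    curve$prevalence[curve$exposure == 0]
  expect_gt(suppressWarnings(cor(gap, 1:10, method = "spearman")), 0)

  # outcome independent of PRS: flat within noise
  out_flat <- rbinom(n, 1, 0.1)
  flat <- prevalence_risk_curve(prs, out_flat, exposure, n_bins = 5)
  expect_true(all(abs(flat$prevalence - 0.1) < 5 * flat$se))

  # two bins aggregate consistently with overall prevalence
  two <- prevalence_risk_curve(prs, outcome, exposure, n_bins = 2)
  overall <- sum(two$prevalence * two$n) / sum(two$n)
  expect_equal(overall, mean(outcome), tolerance = 1e-12)
})
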