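test_that("interaction statistics match hand evaluation of the formulas", {
  # b1 = ln 1.5, b2 = ln 2, b3 = 0: HR11 = 3, RERI = 0.5, AP = 1/6, SI = 4/3
  ir <- additive_interaction(fake_cox_fit(log(1.5), log(2), 0))
  expect_equal(ir$hr11, 3, tolerance = 1e-12)
  expect_equal(ir$reri[["estimate"]], 0.5, tolerance = 1e-12)
  expect_equal(ir$ap[["estimate"]], 1 / 6, tolerance = 1e-12)
  expect_equal(ir$si[["estimate"]], 4 / 3, tolerance = 1e-12)
  expect_equal(ir$hr_multiplicative[["estimate"]], 1, tolerance = 1e-12)

  # exact additivity: HR10 = 1.5, HR01 = 1.2, b3 = ln(1.7/1.8) -> RERI = 0
  ir0 <- additive_interaction(fake_cox_fit(log(1.5), log(1.2), log(1.7 / 1.8)))
  expect_equal(ir0$reri[["estimate"]], 0, tolerance = 1e-12)
  expect_equal(ir0$ap[["estimate"]], 0, tolerance = 1e-12)
  expect_equal(ir0$si[["estimate"]], 1, tolerance = 1e-12)

  # global null: SI undefined (0/0), multiplicative HR 1
  irn <- additive_interaction(fake_cox_fit(0, 0, 0))
  expect_equal(irn$reri[["estimate"]], 0, tolerance = 1e-12)
  expect_false(irn$si_defined)
  expect_true(is.na(irn$si[["estimate"]]))
  expect_equal(irn$hr_multiplicative[["estimate"]], 1)

  expect_error(additive_interaction(fake_cox_fit(0, 0, 0),
                                    term_product = "missing"), "not in fit")
})

test_that("interaction identities hold on random coefficient triples", {
  set.seed(41)
  for (i in 1:50) {
    b <- rnorm(3, 0, 0.5)
    ir <- additive_interaction(fake_cox_fit(b[1], b[2], b[3]))
    h10 <- exp(b[1]); h01 <- exp(b[2]); h11 <- exp(sum(b))
    expect_equal(ir$ap[["estimate"]] * ir$hr11, ir$reri[["estimate"]],
                 tolerance = 1e-12)
    if (ir$si_defined)
      expect_equal(ir$si[["estimate"]] * ((h10 - 1) + (h01 - 1)), h11 - 1,
                   tolerance = 1e-12)
  }
})

test_that("fit_cox recovers a known hazard ratio and rejects bad input", {
  sc <- simulation_scenario(n_individuals = 20000, n_variants = 2,
                            beta_prs = 0, beta_smoke = log(2),
                            beta_interaction = 0,
                            covariate_effects = c(age = 0, female = 0,
                                                  bmi = 0, alcohol = 0),
                            baseline_hazard = 0.02, seed = 19)
  co <- simulate_survival(sc)
  fit <- fit_cox(co, "smoking")
  ci <- fit$coefficients[["smoking"]] +
    c(-1, 1) * 1.96 * sqrt(fit$covariance[1, 1])
  expect_true(ci[1] <= log(2) && log(2) <= ci[2])
  expect_gt(fit$c_index, 0.5)
  expect_true(fit$ph_global_p > 0 && fit$ph_global_p <= 1)

  no_events <- co; no_events$event <- 0
  expect_error(fit_cox(no_events, "smoking"), "no events")
  const <- co; const$bmi <- 1
  expect_error(fit_cox(const, c("smoking", "bmi")), "constant covariate: bmi")
  neg <- co; neg$time[1] <- 0
  expect_error(fit_cox(neg, "smoking"), "positive")
})

test_that("C-index of a random score is near one half", {
  sc <- simulation_scenario(n_individuals = 10000, n_variants = 2,
                            baseline_hazard = 0.02, seed = 23)
  co <- simulate_survival(sc)
  set.seed(23)
  co$noise <- rnorm(nrow(co))
  fit <- fit_cox(co, "noise")
  expect_lt(abs(fit$c_index - 0.5), 0.02)
})

test_that("model ladder shares one analysis set and is Table-2 shaped", {
  sc <- simulation_scenario(n_individuals = 15000, n_variants = 5,
                            baseline_hazard = 0.01, seed = 29)
  co <- simulate_survival(sc)
  ladder <- run_model_ladder(co)
  expect_length(ladder, 4)
  ns <- vapply(ladder, function(r) r$fit$n, 0L)
  expect_equal(length(unique(ns)), 1L)

  tab <- ladder_table(ladder)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("model", "hr_smoke", "reri", "ap", "si", "hr_mult",
                    "p_mult", "ph_p", "c_index") %in% names(tab)))

  # RERI stable across models when adjustment covariates are irrelevant
  sc0 <- simulation_scenario(n_individuals = 15000, n_variants = 5,
                             covariate_effects = c(age = 0, female = 0,
                                                   bmi = 0, alcohol = 0),
                             baseline_hazard = 0.01, seed = 29)
  co0 <- simulate_survival(sc0)
  lad0 <- run_model_ladder(co0)
  tab0 <- ladder_table(lad0)
  reri_se <- (tab0$reri_hi - tab0$reri_lo) / (2 * 1.96)
  expect_true(all(abs(tab0$reri - tab0$reri[1]) < 2 * reri_se))

  const <- co; const$bmi <- 1
  expect_error(run_model_ladder(const), "bmi")
  expect_error(run_model_ladder(co[, setdiff(names(co), "alcohol")]),
               "alcohol")
})

test_that("short-followup exclusion removes early events only", {
  co <- data.frame(individual_id = c("a", "b", "c", "d"),
                   time = c(0.2, 0.2, 2, 3), event = c(1, 0, 1, 0))
  out <- exclude_short_followup(co)
  expect_equal(out$individual_id, c("b", "c", "d"))
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("train/test split is stratified, disjoint, exhaustive, seeded", {
  co <- data.frame(individual_id = sprintf("i%04d", 1:1000),
                   event = rep(c(1, 0), c(100, 900)))
  sp <- split_cohort(co, 0.5, seed = 5)
  expect_equal(sum(sp$train$event), 50)
  expect_equal(nrow(sp$train) + nrow(sp$test), 1000)
  expect_length(intersect(sp$train$individual_id, sp$test$individual_id), 0)
  expect_setequal(c(sp$train$individual_id, sp$test$individual_id),
                  co$individual_id)
  sp2 <- split_cohort(co, 0.5, seed = 5)
  expect_identical(sp$train$individual_id, sp2$train$individual_id)
})

test_that("cumulative incidence matches the exponential closed form", {
  set.seed(7)
  n <- 20000; lambda <- 0.1
  co <- data.frame(time = rexp(n, lambda), event = 1)
  grid <- c(2, 5, 10)
  ci <- cumulative_incidence(co, rep("all", n), grid)
  expect_equal(nrow(ci), 3)
  for (i in 1:3) {
    expect_lt(abs(ci$incidence[i] - (1 - exp(-lambda * grid[i]))),
              3 * ci$se[i] + 1e-6)
  }

  # no events -> identically zero
  co0 <- data.frame(time = rep(5, 100), event = 0)
  ci0 <- cumulative_incidence(co0, rep("all", 100), c(1, 4))
  expect_equal(ci0$incidence, c(0, 0))

  # groups ordered by true hazard give ordered curves
  g <- rep(c("lo", "hi"), each = n / 2)
  co2 <- data.frame(time = c(rexp(n / 2, 0.05), rexp(n / 2, 0.2)), event = 1)
  ci2 <- cumulative_incidence(co2, g, 5)
  expect_gt(ci2$incidence[ci2$group == "hi"], ci2$incidence[ci2$group == "lo"])

  expect_error(cumulative_incidence(co[0, ], character(0), 1), "empty")
})
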