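test_that("contingency_2x2 matches closed forms and symmetries", {
  r <- contingency_2x2(10, 100, 10, 100)
  expect_equal(r$odds_ratio, 1.0, tolerance = 1e-12)
  expect_lt(r$chi2, 0.01)

  # OR is exactly ad/bc; chi2 with correction matches the brute-force formula
  set.seed(61)
  for (i in 1:20) {
    cts <- sample(5:500, 4)
    r <- contingency_2x2(cts[1], cts[2], cts[3], cts[4])
    expect_equal(r$odds_ratio, cts[1] * cts[4] / (cts[2] * cts[3]),
                 tolerance = 1e-12)
    expect_equal(r$chi2, brute_force_chi2(cts[1], cts[2], cts[3], cts[4]),
                 tolerance = 1e-9)
    # swapping the rows inverts the OR and preserves chi2
    sw <- contingency_2x2(cts[3], cts[4], cts[1], cts[2])
    expect_equal(sw$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-12)
    expect_equal(sw$chi2, r$chi2, tolerance = 1e-12)
  }

  # continuity correction can be disabled
  rn <- contingency_2x2(20, 80, 10, 90, continuity = FALSE)
  expect_equal(rn$chi2, brute_force_chi2(20, 80, 10, 90, correct = FALSE),
               tolerance = 1e-9)

  # zero cell triggers the Haldane-Anscombe correction, flagged
  z <- contingency_2x2(0, 50, 10, 90)
  expect_true(z$zero_cell_corrected)
  expect_equal(z$odds_ratio, (0.5 * 90.5) / (50.5 * 10.5), tolerance = 1e-12)
  expect_error(contingency_2x2(0, 0, 10, 90), "non-empty")
})

test_that("published variant-smoking count sets reproduce their statistics", {
  counts <- read.delim(system.file("extdata", "variant_smoking_counts.tsv",
                                   package = "amdgxe"))
  expect_equal(nrow(counts), 8)
  ors <- chis <- numeric(8)
  for (i in 1:8) {
    r <- contingency_2x2(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
    ors[i] <- r$odds_ratio; chis[i] <- r$chi2
  }
  expect_equal(round(ors, 2), c(1.61, 1.26, 1.45, 1.29, 0.97, 1.02, 1.28, 1.11))
  expect_equal(round(chis[c(1, 2, 3, 4, 7, 8)], 2),
               c(81.52, 36.59, 6.19, 36.71, 25.19, 4.98))
})

test_that("genotype-exposure tables match a hand tally", {
  # 10 individuals covering all genotype x exposure cells
  dos <- c(2, 2, 1, 1, 0, 0, 0, 0, 2, 2)
  exp_ <- c(1, 1, 1, 1, 0, 0, 1, 0, 0, 0)
  out <- c(1, 0, 1, 0, 1, 0, 1, 0, 0, 1)
  g <- genotype_exposure_groups(dos, exp_, out)
  expect_equal(c(g$hom$a, g$hom$b, g$hom$c, g$hom$d), c(1, 1, 1, 2))
  expect_equal(c(g$het$a, g$het$b, g$het$c, g$het$d), c(1, 1, 1, 2))
  expect_length(g$skipped, 0)

  # no hom carriers: hom table skipped with flag
  g2 <- genotype_exposure_groups(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_null(g2$hom)
  expect_equal(g2$skipped, "hom")

  # flipped coding yields the complementary genotype comparison
  gf <- genotype_exposure_groups(2 - dos, exp_, out)
  expect_equal(c(gf$hom$a, gf$hom$b),
               c(sum(out[dos == 0 & exp_ == 1]), sum(1 - out[dos == 0 & exp_ == 1])))
})

test_that("variant scan returns ordered rows and survives non-convergence", {
  sc <- simulation_scenario(n_individuals = 8000, n_variants = 3,
                            baseline_hazard = 0.02, seed = 67)
  co <- simulate_survival(sc)
  scan <- variant_interaction_scan(co, c("var1", "var2", "var3"))
  expect_equal(scan$variant_id, c("var1", "var2", "var3"))
  expect_true(all(scan$converged))
  expect_true(all(scan$hr_mult > 0))

  expect_equal(nrow(variant_interaction_scan(co, character(0))), 0)

  # a constant dosage column cannot converge; scan continues with a flag
  co$flat <- 1
  scan2 <- variant_interaction_scan(co, c("var1", "flat"))
  expect_true(scan2$converged[1])
  expect_false(scan2$converged[2])
})

test_that("a strong injected interaction ranks first in the scan", {
  set.seed(71)
  wins <- 0L
  for (r in 1:10) {
    n <- 20000
    dos <- simulate_genotypes(n, rep(0.3, 6), seed = 100 + r)
    smoking <- rbinom(n, 1, 0.6)
    lp <- 0.2 * dos[, 1] + log(1.4) * dos[, 1] * smoking + 0.1 * smoking
    t_ev <- rexp(n, 0.02 * exp(lp))
    co <- data.frame(time = pmin(t_ev, 16.7),
                     event = as.integer(t_ev <= 16.7), smoking = smoking)
    co <- cbind(co, as.data.frame(dos))
    scan <- variant_interaction_scan(co, paste0("var", 1:6),
                                     spec = model_spec(0L))
    if (which.min(scan$p_mult) == 1) wins <- wins + 1L
  }
  expect_gte(wins, 8)
})

test_that("empty result from contingency scan keeps table shape", {
  sc <- simulation_scenario(n_individuals = 3000, n_variants = 2,
                            baseline_hazard = 0.02, seed = 73)
  co <- simulate_survival(sc)
  tab <- contingency_table_scan(co, c("var1", "var2"))
  expect_true(all(c("variant_id", "comparison", "odds_ratio", "chi2", "p")
                  %in% names(tab)))
  expect_equal(unique(tab$comparison), c("hom", "het"))
})
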