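test_that("qc_filter tallies each rejection reason", {
  rec <- make_sumstats(5)
  rec$info <- c(0.95, 0.5, 0.95, 0.95, 0.95)   # rs2 fails INFO
  rec$eaf <- c(0.2, 0.2, 0.002, 0.2, 0.2)      # rs3 fails MAF
  panel <- c("rs1", "rs2", "rs3", "rs5")        # rs4 not in panel
  ref <- c(rs5 = 0.65)                          # rs5 fails freq discrepancy
  out <- qc_filter(rec, panel, run_config(), ref_freq = ref)
  expect_equal(out$kept$variant_id, "rs1")
  expect_equal(unname(out$rejection_log[c("panel", "info", "maf",
                                          "freq_discrepancy")]),
               c(1, 1, 1, 1))

  # INFO = 0.95, MAF = 0.2, in panel -> kept
  expect_true("rs1" %in% out$kept$variant_id)
  expect_warning(qc_filter(rec, character(0), run_config()), "every variant")
})

test_that("compute_prs is a dosage-weighted sum with allele alignment", {
  dos <- matrix(c(1, 2, 0, 0, 1, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("i1", "i2"), c("v1", "v2", "v3")))
  w <- data.frame(variant_id = c("v1", "v2", "v3"),
                  effect_allele = c("A", "A", "A"),
                  weight = c(0.1, -0.2, 0.3), stringsAsFactors = FALSE)
  sc <- compute_prs(dos, w)
  expect_equal(sc$raw_score[1], 0.1 * 1 - 0.2 * 2 + 0.3 * 0)  # -0.3
  expect_equal(sc$raw_score[1], -0.3)

  # all-zero weights give zero scores
  w0 <- w; w0$weight <- 0
  expect_equal(compute_prs(dos, w0)$raw_score, c(0, 0))

  # single variant, weight 0.5, dosage 2 -> raw 1.0
  d1 <- matrix(c(2, 0), ncol = 1, dimnames = list(NULL, "v1"))
  expect_equal(compute_prs(d1, w[1, ] |>
                             transform(weight = 0.5))$raw_score[1], 1.0)

  expect_error(compute_prs(dos[, 1:2], w), "absent")

  # z-scores standardized over the cohort
  set.seed(2)
  dbig <- matrix(rbinom(300, 2, 0.3), 100, 3,
                 dimnames = list(NULL, c("v1", "v2", "v3")))
  z <- compute_prs(dbig, w)$z_score
  expect_lt(abs(mean(z)), 1e-9)
  expect_equal(sd(z), 1, tolerance = 1e-9)
})

test_that("compute_prs is linear and allele-flip equivariant", {
  set.seed(3)
  dos <- matrix(rbinom(200, 2, 0.4), 50, 4,
                dimnames = list(NULL, paste0("v", 1:4)))
  w1 <- data.frame(variant_id = paste0("v", 1:4), effect_allele = "A",
                   weight = runif(4), stringsAsFactors = FALSE)
  w2 <- w1; w2$weight <- rnorm(4)
  wsum <- w1; wsum$weight <- w1$weight + w2$weight
  expect_equal(compute_prs(dos, wsum)$raw_score,
               compute_prs(dos, w1)$raw_score + compute_prs(dos, w2)$raw_score,
               tolerance = 1e-12)

  # flipping one weight's allele with matching dosage recode preserves
  # raw scores up to a constant and z-scores exactly
  align <- c(v1 = "A", v2 = "A", v3 = "A", v4 = "A")
  base <- compute_prs(dos, w1, align)
  wf <- w1; wf$effect_allele[2] <- "G"; wf$weight[2] <- -wf$weight[2]
  flipped <- compute_prs(dos, wf, align)
  expect_equal(diff(range(flipped$raw_score - base$raw_score)), 0,
               tolerance = 1e-12)
  expect_equal(flipped$z_score, base$z_score, tolerance = 1e-12)
})

test_that("clump_threshold_weights mirrors the clumping fixture", {
  m <- make_sumstats(6)
  m$p_meta <- c(1e-10, 1e-9, 0.5, 1e-12, 0.2, 1e-8)
  m$beta_meta <- m$beta
  w <- clump_threshold_weights(m)
  expect_equal(sort(w$variant_id), c("rs1", "rs2", "rs4", "rs6"))
  expect_equal(unique(w$weight), 0.2)

  expect_equal(nrow(clump_threshold_weights(m, p_cut = 1e-20)), 0)

  # window larger than the chromosome: one entry (best variant)
  w1 <- clump_threshold_weights(m, p_cut = 1, window_bp = 1e9)
  expect_equal(w1$variant_id, "rs4")
})

test_that("stratify_prs counts and tie handling are deterministic", {
  sc <- data.frame(individual_id = sprintf("i%02d", 1:10),
                   z_score = seq(-2, 2.5, by = 0.5))
  lab <- stratify_prs(sc, c(0.2, 0.8))
  expect_equal(as.vector(table(lab)), c(2, 6, 2))

  med <- stratify_prs(sc, c(0.5, 0.5))
  expect_equal(sum(med == "mid"), 0)
  expect_equal(as.vector(table(med)), c(5, 0, 5))

  # all-tied scores: stable id-based rule preserves totals
  tie <- data.frame(individual_id = sprintf("i%02d", 1:10), z_score = 1)
  lab_tie <- stratify_prs(tie, c(0.2, 0.8))
  expect_equal(length(lab_tie), 10)
  expect_equal(as.vector(table(lab_tie)), c(2, 6, 2))
  expect_equal(which(lab_tie == "low"), 1:2)  # first ids take the low bin
})

test_that("PRS tracks true liability more closely as effects grow", {
  cors <- vapply(c(0.05, 0.2, 0.5), function(b) {
    sc <- simulation_scenario(n_individuals = 3000, n_variants = 20,
                              beta_variants = b, seed = 17)
    co <- simulate_survival(sc)
    dos <- as.matrix(co[, sc$variant_ids])
    liability <- as.numeric(dos %*% rep(b, 20))
    w <- data.frame(variant_id = sc$variant_ids, effect_allele = "A",
                    weight = rnorm(20, b, 0.05))
    cor(liability, compute_prs(dos, w)$raw_score)
  }, 0)
  expect_true(all(diff(cors) > 0))
})
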