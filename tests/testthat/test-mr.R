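test_that("Wald ratio follows the sign and scale rules", {
  wr <- wald_ratio(0.5, 0.01, 0.25, 0.02)
  expect_equal(wr$estimate, 0.5)
  expect_equal(wr$se, 0.04)
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.02)$estimate, 0)
  expect_lt(wald_ratio(-0.5, 0.01, 0.25, 0.02)$estimate, 0)
  expect_equal(wald_ratio(-0.5, 0.01, 0.25, 0.02)$se, 0.04)
  expect_error(wald_ratio(0, 0.01, 0.25, 0.02), "zero exposure")
})

test_that("IVW point estimate matches the weighted zero-intercept oracle", {
  h <- data.frame(beta_exposure = c(0.4, 0.5, 0.6),
                  se_exposure = c(0.02, 0.02, 0.02),
                  beta_outcome = c(0.18, 0.29, 0.35),
                  se_outcome = c(0.010, 0.012, 0.011))
  res <- ivw_mre(h)
  oracle <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
               weights = 1 / h$se_outcome^2)
  expect_equal(res$estimate, unname(coef(oracle)), tolerance = 1e-8)
  # lm's se uses sigma2 = weighted RSS / (k - 1): identical to the
  # multiplicative random-effects se whenever dispersion exceeds the floor
  expect_gt(res$residual_scale, 1)
  expect_equal(res$se, summary(oracle)$coefficients[1, 2], tolerance = 1e-8)
  expect_equal(res$ci_low, res$estimate - 1.96 * res$se)
  expect_equal(res$ci_high, res$estimate + 1.96 * res$se)
  expect_equal(res$n_instruments, 3L)
})

test_that("single-instrument IVW degenerates to the Wald ratio", {
  h <- data.frame(beta_exposure = 0.5, se_exposure = 0.01,
                  beta_outcome = 0.25, se_outcome = 0.02)
  res <- ivw_mre(h)
  expect_equal(res$estimate, 0.5)
  expect_equal(res$se, 0.04)
  expect_equal(res$residual_scale, 1)
  expect_match(res$method, "Wald")
})

test_that("perfect homogeneity hits the dispersion floor", {
  h <- data.frame(beta_exposure = c(0.2, 0.4, 0.8),
                  se_exposure = 0.01,
                  beta_outcome = 0.7 * c(0.2, 0.4, 0.8),
                  se_outcome = c(0.02, 0.05, 0.03))
  res <- ivw_mre(h)
  expect_equal(res$estimate, 0.7, tolerance = 1e-12)
  expect_equal(res$residual_scale, 1)
  # with the floor active the se equals the fixed-effect se
  expect_equal(res$se, sqrt(1 / sum(h$beta_exposure^2 / h$se_outcome^2)),
               tolerance = 1e-12)
})

test_that("IVW with equal outcome SEs reduces to OLS through the origin", {
  set.seed(2)
  bx <- runif(8, 0.1, 0.6)
  by <- 0.3 * bx + rnorm(8, sd = 0.05)
  h <- data.frame(beta_exposure = bx, se_exposure = 0.01,
                  beta_outcome = by, se_outcome = 0.04)
  expect_equal(ivw_mre(h)$estimate, sum(bx * by) / sum(bx^2),
               tolerance = 1e-10)
})

test_that("estimate is invariant to per-variant simultaneous sign flips", {
  set.seed(3)
  for (rep in 1:5) {
    k <- sample(3:10, 1)
    h <- data.frame(beta_exposure = runif(k, 0.1, 0.5),
                    se_exposure = runif(k, 0.01, 0.05),
                    beta_outcome = rnorm(k, 0.1, 0.1),
                    se_outcome = runif(k, 0.01, 0.05))
    flip <- sample(c(-1, 1), k, replace = TRUE)
    h2 <- h
    h2$beta_exposure <- flip * h$beta_exposure
    h2$beta_outcome <- flip * h$beta_outcome
    a <- ivw_mre(h); b <- ivw_mre(h2)
    expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
    expect_gte(a$residual_scale, 1)
  }
})

test_that("zero instruments raise a non-estimable error", {
  h <- data.frame(beta_exposure = numeric(0), se_exposure = numeric(0),
                  beta_outcome = numeric(0), se_outcome = numeric(0))
  expect_error(ivw_mre(h), "non-estimable")
  marker <- mr_non_estimable()
  expect_false(marker$estimable)
  expect_equal(marker$n_instruments, 0L)
})

test_that("harmonization aligns, flips and drops variants correctly", {
  ex <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
                     beta = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
                     se = 0.05,
                     effect_allele = c("A", "A", "A", "A", "A", "C"),
                     other_allele = c("G", "G", "G", "T", "T", "G"),
                     eaf = c(0.3, 0.3, 0.3, 0.2, 0.5, 0.3))
  ou <- make_records(c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
                     beta = c(0.05, -0.07, 0.09, 0.11, 0.13, 0.15),
                     se = 0.04,
                     effect_allele = c("A", "G", "A", "T", "A", "C"),
                     other_allele = c("G", "A", "C", "A", "T", "A"),
                     eaf = c(0.31, 0.69, 0.3, 0.78, 0.5, 0.3))
  h <- harmonize(ex, ou)
  # rs1 direct match, untouched
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], 0.05)
  expect_false(h$flipped[h$variant_id == "rs1"])
  # rs2 swapped alleles: outcome beta negated, eaf reflected
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], 0.07)
  expect_equal(h$eaf_outcome[h$variant_id == "rs2"], 0.31)
  # rs3 allele sets irreconcilable: dropped
  expect_false("rs3" %in% h$variant_id)
  # rs4 palindromic with clear, opposite frequencies: flipped
  expect_true(h$flipped[h$variant_id == "rs4"])
  expect_equal(h$beta_outcome[h$variant_id == "rs4"], -0.11)
  # rs5 palindromic at eaf 0.50: unresolvable, dropped
  expect_false("rs5" %in% h$variant_id)
  # rs6 incompatible non-palindromic pair (C/G vs C/A): dropped
  expect_false("rs6" %in% h$variant_id)
  audit <- attr(h, "audit")
  expect_setequal(audit$variant_id, c("rs3", "rs5", "rs6"))
  expect_equal(audit$reason[audit$variant_id == "rs5"],
               "palindromic_ambiguous")
})

test_that("strand-complement records harmonize without sign change", {
  ex <- make_records("rs9", beta = 0.2, se = 0.05,
                     effect_allele = "A", other_allele = "G", eaf = 0.3)
  ou <- make_records("rs9", beta = 0.1, se = 0.04,
                     effect_allele = "T", other_allele = "C", eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_outcome, 0.1)
  expect_false(h$flipped)
  # complement plus swap flips the sign
  ou2 <- make_records("rs9", beta = 0.1, se = 0.04,
                      effect_allele = "C", other_allele = "T", eaf = 0.7)
  expect_equal(harmonize(ex, ou2)$beta_outcome, -0.1)
})

test_that("harmonization errors on zero overlap and duplicate ids", {
  ex <- make_records("rs1", 0.1, 0.05)
  ou <- make_records("rs2", 0.1, 0.05)
  expect_error(harmonize(ex, ou), "no overlapping")
  dup <- make_records(c("rs1", "rs1"), c(0.1, 0.2), 0.05)
  expect_error(harmonize(dup, ex), "duplicate")
})

test_that("four-combination driver re-selects instruments per combination", {
  set.seed(61)
  coh <- simulate_cohort(scenario_config("B", 1, beta_xy_null = FALSE,
                                         n_individuals = 20000, seed = 77))
  halves <- split_samples(coh)
  ex <- halves$exposure; ou <- halves$outcome
  gx_u <- run_gwas(ex$genotypes, ex$phenotypes$X)
  gx_a <- run_gwas(ex$genotypes, ex$phenotypes$X, ex$phenotypes$W)
  gy_u <- run_gwas(ou$genotypes, ou$phenotypes$Y)
  gy_a <- run_gwas(ou$genotypes, ou$phenotypes$Y, ou$phenotypes$W)
  four <- run_four_combinations(gx_u, gx_a, gy_u, gy_a)
  expect_named(four, c("none", "exposure", "outcome", "both"))
  # valid instruments, no confounding: every combination near the truth
  for (lbl in names(four)) {
    r <- four[[lbl]]$result
    expect_true(r$estimable)
    expect_lt(abs(r$estimate - coh$beta_xy_true), 5 * r$se)
  }
  # identical adjusted and unadjusted inputs give four identical results
  same <- run_four_combinations(gx_u, gx_u, gy_u, gy_u)
  ests <- sapply(same, function(el) el$result$estimate)
  expect_true(all(ests == ests[1]))
})

test_that("combinations selecting zero instruments are marked, not fatal", {
  coh <- quick_cohort("A", n = 20000, seed = 13)
  set.seed(13)
  halves <- split_samples(coh)
  ex <- halves$exposure; ou <- halves$outcome
  four <- run_four_combinations(
    run_gwas(ex$genotypes, ex$phenotypes$X),
    run_gwas(ex$genotypes, ex$phenotypes$X, ex$phenotypes$W),
    run_gwas(ou$genotypes, ou$phenotypes$Y),
    run_gwas(ou$genotypes, ou$phenotypes$Y, ou$phenotypes$W))
  # W-adjustment of the exposure GWAS blocks Z-X: nothing selected
  expect_false(four$exposure$result$estimable)
  expect_false(four$both$result$estimable)
  expect_true(four$none$result$estimable)
  expect_true(four$outcome$result$estimable)
})
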