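test_that("association estimates match lm and hand-rolled normal equations", {
  set.seed(42)
  n <- 15
  g <- rbinom(n, 2, 0.4)
  w <- rnorm(n)
  y <- 0.3 * g + 0.5 * w + rnorm(n)

  # unadjusted: hand-rolled normal equations on [1, g]
  X <- cbind(1, g)
  bh <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% bh)^2)
  se_h <- sqrt(rss / (n - 2) * solve(crossprod(X))[2, 2])
  a <- estimate_association(g, y)
  expect_equal(a$beta, bh[2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(a$se, se_h, tolerance = 1e-8)
  expect_equal(a$f_stat, (a$beta / a$se)^2, tolerance = 1e-12)

  # adjusted: compare against lm
  fit <- summary(lm(y ~ g + w))$coefficients
  aa <- estimate_association(g, y, w)
  expect_equal(aa$beta, fit["g", "Estimate"], tolerance = 1e-8)
  expect_equal(aa$se, fit["g", "Std. Error"], tolerance = 1e-8)
  expect_equal(aa$p_value, fit["g", "Pr(>|t|)"], tolerance = 1e-8)
  expect_equal(aa$adjusted_for, "W")
})

test_that("vectorized GWAS agrees with per-variant lm fits", {
  set.seed(8)
  n <- 200
  g <- draw_genotypes(n, 5, c(0.2, 0.8))
  w <- rnorm(n)
  y <- 0.1 * g[, 2] + 0.4 * w + rnorm(n)
  res_u <- run_gwas(g, y, trait_label = "Y")
  res_a <- run_gwas(g, y, w, trait_label = "Y")
  expect_equal(nrow(res_u), 5L)
  for (j in 1:5) {
    cf_u <- summary(lm(y ~ g[, j]))$coefficients
    cf_a <- summary(lm(y ~ g[, j] + w))$coefficients
    expect_equal(res_u$beta[j], cf_u[2, 1], tolerance = 1e-10)
    expect_equal(res_u$se[j], cf_u[2, 2], tolerance = 1e-10)
    expect_equal(res_a$beta[j], cf_a[2, 1], tolerance = 1e-10)
    expect_equal(res_a$se[j], cf_a[2, 2], tolerance = 1e-10)
  }
  expect_true(all(res_a$adjusted_for == "W"))
  expect_true(all(is.na(res_u$adjusted_for)))
  # deterministic: same call twice
  expect_identical(res_u, run_gwas(g, y, trait_label = "Y"))
})

test_that("perfect fit and null associations behave as expected", {
  set.seed(12)
  g <- rbinom(2000, 2, 0.5)
  perfect <- estimate_association(g, as.numeric(g))
  expect_equal(perfect$beta, 1, tolerance = 1e-10)
  expect_gt(perfect$f_stat, 1e10)

  # independent trait: central F, so F >= 10 is rare across 40 variants
  gm <- draw_genotypes(2000, 40, c(0.2, 0.8))
  res <- run_gwas(gm, rnorm(2000))
  expect_lt(sum(res$f_stat >= 10), 3)
})

test_that("adjusting for a full mediator removes the association", {
  coh <- quick_cohort("A", n = 20000, seed = 71)
  adj <- run_gwas(coh$genotypes, coh$phenotypes$X, coh$phenotypes$W)
  expect_lt(mean(adj$f_stat), 3)
  expect_equal(nrow(select_instruments(adj, 10)), 0L)
})

test_that("constant genotype columns are flagged, not fatal", {
  g <- cbind(v01 = rep(1L, 50), v02 = rbinom(50, 2, 0.5))
  expect_warning(res <- run_gwas(g, rnorm(50)), "constant")
  expect_true(is.na(res$beta[1]))
  expect_false(is.na(res$beta[2]))
  expect_equal(nrow(select_instruments(res, 1e-6)), 1L)
})

test_that("length mismatches and zero-variance traits error", {
  expect_error(estimate_association(1:10, rnorm(9)), "length")
  expect_error(run_gwas(matrix(1:10, 5), rnorm(5), rnorm(4)), "covariable")
  expect_error(run_gwas(matrix(rbinom(10, 2, .5), 5), rep(1, 5)),
               "zero variance")
})

test_that("instrument selection is inclusive at the F threshold", {
  assoc <- make_gwas(c("a", "b", "c"), beta = c(1, 1, 1), se = 0.1)
  assoc$f_stat <- c(9.99, 10, 144.7)
  sel <- select_instruments(assoc, 10)
  expect_equal(sel$variant_id, c("b", "c"))
  expect_equal(attr(sel, "f_threshold"), 10)
  expect_equal(attr(sel, "selection_basis"), "unadjusted")
  expect_equal(nrow(select_instruments(assoc[0, ], 10)), 0L)
  expect_error(select_instruments(assoc, -1), "positive")
})

test_that("strong-instrument selection retains nearly all variants in B", {
  # full-size cohort: exposure half of 50 000, per-variant r2 = 0.10/40
  coh <- simulate_cohort(scenario_config("B", 1, seed = 1234))
  set.seed(55)
  ex <- split_samples(coh)$exposure
  res <- run_gwas(ex$genotypes, ex$phenotypes$X)
  sel <- select_instruments(res, 10)
  expect_gte(nrow(sel), 35L)
  # expected F is about n * r2 / (1 - r2) with r2 = 0.0025 at n = 50 000
  expect_gt(mean(res$f_stat), 80)
  expect_lt(mean(res$f_stat), 190)
})

test_that("covariable-association exclusion keeps the p >= threshold boundary", {
  instr <- make_gwas(c("a", "b", "c"), beta = 1, se = 0.1)
  instr <- select_instruments(instr, 10)
  cov_assoc <- make_gwas(c("a", "b", "c"), beta = 1, se = 0.1,
                         p = c(0.04, 0.05, 0.5), trait = "W")
  kept <- filter_by_covariable_association(instr, cov_assoc, 0.05)
  expect_equal(kept$variant_id, c("b", "c"))
  # threshold near zero retains everything
  expect_equal(nrow(filter_by_covariable_association(instr, cov_assoc, 1e-12)),
               3L)
  # all strongly associated -> empty but representable
  all_low <- make_gwas(c("a", "b", "c"), beta = 1, se = 0.1, p = 1e-10,
                       trait = "W")
  expect_equal(nrow(filter_by_covariable_association(instr, all_low, 0.05)),
               0L)
  expect_error(
    filter_by_covariable_association(instr, cov_assoc[1:2, ], 0.05), "c")
  expect_error(filter_by_covariable_association(instr, cov_assoc, 0), "0, 1")
})

test_that("adjusting for independent noise leaves associations unchanged", {
  set.seed(21)
  g <- draw_genotypes(5000, 10, c(0.2, 0.8))
  y <- 0.05 * rowSums(g) + rnorm(5000)
  noise <- rnorm(5000)
  u <- run_gwas(g, y)
  a <- run_gwas(g, y, noise)
  expect_equal(a$beta, u$beta, tolerance = 0.05)
  expect_equal(a$se, u$se, tolerance = 0.01)
})
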