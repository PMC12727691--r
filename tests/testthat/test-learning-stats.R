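test_that("day-slope fits match the normal equations", {
  f <- suppressWarnings(fit_day_lm(2 * (1:6), 1:6))
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$coefficients$estimate[1], 0, tolerance = 1e-12)
  set.seed(1)
  y <- rnorm(6); d <- c(1, 1, 2, 2, 3, 3)
  f2 <- fit_day_lm(y, d)
  X <- cbind(1, d)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(unname(f2$coefficients$estimate), unname(drop(beta)),
               tolerance = 1e-10)
  expect_error(fit_day_lm(1:4, rep(1, 4)), "distinct days")
})

test_that("the region-by-day interaction recovers divergent slopes", {
  day <- rep(1:6, 2)
  region <- rep(c("TEO", "TE"), each = 6)
  metric <- ifelse(region == "TE", day * 1, 0) + 0.5
  f <- suppressWarnings(fit_region_day_interaction(metric, region, day))
  expect_equal(f$interaction, 1, tolerance = 1e-10)
  expect_lt(f$p_interaction, 1e-8)
  # equal slopes: interaction is approximately null-calibrated
  set.seed(2)
  p <- replicate(300, {
    m <- rep(1:5, 2) * 0.3 + rnorm(10)
    fit_region_day_interaction(m, rep(c("TE", "TEO"), each = 5),
                               rep(1:5, 2))$p_interaction
  })
  expect_lt(abs(mean(p < 0.05) - 0.05),
            1.96 * sqrt(0.05 * 0.95 / 300) + 0.01)
})

test_that("bootstrap day-correlation tests detect and respect structure", {
  real <- lapply(1:5, function(d) rnorm(15, 0.5 + 0.08 * d, 0.02))
  shuf <- lapply(1:5, function(d) rnorm(15, 0.5, 0.02))
  b <- bootstrap_corr_vs_day(real, shuf, n_boot = 500, seed = 3)
  expect_true(b$significant)
  expect_gt(b$delta_mean, 0.5)
  b2 <- bootstrap_corr_vs_day(real, shuf, n_boot = 500, seed = 3)
  expect_identical(b$ci, b2$ci)
  expect_error(bootstrap_corr_vs_day(real[1:2], shuf[1:2]), "3 days")
})

test_that("bootstrap correlation differences compare two observed series", {
  up <- seq(0.1, 0.9, length.out = 8)
  down <- rev(up)
  b <- bootstrap_corr_difference(up, down, 1:8, n_boot = 500, sided = "one",
                                 seed = 4)
  expect_true(b$significant)
  expect_gt(b$ci[1], 0)
  set.seed(5)
  same <- rnorm(8)
  b2 <- bootstrap_corr_difference(same, same, 1:8, n_boot = 500, seed = 6)
  expect_false(b2$significant)
  expect_equal(b2$delta_mean, 0)
})

test_that("permutation comparison agrees with exhaustive enumeration", {
  a <- c(1.2, 3.4, 2.2); b <- c(0.1, 0.6, 0.4)
  p_exact <- permutation_compare(a, b, exact = TRUE)
  # independent enumeration over all 20 splits of the pooled values
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  stats <- combn(6, 3, function(ix) {
    abs(mean(pool[ix]) - mean(pool[-ix]))
  })
  expect_equal(p_exact, mean(stats >= obs - 1e-12))
  # order invariance of the exact test
  expect_equal(permutation_compare(rev(a), b[c(2, 1, 3)], exact = TRUE),
               p_exact)
  # disjoint distributions sit at the resolution floor
  p <- permutation_compare(1:10 + 100, 1:10, n_perm = 999, seed = 7)
  expect_lt(p, 0.01)
  # identical distributions: roughly uniform p
  set.seed(8)
  ps <- replicate(200, {
    x <- rnorm(12)
    permutation_compare(x[1:6], x[7:12], n_perm = 99)
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("BH adjustment is the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.3, 4)), rep(0.3, 4))
  set.seed(9)
  for (i in 1:20) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_fdr(p), bf_bh(p))
  }
})

test_that("partial correlation equals two-stage residualization", {
  set.seed(10)
  x <- rnorm(30); cov1 <- rnorm(30)
  pc <- partial_correlation(x, x + rnorm(30, 0, 1e-8), cov1)
  expect_equal(pc$r, 1, tolerance = 1e-4)
  y2 <- 2 * cov1 + rnorm(30, 0, 1e-8)
  pc2 <- partial_correlation(rnorm(30), y2, cov1)
  expect_lt(abs(pc2$r), 0.4)
  # 10-point fixture vs residual-regression oracle
  x3 <- rnorm(10); y3 <- rnorm(10); z3 <- cbind(rnorm(10), rnorm(10))
  pc3 <- partial_correlation(x3, y3, z3)
  rx <- residuals(lm(x3 ~ z3)); ry <- residuals(lm(y3 ~ z3))
  expect_equal(pc3$r, cor(rx, ry))
  expect_equal(pc3$df, 10 - 2 - 2)
})

test_that("psychometric fits recover the generating parameters", {
  lev <- rep(morph_levels(), each = 80)
  x <- (lev - 50) / 50
  set.seed(11)
  choice <- as.integer(runif(length(x)) < plogis(3 * x + 0.5))
  f <- fit_psychometric(choice, lev)
  expect_equal(f$slope, 3, tolerance = 0.35)
  expect_equal(f$bias, 0.5, tolerance = 0.35)
  expect_false(f$capped)
  # separable data hit the cap; flat data have near-zero slope
  f2 <- fit_psychometric(as.integer(lev > 50), lev)
  expect_true(f2$capped)
  expect_equal(abs(f2$slope), 50)
  choice0 <- rep(c(0L, 1L), length.out = length(lev))
  f3 <- fit_psychometric(choice0, lev)
  expect_lt(abs(f3$slope), 0.5)
  expect_error(fit_psychometric(c(0, 1), c(0, 100)), "3 morph levels")
})

test_that("behavior regression ranks the generating region lowest by AIC", {
  set.seed(12)
  te <- c(runif(7, 0.5, 1), runif(7, 0.5, 1))
  teo <- runif(14, 0.5, 1)
  monkey <- rep(0:1, each = 7)
  behavior <- 0.2 + 0.7 * te + rnorm(14, 0, 0.03)
  res <- behavior_neural_regression(te, teo, behavior, monkey)
  expect_identical(res$best, "TE")
  expect_lt(res$models$p_te[res$models$model == "TE"], 0.01)
  expect_gt(res$models$p_teo[res$models$model == "TEO"], 0.05)
  # AIC/BIC ordering is invariant to a common affine rescaling of the
  # accuracy metrics (fixed model dimension)
  res2 <- behavior_neural_regression(10 * te - 2, 10 * teo - 2, behavior,
                                     monkey)
  expect_identical(order(res$models$aic), order(res2$models$aic))
})
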