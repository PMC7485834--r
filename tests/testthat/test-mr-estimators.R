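test_that("Wald ratios carry first-order SEs and inverse-variance weights", {
  h <- make_h(bx = 0.1, sx = 0.005, by = 0.05, sy = 0.01)
  re <- ratio_estimates(h)
  expect_equal(re$r, 0.5)
  expect_equal(re$se_r, 0.1)
  expect_equal(re$w, 100)
  # joint sign flip of exposure and outcome leaves the ratio unchanged
  h2 <- make_h(bx = -0.1, sx = 0.005, by = -0.05, sy = 0.01)
  expect_equal(ratio_estimates(h2)$r, 0.5)
  # 3-SNP toy against calculator arithmetic
  h3 <- make_h(bx = c(0.2, 0.4, 0.5), sx = 0.01,
               by = c(0.06, 0.08, 0.20), sy = c(0.02, 0.04, 0.05))
  re3 <- ratio_estimates(h3)
  expect_equal(re3$r, c(0.3, 0.2, 0.4))
  expect_equal(re3$se_r, c(0.1, 0.1, 0.1))
  expect_equal(re3$w, c(100, 100, 100))
  expect_error(ratio_estimates(make_h(c(0.1, 0), 0.01, c(0.1, 0.1), 0.01)),
               "zero exposure")
})

test_that("IVW matches the closed-form weighted least squares oracle", {
  # toy by construction: w = (100, 400), r = (0.2, 0.1) -> beta 0.12, Q 0.80
  h <- make_h(bx = c(0.1, 0.2), sx = 0.001, by = c(0.02, 0.02),
              sy = c(0.01, 0.01))
  fit <- mr_ivw(h, model = "fixed")
  expect_equal(fit$estimate$beta, 0.12, tolerance = 1e-12)
  expect_equal(fit$heterogeneity$Q, 100 * 0.08^2 + 400 * 0.02^2,
               tolerance = 1e-12)
  expect_equal(fit$estimate$se, 1 / sqrt(500), tolerance = 1e-12)
  # here Q/(k-1) = 0.8 < 1: the dispersion floor keeps the fixed SE
  mre <- mr_ivw(h, model = "multiplicative_random")
  expect_equal(mre$estimate$se, 1 / sqrt(500), tolerance = 1e-12)
  # overdispersed toy: w = (400, 1600), r = (0.2, 0.1), Q = 3.2 > k-1
  hb <- make_h(bx = c(0.1, 0.2), sx = 0.001, by = c(0.02, 0.02),
               sy = c(0.005, 0.005))
  mreb <- mr_ivw(hb, model = "multiplicative_random")
  expect_equal(mr_ivw(hb, "fixed")$heterogeneity$Q, 3.2, tolerance = 1e-12)
  expect_equal(mreb$estimate$se, sqrt(3.2) / sqrt(2000), tolerance = 1e-12)
  # zero dispersion: both models coincide
  h0 <- make_h(bx = c(1, 2, 4), sx = 0.01, by = c(0.5, 1, 2), sy = 0.01)
  expect_equal(mr_ivw(h0, "fixed")$estimate$se,
               mr_ivw(h0, "multiplicative_random")$estimate$se)
  expect_equal(mr_ivw(h0, "fixed")$estimate$beta, 0.5)
  expect_equal(mr_ivw(h0, "fixed")$heterogeneity$Q, 0)
  expect_error(mr_ivw(make_h(1, 0.1, 0.5, 0.1)), "at least 2")
})

test_that("IVW agrees with an independent fixed-effects meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(31)
  k <- 7
  h <- make_h(bx = runif(k, 0.3, 1), sx = 0.01,
              by = rnorm(k, 0.2, 0.05), sy = runif(k, 0.01, 0.05))
  re <- ratio_estimates(h)
  rma <- metafor::rma(yi = re$r, sei = re$se_r, method = "FE")
  fit <- mr_ivw(h, model = "fixed")
  expect_equal(fit$estimate$beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(fit$estimate$se, rma$se, tolerance = 1e-10)
  expect_equal(fit$heterogeneity$Q, rma$QE, tolerance = 1e-10)
})

test_that("IVW invariants: k = 2 closed form, SE scaling, OR/CI assembly", {
  h <- make_h(bx = c(0.5, 0.25), sx = 0.01, by = c(0.2, 0.15),
              sy = c(0.02, 0.03))
  re <- ratio_estimates(h)
  expect_equal(mr_ivw(h, "fixed")$estimate$beta,
               sum(re$w * re$r) / sum(re$w), tolerance = 1e-14)
  # scaling all outcome SEs by c scales the fixed SE by c, beta unchanged
  h2 <- make_h(bx = c(0.5, 0.25), sx = 0.01, by = c(0.2, 0.15),
               sy = 3 * c(0.02, 0.03))
  expect_equal(mr_ivw(h2, "fixed")$estimate$beta,
               mr_ivw(h, "fixed")$estimate$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(h2, "fixed")$estimate$se,
               3 * mr_ivw(h, "fixed")$estimate$se, tolerance = 1e-12)
  est <- mr_ivw(h, "fixed")$estimate
  expect_equal(est$or, exp(est$beta))
  expect_equal(est$ci_low, exp(est$beta - qnorm(0.975) * est$se))
  expect_equal(est$ci_high, exp(est$beta + qnorm(0.975) * est$se))
})

test_that("Egger regression matches the normal-equations oracle", {
  # exact linear data: intercept and slope recovered with zero residual Q
  bx <- c(0.2, 0.4, 0.6, 0.8)
  h <- make_h(bx = bx, sx = 0.01, by = 0.03 + 0.5 * bx, sy = 0.02)
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$intercept$value, 0.03, tolerance = 1e-12)
  expect_equal(e$heterogeneity$Q, 0, tolerance = 1e-18)

  # 4-point toy with unequal weights vs an explicit 2x2 solve
  by <- c(0.05, 0.24, 0.28, 0.45)
  sy <- c(0.02, 0.05, 0.03, 0.04)
  h2 <- make_h(bx = bx, sx = 0.01, by = by, sy = sy)
  w <- 1 / sy^2
  X <- cbind(1, bx)
  coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * by))
  e2 <- mr_egger(h2)
  expect_equal(e2$intercept$value, coefs[1], tolerance = 1e-10)
  expect_equal(e2$slope$beta, coefs[2], tolerance = 1e-10)
  resid <- by - X %*% coefs
  Q <- sum(w * resid^2)
  disp <- max(1, sqrt(Q / 2))
  covm <- solve(t(X) %*% (w * X)) * disp^2
  expect_equal(e2$slope$se, sqrt(covm[2, 2]), tolerance = 1e-10)
  expect_equal(e2$intercept$se, sqrt(covm[1, 1]), tolerance = 1e-10)
  expect_error(mr_egger(make_h(c(1, 2), 0.01, c(1, 2), 0.1)), "at least 3")
})

test_that("Egger orients instruments to positive exposure effects", {
  bx <- c(0.2, -0.4, 0.6)
  by <- 0.02 + 0.3 * abs(bx)
  by[2] <- -by[2]  # outcome follows the joint flip
  h <- make_h(bx = bx, sx = 0.01, by = by, sy = 0.02)
  e <- mr_egger(h)
  expect_equal(e$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(e$intercept$value, 0.02, tolerance = 1e-10)
})

test_that("Egger constrained through the origin reproduces IVW", {
  set.seed(17)
  k <- 9
  bx <- runif(k, 0.2, 1)
  sy <- runif(k, 0.01, 0.06)
  by <- 0.25 * bx + rnorm(k, 0, 0.03)
  h <- make_h(bx = bx, sx = 0.01, by = by, sy = sy)
  w <- 1 / sy^2
  slope_origin <- sum(w * bx * by) / sum(w * bx^2)
  expect_equal(mr_ivw(h, "fixed")$estimate$beta, slope_origin,
               tolerance = 1e-12)
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  # equal weights, odd k: ordinary median
  h <- make_h(bx = rep(1, 3), sx = 0.01, by = c(0.1, 0.5, 0.9), sy = 0.1)
  expect_equal(mr_weighted_median(h, n_boot = 0)$beta, 0.5)
  # weights (1,1,8) on ratios (0.1,0.2,0.3): hand interpolation
  # p = (0.1,0.1,0.8), s = (0.05,0.15,0.6);
  # beta = 0.2 + 0.1 * (0.5-0.15)/(0.6-0.15)
  h2 <- make_h(bx = rep(1, 3), sx = 0.01, by = c(0.1, 0.2, 0.3),
               sy = c(1, 1, 1 / sqrt(8)))
  expect_equal(mr_weighted_median(h2, n_boot = 0)$beta,
               0.2 + 0.1 * 0.35 / 0.45, tolerance = 1e-12)
  # equal weights, even k reduces to the midpoint interpolation
  h3 <- make_h(bx = rep(1, 4), sx = 0.01, by = c(0.1, 0.2, 0.6, 0.9), sy = 0.1)
  expect_equal(mr_weighted_median(h3, n_boot = 0)$beta, 0.4, tolerance = 1e-12)
  expect_error(mr_weighted_median(make_h(c(1, 1), 0.1, c(1, 1), 0.1)),
               "at least 3")
})

test_that("bootstrap SEs are reproducible given seed and differ across seeds", {
  set.seed(4)
  k <- 10
  h <- make_h(bx = runif(k, 0.5, 1), sx = 0.05,
              by = rnorm(k, 0.2, 0.05), sy = 0.05)
  a <- mr_weighted_median(h, n_boot = 200, seed = 99)
  b <- mr_weighted_median(h, n_boot = 200, seed = 99)
  c <- mr_weighted_median(h, n_boot = 200, seed = 100)
  expect_identical(a$se, b$se)
  expect_false(identical(a$se, c$se))
  expect_gt(a$se, 0)
})

test_that("mode estimator finds the dominant ratio cluster", {
  # degenerate: all ratios equal
  h0 <- make_h(bx = rep(1, 4), sx = 0.01, by = rep(0.5, 4), sy = 0.1)
  expect_equal(mr_mode(h0, n_boot = 0)$beta, 0.5)

  # bimodal 7 vs 3 with equal weights: mode sits near the majority cluster;
  # cross-check against an independent dense grid search on the same kernel
  r <- c(0.18, 0.19, 0.2, 0.2, 0.21, 0.22, 0.2, 1.0, 1.02, 0.98)
  h <- make_h(bx = rep(1, 10), sx = 0.01, by = r, sy = 0.1)
  est <- mr_mode(h, weighted = FALSE, n_boot = 0)
  k <- length(r)
  bw <- 0.9 * min(sd(r), IQR(r) / 1.349) * k^(-1 / 5)
  grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 200001)
  dens <- colSums(outer(r, grid, function(a, b) dnorm((b - a) / bw))) / k
  oracle <- grid[which.max(dens)]
  expect_equal(est$beta, oracle, tolerance = 1e-4)
  expect_lt(abs(est$beta - 0.2), 0.05)

  # skewed weights toward the minority cluster move the weighted mode
  sy <- c(rep(0.3, 7), rep(0.03, 3))
  hw <- make_h(bx = rep(1, 10), sx = 0.01, by = r, sy = sy)
  mw <- mr_mode(hw, weighted = TRUE, n_boot = 0)
  ms <- mr_mode(hw, weighted = FALSE, n_boot = 0)
  expect_gt(abs(mw$beta - ms$beta), 0.1)
  expect_lt(abs(mw$beta - 1.0), 0.05)
})

test_that("Steiger test infers the causal direction from explained variance", {
  k <- 20
  h <- make_h(bx = rep(0.2, k), sx = 0.01, by = rep(0.02, k), sy = 0.01,
              n_exposure = 1e5, ncase = 6e4, ncontrol = 5e4)
  st <- steiger_test(h)
  expect_true(st$direction_correct)
  expect_gt(st$r2_exposure, st$r2_outcome)
  expect_lt(st$pval, 0.05)
  # symmetric null: equal r2 at equal n gives p ~ 1
  hs <- make_h(bx = 0.2, sx = 0.01, by = 0.2, sy = 0.01,
               n_exposure = 1e5, ncase = 1e5, ncontrol = 1e5)
  # outcome effective n = 4/(1/1e5 + 1/1e5) = 2e5; rebuild with matched n
  hs2 <- make_h(bx = 0.2, sx = 0.01, by = 0.2, sy = 0.01,
                n_exposure = 2e5, ncase = 1e5, ncontrol = 1e5)
  expect_gt(steiger_test(hs2)$pval, 0.999)
  expect_error(steiger_test(make_h(1, 0.1, 1, 0.1)), "sample sizes missing")
  # simulated forward-causal data: correct direction in every seed tried
  ok <- vapply(1:20, function(s) {
    d <- sim_h(fast_config(seed = 200 + s, n_exposure = 1e5))
    steiger_test(d$h)$direction_correct
  }, logical(1))
  expect_true(all(ok))
})

test_that("analytic power is alpha at the null and monotone in r2 and OR", {
  expect_equal(mr_power(6e4, 5e4, 0.05, or_alt = 1, alpha = 0.01), 0.01,
               tolerance = 1e-12)
  p1 <- mr_power(6e4, 5e4, 0.02, 1.05)
  p2 <- mr_power(6e4, 5e4, 0.04, 1.05)
  p3 <- mr_power(6e4, 5e4, 0.02, 1.10)
  expect_gt(p2, p1)
  expect_gt(p3, p1)
  expect_error(mr_power(100, 100, 1.2, 1.1), "r2_exposure")
  expect_error(mr_power(100, 100, 0.1, -1), "or_alt")
})

test_that("the tidy estimator battery has the reporting shape", {
  set.seed(8)
  k <- 12
  h <- make_h(bx = runif(k, 0.3, 1), sx = 0.02,
              by = rnorm(k, 0.15, 0.04), sy = 0.04)
  tab <- mr_all(h, n_boot = 50, seed = 3)
  expect_equal(tab$method, c("ivw_mre", "egger", "weighted_median",
                             "mode_weighted"))
  expect_true(all(c("or", "ci_low", "ci_high", "Q", "Q_df", "Q_pval",
                    "egger_intercept") %in% names(tab)))
  expect_equal(tab$k, rep(k, 4))
  expect_false(any(is.na(tab$beta)))
})
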