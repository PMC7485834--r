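# build a bare mvmr_set from matrices
make_mvmr <- function(B, SE_B, y, sy, names = paste0("x", seq_len(ncol(B)))) {
  structure(list(snp_ids = sprintf("rs%03d", seq_len(nrow(B))),
                 B = B, SE_B = SE_B, beta_out = y, se_out = sy,
                 exposure_names = names),
            class = "mvmr_set")
}

test_that("multivariable fit recovers exact linear data and detects collinearity", {
  set.seed(2)
  m <- 8
  B <- cbind(runif(m, 0.2, 1), runif(m, -1, -0.2))
  y <- drop(B %*% c(0.2, -0.1))
  s <- make_mvmr(B, matrix(0.01, m, 2), y, rep(0.05, m))
  fit <- mvmr_fit(s)
  expect_equal(fit$estimates$beta, c(0.2, -0.1), tolerance = 1e-12)
  expect_equal(fit$QA, 0, tolerance = 1e-16)
  expect_equal(fit$QA_df, m - 2)

  sdup <- make_mvmr(cbind(B[, 1], 2 * B[, 1]), matrix(0.01, m, 2), y,
                    rep(0.05, m), names = c("a", "b"))
  expect_error(mvmr_fit(sdup), "collinear")
  szero <- make_mvmr(cbind(B[, 1], 0), matrix(0.01, m, 2), y, rep(0.05, m),
                     names = c("a", "zero_col"))
  expect_error(mvmr_fit(szero), "zero_col")
})

test_that("multivariable fit matches the explicit matrix-inverse oracle", {
  # m = 4, K = 2 with unequal weights: hand linear algebra
  B <- rbind(c(0.5, 0.1), c(0.3, 0.4), c(0.8, -0.2), c(0.1, 0.6))
  y <- c(0.12, 0.05, 0.2, -0.03)
  sy <- c(0.02, 0.05, 0.03, 0.04)
  s <- make_mvmr(B, matrix(0.01, 4, 2), y, sy)
  W <- diag(1 / sy^2)
  A <- t(B) %*% W %*% B
  beta_oracle <- solve(A) %*% t(B) %*% W %*% y
  QA <- sum((1 / sy^2) * (y - B %*% beta_oracle)^2)
  covm <- solve(A) * max(1, QA / 2)
  fit <- mvmr_fit(s)
  expect_equal(fit$estimates$beta, drop(beta_oracle), tolerance = 1e-10)
  expect_equal(fit$QA, QA, tolerance = 1e-10)
  expect_equal(fit$estimates$se, sqrt(diag(covm)), tolerance = 1e-10)
  fixed <- mvmr_fit(s, model = "fixed")
  expect_equal(fixed$estimates$se, sqrt(diag(solve(A))), tolerance = 1e-10)
})

test_that("with one exposure the multivariable fit reproduces IVW exactly", {
  set.seed(5)
  k <- 15
  bx <- runif(k, 0.2, 1)
  by <- 0.3 * bx + rnorm(k, 0, 0.05)
  sy <- runif(k, 0.02, 0.06)
  h <- make_h(bx = bx, sx = 0.01, by = by, sy = sy)
  s <- make_mvmr(matrix(bx), matrix(0.01, k, 1), by, sy, names = "x")
  for (model in c("fixed", "multiplicative_random")) {
    ivw <- mr_ivw(h, model = model)
    mv <- mvmr_fit(s, model = model)
    expect_equal(mv$estimates$beta, ivw$estimate$beta, tolerance = 1e-12)
    expect_equal(mv$estimates$se, ivw$estimate$se, tolerance = 1e-12)
    expect_equal(mv$QA, ivw$heterogeneity$Q, tolerance = 1e-12)
  }
})

test_that("permuting exposure order permutes results correspondingly", {
  set.seed(6)
  m <- 20
  B <- cbind(runif(m, 0.2, 1), runif(m, -0.5, 0.5), runif(m, 0.1, 0.9))
  y <- drop(B %*% c(0.1, -0.2, 0.05)) + rnorm(m, 0, 0.02)
  SE <- matrix(runif(m * 3, 0.01, 0.03), m, 3)
  sy <- runif(m, 0.02, 0.05)
  s1 <- make_mvmr(B, SE, y, sy, names = c("a", "b", "c"))
  perm <- c(3, 1, 2)
  s2 <- make_mvmr(B[, perm], SE[, perm], y, sy, names = c("a", "b", "c")[perm])
  f1 <- mvmr_fit(s1)
  f2 <- mvmr_fit(s2)
  expect_equal(f2$estimates$beta[match(f1$estimates$exposure,
                                       f2$estimates$exposure)],
               f1$estimates$beta, tolerance = 1e-12)
  expect_equal(f1$QA, f2$QA, tolerance = 1e-12)
  cs1 <- conditional_strength(s1)
  cs2 <- conditional_strength(s2)
  expect_equal(cs2$cond_F[match(cs1$exposure, cs2$exposure)], cs1$cond_F,
               tolerance = 1e-10)
})

test_that("conditional F separates strong from collinear exposures", {
  set.seed(7)
  m <- 30
  b1 <- runif(m, 0.5, 1)
  b2 <- runif(m, -1, 1)  # orthogonal-ish to b1
  SE <- matrix(0.02, m, 2)
  y <- rnorm(m, 0, 0.05)
  s <- make_mvmr(cbind(b1, b2), SE, y, rep(0.05, m))
  cs <- conditional_strength(s)
  expect_true(all(cs$cond_F > 10))
  expect_false(any(cs$weak))
  # proportional columns: residuals vanish, F ~ 0
  sp <- make_mvmr(cbind(b1, 2 * b1), SE, y, rep(0.05, m))
  csp <- conditional_strength(sp)
  expect_lt(max(csp$cond_F), 1e-10)
  expect_true(all(csp$weak))
})

test_that("conditional F falls as exposure effect correlation rises", {
  fs <- vapply(c(0.2, 0.6, 0.9, 0.99), function(rho) {
    cfg <- simulation_config(
      m_snps = 800, exposure_names = c("a", "b"), prop_causal = 0.2,
      h2_x = 0.1, effect_corr = matrix(c(1, rho, rho, 1), 2),
      theta = c(0.1, 0), n_exposure = 2e5, seed = 42)
    st <- simulate_gwas_pair(cfg)
    s <- build_mvmr_set(st$exposures, st$outcome)
    mean(conditional_strength(s)$cond_F)
  }, numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("joint instrument assembly honours completeness and the union rule", {
  # disjoint significant SNPs, all independent: union retained
  e1 <- make_tab(paste0("rs", 1:6), c(1, 1, 0.1, 0.1, 0.1, 0.1), 0.1,
                 pval = c(1e-10, 1e-9, 0.5, 0.5, 0.5, 0.5), trait = "a",
                 eaf = 0.3)
  e2 <- make_tab(paste0("rs", 1:6), c(0.1, 0.1, 1, 1, 0.1, 0.1), 0.1,
                 pval = c(0.5, 0.5, 1e-10, 1e-9, 0.5, 0.5), trait = "b",
                 eaf = 0.3)
  out <- make_tab(paste0("rs", 1:6), 0.05, 0.1, eaf = 0.3, type = "binary")
  s <- build_mvmr_set(list(e1, e2), out)
  expect_setequal(s$snp_ids, paste0("rs", 1:4))
  expect_equal(ncol(s$B), 2)

  # SNP significant for exposure 1 but absent from exposure 2: excluded
  e2b <- subset(as.data.frame(e2), snp_id != "rs1")
  e2b <- gwas_table(e2b, "b", validate = FALSE)
  s2 <- build_mvmr_set(list(e1, e2b), out)
  expect_false("rs1" %in% s2$snp_ids)

  # LD pair inside the union: jointly re-clumped by best p across exposures
  e1c <- make_tab(paste0("rs", 1:6), c(1, 1, 0.1, 0.1, 1, 0.1), 0.1,
                  pval = c(1e-10, 1e-9, 0.5, 0.5, 1e-9, 0.5), trait = "a",
                  eaf = 0.3)
  ids <- paste0("rs", 1:6)
  r2 <- diag(6)
  r2[1, 3] <- r2[3, 1] <- 0.9  # rs1 (best p 1e-10 in a) vs rs3 (1e-10 in b)
  r2[2, 4] <- r2[4, 2] <- 0.9  # rs2 (1e-9) vs rs4 (1e-9): tie -> rs2 by id
  ld <- ld_matrix(ids, r2)
  s3 <- build_mvmr_set(list(e1c, e2), out, ld = ld)
  expect_setequal(s3$snp_ids, c("rs1", "rs2", "rs5"))
})

test_that("multivariable heterogeneity pruning removes the gross outlier first", {
  set.seed(11)
  m <- 12
  B <- cbind(runif(m, 0.3, 1), runif(m, -1, -0.3))
  y <- drop(B %*% c(0.2, -0.1)) + rnorm(m, 0, 0.01)
  sy <- rep(0.05, m)
  y[4] <- y[4] + 1.5  # gross invalid instrument
  s <- make_mvmr(B, matrix(0.01, m, 2), y, sy)
  pr <- mvmr_heterogeneity_prune(s)
  expect_equal(pr$log$snp_id[1], "rs004")
  fit <- mvmr_fit(pr$set, model = "fixed")
  expect_gte(fit$QA_pval, 0.05)
  # already-homogeneous set: no removals
  s0 <- make_mvmr(B, matrix(0.01, m, 2), drop(B %*% c(0.2, -0.1)) +
                    rnorm(m, 0, 0.01), sy)
  expect_equal(nrow(mvmr_heterogeneity_prune(s0)$log), 0)
  # floor at K + 2 instruments
  s_small <- make_mvmr(B[1:5, ], matrix(0.01, 5, 2), c(y[1:4], 5), rep(0.01, 5))
  pr2 <- mvmr_heterogeneity_prune(s_small)
  expect_gte(length(pr2$set$snp_ids), 4)
})
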