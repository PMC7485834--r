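#' LD-score panel
#'
#' @param snp_ids character rsIDs.
#' @param ld_score per-SNP LD score (>= 1: a SNP tags itself).
#' @param M total number of SNPs the panel represents (>= rows).
#' @return An `ld_score_panel`.
#' @export
ld_score_panel <- function(snp_ids, ld_score, M) {
  if (any(ld_score < 1)) stop("ld_score_panel: LD scores must be >= 1")
  if (M < length(snp_ids)) stop("ld_score_panel: M smaller than panel size")
  structure(list(snp_ids = as.character(snp_ids),
                 ld_score = as.numeric(ld_score), M = M),
            class = "ld_score_panel")
}

#' Read an LD-score panel from TSV (columns snp_id, ld_score)
#' @param path panel file.
#' @param M total SNP count represented (sidecar metadata).
#' @return An [ld_score_panel()].
#' @export
read_ld_score_panel <- function(path, M) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  ld_score_panel(raw$snp_id, raw$ld_score, M)
}

# contiguous block assignment for the delete-one-block jackknife
jackknife_blocks <- function(n_snps, n_blocks) {
  if (n_snps < 3 * n_blocks) {
    n_blocks <- max(2L, n_snps %/% 3L)
    warning("ldsc: too few SNPs; reducing jackknife blocks to ", n_blocks)
  }
  list(id = as.integer(((seq_len(n_snps) - 1L) * n_blocks) %/% n_snps + 1L),
       n_blocks = as.integer(n_blocks))
}

# Shared two-step regression kernel of y on ld scores ell with fixed
# weights wt: step 1 estimates the intercept on the subset y < chisq_max
# (2-parameter WLS); step 2 estimates the slope on all SNPs with that
# intercept fixed. Returns full-data fit plus delete-one-block estimates.
ldsc_kernel <- function(y, ell, wt, block_id, n_blocks, chisq_max = 30) {
  sub <- abs(y) < chisq_max  # symmetric: cross-trait products can be negative
  # per-block sufficient statistics
  acc <- function(v) {
    s <- rep(0, n_blocks)
    t <- tapply(v, block_id, sum)
    s[as.integer(names(t))] <- t
    s
  }
  # step-1 sums (intercept subset)
  s_w <- acc(wt * sub); s_wx <- acc(wt * ell * sub)
  s_wxx <- acc(wt * ell^2 * sub); s_wy <- acc(wt * y * sub)
  s_wxy <- acc(wt * ell * y * sub)
  # step-2 sums (all SNPs)
  a_wxx <- acc(wt * ell^2); a_wxy <- acc(wt * ell * y); a_wx <- acc(wt * ell)

  fit_from <- function(drop = 0) {
    keep <- if (drop == 0) rep(TRUE, n_blocks) else seq_len(n_blocks) != drop
    sw <- sum(s_w[keep]); swx <- sum(s_wx[keep]); swxx <- sum(s_wxx[keep])
    swy <- sum(s_wy[keep]); swxy <- sum(s_wxy[keep])
    det <- sw * swxx - swx^2
    intercept <- (swxx * swy - swx * swxy) / det
    slope <- (sum(a_wxy[keep]) - intercept * sum(a_wx[keep])) / sum(a_wxx[keep])
    c(intercept = intercept, slope = slope)
  }
  full <- fit_from(0)
  jack <- vapply(seq_len(n_blocks), fit_from, numeric(2))
  list(intercept = full[["intercept"]], slope = full[["slope"]],
       jack_intercept = jack[1, ], jack_slope = jack[2, ])
}

jackknife_se <- function(theta_i) {
  g <- length(theta_i)
  sqrt((g - 1) / g * sum((theta_i - mean(theta_i))^2))
}

# OLS prefit of y on ell, used only to build regression weights; the
# predicted mean is floored to keep weights finite
ldsc_prefit <- function(y, ell, floor_at = 0.05) {
  vx <- stats::var(ell)
  slope <- if (vx > 0) stats::cov(y, ell) / vx else 0
  int <- mean(y) - slope * mean(ell)
  pmax(int + slope * ell, floor_at)
}

#' Univariate LD-score regression
#'
#' Regresses squared z-scores on LD scores: `E[z^2] = intercept +
#' (n h2 / M) l_j`. The intercept absorbs confounding inflation; the slope
#' yields the SNP heritability `h2`. Two-step estimation (intercept from
#' the chi-square < 30 subset, then the slope on all SNPs with the
#' intercept fixed) with heteroskedasticity/oversampling weights
#' `1 / (2 l_j f(l_j)^2)` fixed from an OLS prefit, and delete-one-block
#' jackknife SEs over contiguous SNP blocks.
#'
#' @param z per-SNP z-scores aligned to the panel.
#' @param n GWAS sample size.
#' @param panel an [ld_score_panel()].
#' @param n_blocks jackknife blocks (default 200; reduced with a warning
#'   when fewer than 3 SNPs per block are available).
#' @param chisq_max step-1 chi-square cutoff (default 30).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`, and the
#'   per-block jackknife estimates.
#' @export
univariate_ldsc <- function(z, n, panel, n_blocks = 200, chisq_max = 30) {
  stopifnot(inherits(panel, "ld_score_panel"), length(z) == length(panel$ld_score),
            n > 0)
  ell <- panel$ld_score
  y <- z^2
  f <- ldsc_prefit(y, ell)
  wt <- 1 / (pmax(ell, 1) * 2 * f^2)
  bl <- jackknife_blocks(length(y), n_blocks)
  fit <- ldsc_kernel(y, ell, wt, bl$id, bl$n_blocks, chisq_max)
  scale <- panel$M / n
  list(h2 = fit$slope * scale,
       h2_se = jackknife_se(fit$jack_slope * scale),
       intercept = fit$intercept,
       intercept_se = jackknife_se(fit$jack_intercept),
       jack_h2 = fit$jack_slope * scale,
       jack_intercept = fit$jack_intercept,
       n_blocks = bl$n_blocks)
}

#' Cross-trait LD-score regression
#'
#' Regresses z-score products on LD scores:
#' `E[z1 z2] = intercept + (sqrt(n1 n2) rho_g / M) l_j`, where the
#' intercept absorbs sample overlap and the slope yields the genetic
#' covariance `rho_g`. The genetic correlation is
#' `r_g = rho_g / sqrt(h2_1 h2_2)` using the univariate fits of each
#' trait; all three regressions share the same block partition so the
#' jackknife propagates the full uncertainty of the ratio. `r_g` is
#' reported only when both heritabilities are positive.
#'
#' @param z1,z2 per-SNP z-scores aligned to the panel.
#' @param n1,n2 GWAS sample sizes.
#' @param n_overlap shared samples (informational; overlap enters through
#'   the estimated cross-trait intercept, which is never fixed).
#' @param panel an [ld_score_panel()].
#' @param n_blocks jackknife blocks (default 200).
#' @param chisq_max step-1 cutoff (default 30).
#' @return An `ldsc_fit`: `h2_1`, `h2_2` (+ SEs), `intercept_1`,
#'   `intercept_2`, `intercept_ct` (+ SEs), `rho_g`, `rho_g_se`, `r_g`,
#'   `r_g_se`, `r_g_z`, `pval`.
#' @export
cross_trait_ldsc <- function(z1, z2, n1, n2, n_overlap = 0, panel,
                             n_blocks = 200, chisq_max = 30) {
  stopifnot(inherits(panel, "ld_score_panel"),
            length(z1) == length(panel$ld_score),
            length(z2) == length(panel$ld_score))
  ell <- panel$ld_score
  bl <- jackknife_blocks(length(ell), n_blocks)
  M <- panel$M

  fit_one <- function(y, wt) ldsc_kernel(y, ell, wt, bl$id, bl$n_blocks, chisq_max)

  f1 <- ldsc_prefit(z1^2, ell)
  f2 <- ldsc_prefit(z2^2, ell)
  u1 <- fit_one(z1^2, 1 / (pmax(ell, 1) * 2 * f1^2))
  u2 <- fit_one(z2^2, 1 / (pmax(ell, 1) * 2 * f2^2))

  yx <- z1 * z2
  c0 <- ldsc_prefit(yx, ell, floor_at = -Inf)
  ct <- fit_one(yx, 1 / (pmax(ell, 1) * (f1 * f2 + c0^2)))

  h2_1 <- u1$slope * M / n1
  h2_2 <- u2$slope * M / n2
  rho_g <- ct$slope * M / sqrt(n1 * n2)

  rg_from <- function(h1, h2, rho) {
    ifelse(h1 > 0 & h2 > 0, rho / sqrt(h1 * h2), NA_real_)
  }
  r_g <- rg_from(h2_1, h2_2, rho_g)
  jack_rg <- rg_from(u1$jack_slope * M / n1, u2$jack_slope * M / n2,
                     ct$jack_slope * M / sqrt(n1 * n2))
  r_g_se <- if (anyNA(jack_rg)) NA_real_ else jackknife_se(jack_rg)
  z_rg <- r_g / r_g_se

  structure(list(
    h2_1 = h2_1, h2_1_se = jackknife_se(u1$jack_slope * M / n1),
    h2_2 = h2_2, h2_2_se = jackknife_se(u2$jack_slope * M / n2),
    intercept_1 = u1$intercept, intercept_1_se = jackknife_se(u1$jack_intercept),
    intercept_2 = u2$intercept, intercept_2_se = jackknife_se(u2$jack_intercept),
    intercept_ct = ct$intercept, intercept_ct_se = jackknife_se(ct$jack_intercept),
    rho_g = rho_g, rho_g_se = jackknife_se(ct$jack_slope * M / sqrt(n1 * n2)),
    r_g = r_g, r_g_se = r_g_se, r_g_z = z_rg,
    pval = 2 * stats::pnorm(-abs(z_rg)),
    n_overlap = n_overlap, n_blocks = bl$n_blocks
  ), class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat(sprintf("<ldsc_fit> h2: %.4f (%.4f) / %.4f (%.4f)\n",
              x$h2_1, x$h2_1_se, x$h2_2, x$h2_2_se))
  cat(sprintf("  rho_g = %.4f (%.4f); r_g = %.4f (%.4f), p = %.3g\n",
              x$rho_g, x$rho_g_se, x$r_g, x$r_g_se, x$pval))
  invisible(x)
}

#' Bonferroni threshold over independent partitions
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of LD-independent partitions tested (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (alpha <= 0 || alpha >= 1) stop("bonferroni_threshold: alpha outside (0, 1)")
  if (n_tests < 1 || n_tests != round(n_tests)) {
    stop("bonferroni_threshold: n_tests must be a positive integer")
  }
  alpha / n_tests
}
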