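# Run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. Bootstrap SEs are thus bit-reproducible for a
# given (seed, n_boot) without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

Z95 <- stats::qnorm(0.975)

new_mr_estimate <- function(method, k, beta, se) {
  pval <- if (is.na(se) || se <= 0) NA_real_ else 2 * stats::pnorm(-abs(beta / se))
  structure(list(method = method, k = as.integer(k), beta = beta, se = se,
                 pval = pval, or = exp(beta),
                 ci_low = exp(beta - Z95 * se),
                 ci_high = exp(beta + Z95 * se)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (k=%d): OR %.4f [%.4f, %.4f], p = %.3g\n",
              x$method, x$k, x$or, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

new_heterogeneity <- function(Q, df) {
  structure(list(Q = Q, df = as.integer(df),
                 pval = stats::pchisq(Q, df = df, lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' Per-SNP Wald ratio estimates
#'
#' For each instrument, the ratio `r_j = b_Yj / b_Xj` with first-order
#' standard error `se_Yj / |b_Xj|` and inverse-variance weight
#' `w_j = b_Xj^2 / se_Yj^2` (the reciprocal squared ratio SE).
#'
#' @param h single-exposure `harmonized_set`; all exposure betas must be
#'   nonzero.
#' @return data.frame with columns `snp_id`, `r`, `se_r`, `w`.
#' @export
ratio_estimates <- function(h) {
  h <- single_exposure(h, "ratio_estimates")
  bx <- h$beta_exp[, 1]
  if (any(bx == 0)) {
    stop("ratio_estimates: zero exposure effect for ",
         paste(h$snp$snp_id[bx == 0], collapse = ", "))
  }
  data.frame(snp_id = h$snp$snp_id,
             r = h$beta_out / bx,
             se_r = h$se_out / abs(bx),
             w = bx^2 / h$se_out^2,
             stringsAsFactors = FALSE)
}

#' Inverse-variance weighted MR
#'
#' Weighted mean of the Wald ratios. Under the fixed-effects model the SE
#' is `(sum w_j)^(-1/2)`; under the multiplicative random-effects model it
#' is scaled by the residual overdispersion `max(1, sqrt(Q / (k - 1)))`,
#' floored at 1 so underdispersion is never rewarded.
#'
#' @param h single-exposure `harmonized_set` with k >= 2 (use
#'   [mr_wald()] for a single instrument).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return `list(estimate = mr_estimate, heterogeneity = mr_heterogeneity)`
#'   where heterogeneity carries Cochran's Q on k - 1 df.
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  re <- ratio_estimates(h)
  k <- nrow(re)
  if (k < 2) stop("mr_ivw: needs at least 2 instruments")
  fit <- ivw_kernel(re$r, re$w)
  se_fixed <- 1 / sqrt(sum(re$w))
  disp <- if (model == "multiplicative_random") {
    max(1, sqrt(fit$Q / (k - 1)))
  } else 1
  method <- if (model == "fixed") "ivw_fe" else "ivw_mre"
  list(estimate = new_mr_estimate(method, k, fit$beta, se_fixed * disp),
       heterogeneity = new_heterogeneity(fit$Q, k - 1))
}

#' Single-instrument Wald estimate
#' @param h single-exposure `harmonized_set` with exactly 1 instrument.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald <- function(h) {
  re <- ratio_estimates(h)
  if (nrow(re) != 1) stop("mr_wald: expects exactly one instrument")
  new_mr_estimate("wald", 1L, re$r, re$se_r)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with an
#' intercept, weights `1 / se_Yj^2`, after orienting every instrument so
#' the exposure beta is positive (flipping exposure and outcome jointly).
#' A nonzero intercept indicates directional pleiotropy. Slope and
#' intercept SEs carry the multiplicative overdispersion
#' `max(1, sqrt(Q_egger / (k - 2)))`.
#'
#' @param h single-exposure `harmonized_set` with k >= 3.
#' @return list with `slope` (an `mr_estimate`), `intercept`
#'   (`value`/`se`/`pval`), and `heterogeneity` (Q on k - 2 df).
#' @export
mr_egger <- function(h) {
  h <- single_exposure(h, "mr_egger")
  k <- n_instruments(h)
  if (k < 3) stop("mr_egger: needs at least 3 instruments")
  s <- sign(h$beta_exp[, 1])
  if (any(s == 0)) stop("mr_egger: zero exposure effect")
  bx <- abs(h$beta_exp[, 1])
  by <- h$beta_out * s
  w <- 1 / h$se_out^2

  # closed-form weighted normal equations for [intercept, slope]
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (abs(det) < .Machine$double.eps * sw * swxx) {
    stop("mr_egger: degenerate design (constant exposure betas)")
  }
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  Q <- sum(w * resid^2)
  disp <- max(1, sqrt(Q / (k - 2)))
  var_slope <- sw / det * disp^2
  var_int <- swxx / det * disp^2
  int_se <- sqrt(var_int)
  list(slope = new_mr_estimate("egger", k, slope, sqrt(var_slope)),
       intercept = list(value = intercept, se = int_se,
                        pval = 2 * stats::pnorm(-abs(intercept / int_se))),
       heterogeneity = new_heterogeneity(Q, k - 2))
}

# weighted median of values `x` with normalized weights `p`: linear
# interpolation of the ordered values at cumulative-midpoint 0.5
weighted_median_point <- function(x, p) {
  o <- order(x)
  x <- x[o]
  p <- p[o] / sum(p)
  s <- cumsum(p) - p / 2
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  j <- findInterval(0.5, s)
  x[j] + (x[j + 1] - x[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# parametric bootstrap SE for ratio-based point estimators: resample
# exposure and outcome betas from their estimation distributions
boot_se <- function(h, point_fun, n_boot, seed) {
  if (is.null(n_boot) || n_boot < 2) return(NA_real_)
  bx <- h$beta_exp[, 1]; sx <- h$se_exp[, 1]
  by <- h$beta_out; sy <- h$se_out
  k <- length(bx)
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(i) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, by, sy)
      bxs[bxs == 0] <- .Machine$double.eps
      point_fun(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
    stats::sd(est)
  })
}

#' Weighted-median MR estimator
#'
#' The weighted median of the Wald ratios: order the per-SNP ratios, form
#' normalized inverse-variance weights `p_j` and cumulative midpoints
#' `s_j = cum(p)_j - p_j / 2`, and interpolate the ordered ratios at
#' `s = 0.5`. Consistent when at least half the weight comes from valid
#' instruments. SE by parametric bootstrap (normal resampling of exposure
#' and outcome betas).
#'
#' @param h single-exposure `harmonized_set` with k >= 3.
#' @param n_boot bootstrap replicates for the SE (default 1000; 0 skips the
#'   bootstrap and reports `NA` SE).
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  re <- ratio_estimates(h)
  k <- nrow(re)
  if (k < 3) stop("mr_weighted_median: needs at least 3 instruments")
  beta <- weighted_median_point(re$r, re$w)
  se <- boot_se(h, function(r, w) weighted_median_point(r, w), n_boot, seed)
  new_mr_estimate("weighted_median", k, beta, se)
}

# bandwidth and argmax of a weighted normal-kernel density over ratios
mode_bandwidth <- function(r, bandwidth_factor) {
  spread <- min(stats::sd(r), stats::IQR(r) / 1.349)
  bandwidth_factor * 0.9 * spread * length(r)^(-1 / 5)
}

mode_point <- function(r, p, bandwidth_factor) {
  p <- p / sum(p)
  hb <- mode_bandwidth(r, bandwidth_factor)
  if (!is.finite(hb) || hb <= 0) return(r[1])  # all ratios identical
  dens <- function(x) {
    vapply(x, function(xi) sum(p * stats::dnorm((xi - r) / hb)), numeric(1))
  }
  # derivative of the kernel density: zero at the mode; root-finding on it
  # localizes the argmax to machine precision, unlike value comparison,
  # which is limited by the density's flatness at the peak
  ddens <- function(x) {
    u <- (x - r) / hb
    -sum(p * u * stats::dnorm(u))
  }
  grid <- seq(min(r) - 2 * hb, max(r) + 2 * hb, length.out = 512)
  i <- which.max(dens(grid))
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  if (ddens(lo) > 0 && ddens(hi) < 0) {
    stats::uniroot(ddens, c(lo, hi), tol = 1e-13)$root
  } else {
    stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
  }
}

#' Mode-based MR estimator
#'
#' The causal estimate is the mode of a normal-kernel smoothed density of
#' the Wald ratios, with bandwidth
#' `bandwidth_factor * 0.9 * min(sd, IQR/1.349) * k^(-1/5)`. With
#' `weighted = TRUE` each ratio carries its normalized inverse-variance
#' weight; otherwise weights are uniform. Consistent when the largest
#' homogeneous cluster of instruments is valid. SE by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param weighted use inverse-variance weights in the kernel density?
#' @param bandwidth_factor multiplier on the default bandwidth.
#' @return An `mr_estimate` with method `"mode_weighted"` or
#'   `"mode_simple"`.
#' @export
mr_mode <- function(h, weighted = TRUE, bandwidth_factor = 1,
                    n_boot = 1000, seed = 1) {
  re <- ratio_estimates(h)
  k <- nrow(re)
  if (k < 3) stop("mr_mode: needs at least 3 instruments")
  p <- if (weighted) re$w else rep(1, k)
  beta <- mode_point(re$r, p, bandwidth_factor)
  se <- boot_se(h, function(r, w) {
    mode_point(r, if (weighted) w else rep(1, length(r)), bandwidth_factor)
  }, n_boot, seed)
  new_mr_estimate(if (weighted) "mode_weighted" else "mode_simple", k, beta, se)
}

#' Steiger directionality test
#'
#' Compares the variance in exposure versus outcome explained by the
#' instruments. Per instrument, `r2 = t^2 / (t^2 + n - 2)` with
#' `t = beta / se`; the outcome (case-control) uses the effective sample
#' size `4 / (1/ncase + 1/ncontrol)`. Instrument r2 values are summed per
#' trait; the correct direction (exposure causes outcome) is inferred when
#' the exposure r2 exceeds the outcome r2, with a two-sided p-value from
#' the Fisher-z comparison of the two correlations at their sample sizes.
#'
#' @param h single-exposure `harmonized_set`.
#' @param n_exposure exposure GWAS sample size (defaults to the harmonized
#'   metadata when present).
#' @param n_case,n_control outcome case/control counts (default metadata).
#' @return list with `r2_exposure`, `r2_outcome`, `direction_correct`,
#'   `pval`.
#' @export
steiger_test <- function(h, n_exposure = NULL, n_case = NULL, n_control = NULL) {
  h <- single_exposure(h, "steiger_test")
  if (n_instruments(h) < 1) stop("steiger_test: no instruments")
  if (is.null(n_exposure)) n_exposure <- h$n_exposure[1]
  if (is.null(n_case)) n_case <- h$ncase
  if (is.null(n_control)) n_control <- h$ncontrol
  if (anyNA(c(n_exposure, n_case, n_control))) {
    stop("steiger_test: sample sizes missing; supply n_exposure/n_case/n_control")
  }
  n_out <- 4 / (1 / n_case + 1 / n_control)
  tx <- h$beta_exp[, 1] / h$se_exp[, 1]
  ty <- h$beta_out / h$se_out
  r2x <- sum(tx^2 / (tx^2 + n_exposure - 2))
  r2y <- sum(ty^2 / (ty^2 + n_out - 2))
  z <- (atanh(sqrt(min(r2x, 1 - 1e-12))) - atanh(sqrt(min(r2y, 1 - 1e-12)))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_out - 3))
  list(r2_exposure = r2x, r2_outcome = r2y,
       direction_correct = r2x > r2y,
       pval = 2 * stats::pnorm(-abs(z)))
}

#' Analytic power of an MR test for a binary outcome
#'
#' Two-sided power of the IVW z-test at level `alpha` to detect an odds
#' ratio `or_alt` per SD of exposure, given instruments explaining
#' `r2_exposure` of the exposure variance and a case-control outcome GWAS
#' of `n_case` + `n_control` samples. The noncentrality is
#' `|ln OR| * sqrt(N * r2 * phi * (1 - phi))` with case fraction `phi`;
#' power is `pnorm(lambda - z) + pnorm(-lambda - z)`, which equals `alpha`
#' at the null OR of 1.
#'
#' @param n_case,n_control outcome sample counts.
#' @param r2_exposure instrument variance explained, in (0, 1).
#' @param or_alt alternative odds ratio (> 0).
#' @param alpha two-sided test size (default 0.01).
#' @return power in (0, 1).
#' @export
mr_power <- function(n_case, n_control, r2_exposure, or_alt, alpha = 0.01) {
  if (r2_exposure <= 0 || r2_exposure >= 1) {
    stop("mr_power: r2_exposure must lie in (0, 1)")
  }
  if (or_alt <= 0) stop("mr_power: or_alt must be positive")
  if (alpha <= 0 || alpha >= 1) stop("mr_power: alpha must lie in (0, 1)")
  N <- n_case + n_control
  phi <- n_case / N
  lambda <- abs(log(or_alt)) * sqrt(N * r2_exposure * phi * (1 - phi))
  z <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(lambda - z) + stats::pnorm(-lambda - z)
}

#' Run the full single-exposure estimator battery as a tidy table
#'
#' One row per method (IVW under the requested model, MR-Egger, weighted
#' median, weighted mode), with Cochran's Q attached to the IVW row and the
#' Egger residual Q to the Egger row — the shape of a study's per-method
#' results tables.
#'
#' @param h single-exposure `harmonized_set` with k >= 3.
#' @param model IVW error model.
#' @param n_boot,seed bootstrap controls for median/mode SEs.
#' @return data.frame with columns `exposure`, `outcome`, `method`, `k`,
#'   `beta`, `se`, `or`, `ci_low`, `ci_high`, `pval`, `Q`, `Q_df`,
#'   `Q_pval`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_pval`.
#' @export
mr_all <- function(h, model = c("multiplicative_random", "fixed"),
                   n_boot = 1000, seed = 1) {
  model <- match.arg(model)
  ivw <- mr_ivw(h, model = model)
  egg <- mr_egger(h)
  wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
  md <- mr_mode(h, weighted = TRUE, n_boot = n_boot, seed = seed + 1)
  row <- function(est, het = NULL, eg = NULL) {
    data.frame(
      exposure = h$exposure_names[1], outcome = h$outcome_name,
      method = est$method, k = est$k, beta = est$beta, se = est$se,
      or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
      pval = est$pval,
      Q = if (is.null(het)) NA_real_ else het$Q,
      Q_df = if (is.null(het)) NA_integer_ else het$df,
      Q_pval = if (is.null(het)) NA_real_ else het$pval,
      egger_intercept = if (is.null(eg)) NA_real_ else eg$value,
      egger_intercept_se = if (is.null(eg)) NA_real_ else eg$se,
      egger_intercept_pval = if (is.null(eg)) NA_real_ else eg$pval,
      stringsAsFactors = FALSE
    )
  }
  rbind(row(ivw$estimate, ivw$heterogeneity),
        row(egg$slope, egg$heterogeneity, egg$intercept),
        row(wm), row(md))
}
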