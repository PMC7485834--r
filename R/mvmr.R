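#' Assemble a multivariable MR instrument set
#'
#' Candidate instruments are the union over exposures of SNPs passing
#' genome-wide significance and LD clumping in that exposure, restricted to
#' SNPs present in every exposure table and the outcome. The union is then
#' re-clumped jointly, ranking SNPs by their minimum p-value across
#' exposures, and harmonized to a common effect allele.
#'
#' @param exposures list of at least two `gwas_table`s.
#' @param outcome a `gwas_table`.
#' @param ld an [ld_matrix()] over the candidate SNPs, or `NULL` for
#'   unlinked variants.
#' @param p_threshold per-exposure significance filter (default `5e-8`).
#' @param r2_threshold clumping threshold (default 0.001).
#' @param palindrome_eaf_window passed to [harmonize()].
#' @return An `mvmr_set`: list with `snp_ids`, exposure beta matrix `B`
#'   (m x K), SE matrix `SE_B`, outcome `beta_out`/`se_out`, and
#'   `exposure_names`.
#' @export
build_mvmr_set <- function(exposures, outcome, ld = NULL, p_threshold = 5e-8,
                           r2_threshold = 0.001, palindrome_eaf_window = 0.08) {
  if (length(exposures) < 2) stop("build_mvmr_set: needs at least 2 exposures")
  K <- length(exposures)

  in_all <- Reduce(intersect, c(lapply(exposures, function(t) t$snp_id),
                                list(outcome$snp_id)))
  if (length(in_all) == 0) stop("build_mvmr_set: no shared SNP universe")

  cand <- character()
  for (t in exposures) {
    sig <- select_significant(t, p_threshold)
    cl <- ld_clump(sig, ld, r2_threshold)$table
    cand <- union(cand, cl$snp_id)
  }
  cand <- intersect(cand, in_all)
  if (length(cand) == 0) stop("build_mvmr_set: no candidate instruments")

  # joint re-clump: rank the union by best p across exposures
  minp <- rep(Inf, length(cand))
  for (t in exposures) {
    p <- t$pval[match(cand, t$snp_id)]
    minp <- pmin(minp, p, na.rm = TRUE)
  }
  joint <- gwas_table(
    data.frame(snp_id = cand, effect_allele = "A", other_allele = "G",
               beta = 1, se = 1, pval = minp, stringsAsFactors = FALSE),
    trait_name = "joint", validate = FALSE)
  keep <- ld_clump(joint, ld, r2_threshold)$table$snp_id

  exp_sub <- lapply(exposures, function(t) subset_gwas(t, t$snp_id %in% keep))
  out_sub <- subset_gwas(outcome, outcome$snp_id %in% keep)
  h <- harmonize(exp_sub, out_sub, palindrome_eaf_window)

  m <- n_instruments(h)
  if (m <= K) {
    stop("build_mvmr_set: only ", m, " instruments for ", K,
         " exposures after filtering")
  }
  structure(list(
    snp_ids = h$snp$snp_id,
    B = h$beta_exp, SE_B = h$se_exp,
    beta_out = h$beta_out, se_out = h$se_out,
    exposure_names = h$exposure_names
  ), class = "mvmr_set")
}

# build an mvmr_set directly from a multi-exposure harmonized_set
as_mvmr_set <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  structure(list(snp_ids = h$snp$snp_id, B = h$beta_exp, SE_B = h$se_exp,
                 beta_out = h$beta_out, se_out = h$se_out,
                 exposure_names = h$exposure_names),
            class = "mvmr_set")
}

subset_mvmr <- function(s, idx) {
  s$snp_ids <- s$snp_ids[idx]
  s$B <- s$B[idx, , drop = FALSE]
  s$SE_B <- s$SE_B[idx, , drop = FALSE]
  s$beta_out <- s$beta_out[idx]
  s$se_out <- s$se_out[idx]
  s
}

#' Multivariable MR fit
#'
#' Weighted least squares of the outcome betas on the exposure beta matrix
#' without intercept, weights `1 / se_Yj^2`:
#' `beta = (B' W B)^(-1) B' W y`. The global heterogeneity statistic is
#' `Q_A = sum_j w_j (y_j - B_j beta)^2` on `m - K` df; under the
#' multiplicative random-effects model the coefficient covariance is
#' inflated by `max(1, Q_A / (m - K))`.
#'
#' @param s an `mvmr_set` with m > K and full-column-rank `B`.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mvmr_result`: `estimates` data.frame (one row per exposure:
#'   `exposure`, `beta`, `se`, `or`, `ci_low`, `ci_high`, `pval`), plus
#'   `QA`, `QA_df`, `QA_pval`, `k` and the fitted `model`.
#' @export
mvmr_fit <- function(s, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  stopifnot(inherits(s, "mvmr_set"))
  m <- length(s$beta_out)
  K <- ncol(s$B)
  if (m <= K) stop("mvmr_fit: needs more instruments than exposures")
  w <- 1 / s$se_out^2
  Xw <- s$B * sqrt(w)
  qrX <- qr(Xw)
  if (qrX$rank < K) {
    bad <- s$exposure_names[qrX$pivot[(qrX$rank + 1):K]]
    stop("mvmr_fit: collinear exposure columns: ",
         paste(bad, collapse = ", "))
  }
  A <- crossprod(Xw)
  b <- crossprod(s$B, w * s$beta_out)
  beta <- drop(solve(A, b))
  resid <- s$beta_out - drop(s$B %*% beta)
  QA <- sum(w * resid^2)
  df <- m - K
  disp2 <- if (model == "multiplicative_random") max(1, QA / df) else 1
  covb <- solve(A) * disp2
  se <- sqrt(diag(covb))
  est <- data.frame(
    exposure = s$exposure_names,
    k = m,
    beta = beta, se = se,
    or = exp(beta),
    ci_low = exp(beta - Z95 * se),
    ci_high = exp(beta + Z95 * se),
    pval = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  rownames(est) <- NULL
  structure(list(estimates = est, QA = QA, QA_df = df,
                 QA_pval = stats::pchisq(QA, df, lower.tail = FALSE),
                 k = m, model = model, resid = resid, w = w),
            class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("<mvmr_result> %d exposures, %d instruments (%s)\n",
              nrow(x$estimates), x$k, x$model))
  print(x$estimates, digits = 4)
  cat(sprintf("Q_A = %.3f on %d df (p = %.3g)\n", x$QA, x$QA_df, x$QA_pval))
  invisible(x)
}

#' Conditional instrument strength per exposure
#'
#' Sanderson-Windmeijer-style conditional F statistics: for each exposure,
#' its beta column is regressed (weights `1 / se_Yj^2`, no intercept) on
#' the remaining exposures' columns; the residual association left over is
#' summarised as `Q_strength = sum_j resid_jk^2 / se_Xjk^2` and
#' `F = Q_strength / (m - K + 1)`. Exposures with conditional F below 10
#' are flagged weak (reported, never auto-enforced).
#'
#' @param s an `mvmr_set`.
#' @return data.frame with `exposure`, `cond_F`, `weak` (logical flag).
#' @export
conditional_strength <- function(s) {
  stopifnot(inherits(s, "mvmr_set"))
  m <- length(s$beta_out)
  K <- ncol(s$B)
  if (m <= K) stop("conditional_strength: needs more instruments than exposures")
  w <- 1 / s$se_out^2
  Fk <- numeric(K)
  for (k in seq_len(K)) {
    yk <- s$B[, k]
    Xo <- s$B[, -k, drop = FALSE]
    if (ncol(Xo) == 0) {
      resid <- yk  # K = 1: unconditional strength
    } else {
      Xw <- Xo * sqrt(w)
      delta <- qr.coef(qr(Xw), yk * sqrt(w))
      delta[is.na(delta)] <- 0
      resid <- yk - drop(Xo %*% delta)
    }
    Qs <- sum(resid^2 / s$SE_B[, k]^2)
    Fk[k] <- Qs / (m - K + 1)
  }
  data.frame(exposure = s$exposure_names, cond_F = Fk, weak = Fk < 10,
             stringsAsFactors = FALSE)
}

#' Prune instruments driving multivariable heterogeneity
#'
#' Iteratively removes the instrument with the largest contribution
#' `w_j (y_j - B_j beta)^2` to the global `Q_A`, refitting after each
#' removal, until the Q_A p-value (chi-square on m - K df) reaches
#' `q_alpha` or the set would fall to `m = K + 2` instruments.
#'
#' @param s an `mvmr_set` with m > K + 1.
#' @param q_alpha stopping threshold (default 0.05).
#' @return `list(set = mvmr_set, log = prune_log)`.
#' @export
mvmr_heterogeneity_prune <- function(s, q_alpha = 0.05) {
  stopifnot(inherits(s, "mvmr_set"))
  K <- ncol(s$B)
  if (length(s$beta_out) <= K + 1) {
    stop("mvmr_heterogeneity_prune: needs m > K + 1 instruments")
  }
  log_id <- character(); log_stat <- numeric(); rounds <- 0L
  repeat {
    fit <- mvmr_fit(s, model = "fixed")
    if (fit$QA_pval >= q_alpha || length(s$beta_out) <= K + 2) break
    contrib <- fit$w * fit$resid^2
    drop <- which.max(contrib)
    log_id <- c(log_id, s$snp_ids[drop])
    log_stat <- c(log_stat, contrib[drop])
    s <- subset_mvmr(s, -drop)
    rounds <- rounds + 1L
  }
  list(set = s,
       log = new_prune_log(log_id, rep("qa_contribution", length(log_id)),
                           log_stat, rounds))
}
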