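#' Default exposure effect-correlation matrix for the lipid study design
#'
#' Correlations among per-SNP true effects on HDL, LDL, triglycerides,
#' BMI and age at menarche, set to magnitudes in line with reported
#' genetic correlations among these traits (HDL and TGs inversely
#' correlated; BMI adversely related to HDL; menarche timing linked to
#' BMI).
#'
#' @return 5x5 positive-definite correlation matrix.
#' @export
default_effect_corr <- function() {
  nm <- c("hdl", "ldl", "tg", "bmi", "menarche")
  R <- diag(5)
  dimnames(R) <- list(nm, nm)
  R["hdl", "ldl"] <- R["ldl", "hdl"] <- 0.10
  R["hdl", "tg"] <- R["tg", "hdl"] <- -0.45
  R["hdl", "bmi"] <- R["bmi", "hdl"] <- -0.25
  R["ldl", "tg"] <- R["tg", "ldl"] <- 0.30
  R["ldl", "bmi"] <- R["bmi", "ldl"] <- 0.05
  R["tg", "bmi"] <- R["bmi", "tg"] <- 0.25
  R["bmi", "menarche"] <- R["menarche", "bmi"] <- -0.30
  R
}

#' Configuration for a synthetic two-sample GWAS study
#'
#' Defines the generative model for summary-level simulation: `m_snps`
#' unlinked variants with frequencies in `maf_range`; a shared
#' spike-and-slab architecture in which a fraction `prop_causal` of SNPs
#' affect the exposures with multivariate-normal effects following
#' `effect_corr`, scaled so each exposure's realized variance explained is
#' `h2_x`; a binary outcome whose per-SNP log odds ratio is
#' `sum_k theta_k * beta_k` plus an optional direct (pleiotropic) effect;
#' and two-sample estimation noise at the stated sample sizes.
#'
#' The defaults emulate the design of a lipids-to-breast-cancer MR study:
#' five exposures (HDL, LDL, TGs, BMI, age at menarche) measured in large
#' biobank GWAS (n = 200,000 each) against a case-control outcome of
#' 120,000 cases and 100,000 controls, with direct effects
#' `theta = (0.06, 0.04, -0.02, -0.10, -0.04)` on the log-OR scale per SD
#' of exposure.
#'
#' @param m_snps number of variants (default 2000).
#' @param maf_range minor-allele frequency range (default 0.05-0.5).
#' @param exposure_names character vector; its length sets K.
#' @param prop_causal fraction of SNPs in the shared causal pool.
#' @param h2_x per-exposure variance explained by the simulated SNPs
#'   (scalar or length K).
#' @param effect_corr K x K positive-semidefinite correlation matrix of
#'   true effects.
#' @param theta length-K direct causal effects on the outcome (log OR per
#'   SD exposure).
#' @param pleiotropy list with `prop_invalid` (fraction of causal SNPs
#'   given a direct outcome effect), `mean_direct_effect`,
#'   `sd_direct_effect`, and `inside_violated` (should direct effects
#'   scale with instrument strength, violating the InSIDE assumption?).
#' @param n_exposure exposure GWAS sample sizes (scalar or length K).
#' @param n_case,n_control outcome case/control counts.
#' @param ld_block_size,ld_r2 optional: emit a block-diagonal LD matrix
#'   with this block size and constant within-block r-squared.
#' @param seed RNG seed; every draw derives from it.
#' @return A validated `simulation_config`.
#' @export
simulation_config <- function(m_snps = 2000,
                              maf_range = c(0.05, 0.5),
                              exposure_names = c("hdl", "ldl", "tg", "bmi", "menarche"),
                              prop_causal = 0.05,
                              h2_x = 0.1,
                              effect_corr = NULL,
                              theta = c(0.06, 0.04, -0.02, -0.10, -0.04),
                              pleiotropy = list(prop_invalid = 0,
                                                mean_direct_effect = 0,
                                                sd_direct_effect = 0,
                                                inside_violated = FALSE),
                              n_exposure = 200000,
                              n_case = 120000, n_control = 100000,
                              ld_block_size = NULL, ld_r2 = NULL,
                              seed = 1) {
  K <- length(exposure_names)
  if (is.null(effect_corr)) {
    effect_corr <- if (K == 5) default_effect_corr() else diag(K)
  }
  effect_corr <- as.matrix(effect_corr)
  if (nrow(effect_corr) != K || ncol(effect_corr) != K) {
    stop("simulation_config: effect_corr must be ", K, "x", K)
  }
  if (max(abs(effect_corr - t(effect_corr))) > 1e-10 ||
      min(eigen(effect_corr, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    stop("simulation_config: effect_corr must be symmetric positive semidefinite")
  }
  h2_x <- rep_len(h2_x, K)
  n_exposure <- rep_len(n_exposure, K)
  if (length(theta) != K) stop("simulation_config: theta must have length K")
  if (any(h2_x < 0 | h2_x >= 1)) stop("simulation_config: h2_x outside [0, 1)")
  if (prop_causal < 0 || prop_causal > 1) {
    stop("simulation_config: prop_causal outside [0, 1]")
  }
  pl <- utils::modifyList(list(prop_invalid = 0, mean_direct_effect = 0,
                               sd_direct_effect = 0, inside_violated = FALSE),
                          pleiotropy)
  if (pl$prop_invalid < 0 || pl$prop_invalid > 1) {
    stop("simulation_config: prop_invalid outside [0, 1]")
  }
  structure(list(m_snps = m_snps, maf_range = maf_range,
                 exposure_names = exposure_names, prop_causal = prop_causal,
                 h2_x = h2_x, effect_corr = effect_corr, theta = theta,
                 pleiotropy = pl, n_exposure = n_exposure,
                 n_case = n_case, n_control = n_control,
                 ld_block_size = ld_block_size, ld_r2 = ld_r2, seed = seed),
            class = "simulation_config")
}

#' Read a simulation config from a YAML file
#' @param path YAML file whose keys mirror [simulation_config()] arguments.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$effect_corr)) {
    args$effect_corr <- matrix(unlist(args$effect_corr),
                               nrow = length(args$effect_corr), byrow = TRUE)
  }
  do.call(simulation_config, args)
}

#' Draw the true generative effects of a synthetic study
#'
#' Causal status is a single shared Bernoulli pool across exposures; for
#' causal SNPs the exposure effects are multivariate normal with the
#' configured correlation, then rescaled per exposure so the realized
#' variance explained (`sum_j 2 p_j (1-p_j) beta_jk^2`) equals `h2_x`
#' exactly. A fraction `prop_invalid` of causal SNPs receives a direct
#' (pleiotropic) outcome effect; with `inside_violated` the direct effect
#' scales with instrument strength.
#'
#' Bookkeeping includes `theta_marginal`, the effect a single-trait MR of
#' each exposure consistently targets: the maf-weighted projection of the
#' total outcome effect onto that exposure's instrument effects,
#' `theta_k + sum_{l != k} theta_l * <beta_l, beta_k> / <beta_k, beta_k>`.
#'
#' @param config a [simulation_config()].
#' @return A `true_model`: `maf`, `beta` (m x K), `direct` (length m),
#'   `valid`, `causal`, `r2_explained`, `theta`, `theta_marginal`,
#'   `snp_id`, allele columns and positions.
#' @export
simulate_effects <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    m <- config$m_snps
    K <- length(config$exposure_names)
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    het <- 2 * maf * (1 - maf)

    causal <- stats::runif(m) < config$prop_causal
    beta <- matrix(0, m, K, dimnames = list(NULL, config$exposure_names))
    if (any(causal) && any(config$h2_x > 0)) {
      slab <- MASS::mvrnorm(sum(causal), mu = rep(0, K),
                            Sigma = config$effect_corr)
      slab <- matrix(slab, ncol = K)
      beta[causal, ] <- slab
      for (k in seq_len(K)) {
        v <- sum(het * beta[, k]^2)
        beta[, k] <- if (v > 0) beta[, k] * sqrt(config$h2_x[k] / v) else 0
      }
    }

    pl <- config$pleiotropy
    direct <- rep(0, m)
    inv <- causal & stats::runif(m) < pl$prop_invalid
    if (any(inv)) {
      if (pl$inside_violated) {
        strength <- rowSums(abs(beta[inv, , drop = FALSE]))
        strength <- strength / mean(strength)
        direct[inv] <- pl$mean_direct_effect * strength +
          stats::rnorm(sum(inv), 0, pl$sd_direct_effect)
      } else {
        direct[inv] <- stats::rnorm(sum(inv), pl$mean_direct_effect,
                                    pl$sd_direct_effect)
      }
    }

    # marginal (total) per-exposure effect targeted by single-trait MR
    gram <- t(beta) %*% (beta * het)
    theta_marginal <- vapply(seq_len(K), function(k) {
      if (gram[k, k] > 0) sum(gram[k, ] * config$theta) / gram[k, k] else NA_real_
    }, numeric(1))

    # non-palindromic allele pairs so harmonization keeps every SNP
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pi <- sample.int(nrow(pairs), m, replace = TRUE)

    structure(list(
      snp_id = sprintf("rs%06d", seq_len(m)),
      chrom = as.character(rep_len(1:22, m)),
      pos = 100000 + 50000 * (seq_len(m) - 1),
      effect_allele = pairs[pi, 1], other_allele = pairs[pi, 2],
      maf = maf, beta = beta, direct = direct,
      causal = causal, valid = direct == 0,
      r2_explained = colSums(het * beta^2),
      theta = config$theta, theta_marginal = theta_marginal
    ), class = "true_model")
  })
}

#' Simulate a two-sample GWAS study with known truth
#'
#' Draws summary statistics at the summary level: exposure beta-hats are
#' normal around the true effects with `se = 1 / sqrt(2 p (1-p) n)`
#' (SD-unit traits); the outcome's true per-SNP log OR is
#' `sum_k theta_k beta_jk + direct_j`, observed with
#' `se = 1 / sqrt(2 p (1-p) N phi (1-phi))` for case fraction `phi`
#' (logistic-GWAS approximation). Exposure and outcome noise are
#' independent, as in a two-sample design. All draws derive from
#' `config$seed`, so a given configuration reproduces byte-identical
#' tables.
#'
#' @param config a [simulation_config()].
#' @param noise_seed optional separate seed for the estimation-noise
#'   stream; defaults to a fixed offset of `config$seed`. Varying it while
#'   keeping the config fixed yields replicate studies of one true model.
#' @return A `synthetic_study`: `exposures` (list of `gwas_table`s),
#'   `outcome` (`gwas_table`), `truth` (the `true_model`), and `ld`
#'   (an [ld_matrix()] when `ld_block_size` is set, else `NULL`).
#' @export
simulate_gwas_pair <- function(config, noise_seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  tm <- simulate_effects(config)
  if (is.null(noise_seed)) noise_seed <- config$seed + 1000003L
  with_seed(noise_seed, {
    m <- config$m_snps
    K <- length(config$exposure_names)
    het <- 2 * tm$maf * (1 - tm$maf)

    exposures <- vector("list", K)
    for (k in seq_len(K)) {
      se_x <- 1 / sqrt(het * config$n_exposure[k])
      bhat <- stats::rnorm(m, tm$beta[, k], se_x)
      exposures[[k]] <- gwas_table(data.frame(
        snp_id = tm$snp_id, chrom = tm$chrom, pos = tm$pos,
        effect_allele = tm$effect_allele, other_allele = tm$other_allele,
        eaf = tm$maf, beta = bhat, se = se_x,
        pval = 2 * stats::pnorm(-abs(bhat / se_x)),
        n = config$n_exposure[k], stringsAsFactors = FALSE
      ), trait_name = config$exposure_names[k], trait_type = "quantitative",
      validate = FALSE)
    }

    N <- config$n_case + config$n_control
    phi <- config$n_case / N
    true_y <- drop(tm$beta %*% config$theta) + tm$direct
    se_y <- 1 / sqrt(het * N * phi * (1 - phi))
    bhat_y <- stats::rnorm(m, true_y, se_y)
    outcome <- gwas_table(data.frame(
      snp_id = tm$snp_id, chrom = tm$chrom, pos = tm$pos,
      effect_allele = tm$effect_allele, other_allele = tm$other_allele,
      eaf = tm$maf, beta = bhat_y, se = se_y,
      pval = 2 * stats::pnorm(-abs(bhat_y / se_y)),
      n = N, ncase = config$n_case, ncontrol = config$n_control,
      stringsAsFactors = FALSE
    ), trait_name = "outcome", trait_type = "binary", validate = FALSE)

    ld <- NULL
    if (!is.null(config$ld_block_size) && !is.null(config$ld_r2)) {
      bs <- config$ld_block_size
      blocks <- split(seq_len(m), (seq_len(m) - 1) %/% bs)
      r2 <- diag(m)
      for (b in blocks) r2[b, b] <- config$ld_r2
      diag(r2) <- 1
      ld <- ld_matrix(tm$snp_id, r2)
    }

    structure(list(exposures = exposures, outcome = outcome,
                   truth = tm, ld = ld, config = config),
              class = "synthetic_study")
  })
}

#' Simulate z-scores and an LD-score panel for LDSC testing
#'
#' LD scores are drawn from a right-skewed positive distribution (1 plus a
#' gamma variate, with block-level location shifts when `n_blocks_ld > 1`).
#' Per-SNP standardized joint effects are bivariate normal with variance
#' `h2 l_j / M` and cross-trait correlation `r_g`; z-scores add unit
#' sampling noise, so `E[z^2] = 1 + n h2 l / M` and
#' `E[z1 z2] = sqrt(n1 n2) rho_g l / M` hold exactly under the generative
#' model.
#'
#' @param m_snps panel size.
#' @param M SNP count the panel represents (default `m_snps`).
#' @param h2_1,h2_2 heritabilities of the two traits.
#' @param r_g true genetic correlation, |r_g| <= 1.
#' @param n1,n2 GWAS sample sizes.
#' @param n_blocks_ld blocks of locally similar LD scores (default 50).
#' @param seed RNG seed.
#' @return `list(z1, z2, panel)` with `panel` an [ld_score_panel()].
#' @export
simulate_ldsc_panel <- function(m_snps, M = m_snps, h2_1, h2_2, r_g,
                                n1, n2, n_blocks_ld = 50, seed = 1) {
  if (abs(r_g) > 1) stop("simulate_ldsc_panel: |r_g| must be <= 1")
  if (h2_1 < 0 || h2_1 >= 1 || h2_2 < 0 || h2_2 >= 1) {
    stop("simulate_ldsc_panel: h2 outside [0, 1)")
  }
  with_seed(seed, {
    block <- ((seq_len(m_snps) - 1L) * n_blocks_ld) %/% m_snps + 1L
    loc <- stats::rgamma(n_blocks_ld, shape = 2, scale = 4)[block]
    ell <- 1 + stats::rgamma(m_snps, shape = 1.5, scale = loc / 1.5)
    sd1 <- sqrt(h2_1 * ell / M)
    sd2 <- sqrt(h2_2 * ell / M)
    u1 <- stats::rnorm(m_snps, 0, sd1)
    u2 <- r_g * sd2 / pmax(sd1, .Machine$double.xmin) * u1 +
      stats::rnorm(m_snps, 0, sd2 * sqrt(max(0, 1 - r_g^2)))
    if (h2_1 == 0) u2 <- stats::rnorm(m_snps, 0, sd2)  # guard degenerate scaling
    z1 <- sqrt(n1) * u1 + stats::rnorm(m_snps)
    z2 <- sqrt(n2) * u2 + stats::rnorm(m_snps)
    list(z1 = z1, z2 = z2,
         panel = ld_score_panel(sprintf("rs%06d", seq_len(m_snps)), ell, M))
  })
}
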