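# reverse-complement single-character alleles, vectorized
rev_comp <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) ea == rev_comp(oa)

# Align one table's alleles to a reference orientation.
# Returns per-SNP status: "kept", "flipped", "dropped_palindromic",
# "dropped_mismatch", and whether effect direction must be flipped.
align_alleles <- function(ref_ea, ref_oa, ref_eaf, ea, oa, eaf, window) {
  n <- length(ref_ea)
  status <- rep("dropped_mismatch", n)
  flip <- rep(FALSE, n)

  same <- ea == ref_ea & oa == ref_oa
  swap <- ea == ref_oa & oa == ref_ea
  rc_ea <- rev_comp(ea)
  rc_oa <- rev_comp(oa)
  same_rc <- rc_ea == ref_ea & rc_oa == ref_oa
  swap_rc <- rc_ea == ref_oa & rc_oa == ref_ea

  pal <- is_palindromic(ref_ea, ref_oa)

  # non-palindromic: orientation is determined by the allele pair itself
  np <- !pal
  status[np & same] <- "kept"
  status[np & !same & swap] <- "flipped"
  flip[np & !same & swap] <- TRUE
  status[np & !same & !swap & same_rc] <- "kept"
  left <- np & !same & !swap & !same_rc & swap_rc
  status[left] <- "flipped"
  flip[left] <- TRUE

  # palindromic (A/T or C/G): strand is unresolvable from alleles alone;
  # infer from allele frequency when both are informative, else drop
  pm <- pal & (same | swap | same_rc | swap_rc)
  informative <- !is.na(ref_eaf) & !is.na(eaf) &
    abs(ref_eaf - 0.5) > window & abs(eaf - 0.5) > window
  status[pm & !informative] <- "dropped_palindromic"
  ok <- pm & informative
  fl <- ok & ((eaf < 0.5) != (ref_eaf < 0.5))
  status[ok & !fl] <- "kept"
  status[fl] <- "flipped"
  flip[fl] <- TRUE

  list(status = status, flip = flip)
}

#' Harmonize exposure and outcome tables onto a shared effect allele
#'
#' Aligns every table to the orientation of the first exposure, SNP-by-SNP
#' over the rsIDs shared by all tables, mirroring the default behaviour of
#' standard two-sample MR harmonization: identical allele pairs are kept;
#' swapped effect/other alleles flip the effect sign (and complement the
#' frequency); reverse-complement pairs are strand-flipped first;
#' palindromic SNPs (A/T, C/G) are resolved through allele frequency when
#' both frequencies lie outside `0.5 +/- palindrome_eaf_window`, and dropped
#' otherwise; irreconcilable pairs are dropped as mismatches.
#'
#' The per-SNP `action` recorded is the outcome's alignment
#' (`kept`/`flipped`) unless any table failed, in which case it is
#' `dropped_mismatch` or `dropped_palindromic`. Actions partition the
#' shared SNPs.
#'
#' @param exposures a `gwas_table` or list of them (the first defines the
#'   reference orientation).
#' @param outcome a `gwas_table`.
#' @param palindrome_eaf_window half-width of the ambiguous frequency zone
#'   around 0.5 (default 0.08).
#' @return A `harmonized_set`: list with `exposure_names`, `outcome_name`,
#'   `snp` (data.frame of retained SNPs in reference orientation),
#'   `beta_exp`/`se_exp`/`eaf_exp` (matrices, SNP x exposure),
#'   `beta_out`/`se_out`, `actions` (all shared SNPs with their action),
#'   and sample-size metadata (`n_exposure`, `ncase`, `ncontrol`).
#' @export
harmonize <- function(exposures, outcome, palindrome_eaf_window = 0.08) {
  if (inherits(exposures, "gwas_table")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "gwas_table"))
  for (e in exposures) {
    if (!inherits(e, "gwas_table") || nrow(e) == 0) {
      stop("harmonize: every exposure must be a nonempty gwas_table")
    }
  }

  shared <- Reduce(intersect, c(lapply(exposures, function(t) t$snp_id),
                                list(outcome$snp_id)))
  if (length(shared) == 0) stop("harmonize: no SNPs shared by all tables")
  shared <- sort(shared)

  ref <- exposures[[1]]
  ri <- match(shared, ref$snp_id)
  ref_ea <- ref$effect_allele[ri]
  ref_oa <- ref$other_allele[ri]
  ref_eaf <- ref$eaf[ri]

  K <- length(exposures)
  m <- length(shared)
  beta_exp <- se_exp <- eaf_exp <- matrix(NA_real_, m, K)
  beta_exp[, 1] <- ref$beta[ri]
  se_exp[, 1] <- ref$se[ri]
  eaf_exp[, 1] <- ref_eaf
  pval_exp <- matrix(NA_real_, m, K)
  pval_exp[, 1] <- ref$pval[ri]

  worst <- rep("kept", m)  # aggregated failure across exposures 2..K
  bump <- function(worst, status) {
    # mismatch dominates palindromic dominates success
    w <- worst
    w[status == "dropped_palindromic" & w != "dropped_mismatch"] <- "dropped_palindromic"
    w[status == "dropped_mismatch"] <- "dropped_mismatch"
    w
  }

  if (K > 1) {
    for (k in 2:K) {
      tk <- exposures[[k]]
      ti <- match(shared, tk$snp_id)
      al <- align_alleles(ref_ea, ref_oa, ref_eaf,
                          tk$effect_allele[ti], tk$other_allele[ti],
                          tk$eaf[ti], palindrome_eaf_window)
      b <- tk$beta[ti]
      f <- tk$eaf[ti]
      b[al$flip] <- -b[al$flip]
      f[al$flip] <- 1 - f[al$flip]
      beta_exp[, k] <- b
      se_exp[, k] <- tk$se[ti]
      eaf_exp[, k] <- f
      pval_exp[, k] <- tk$pval[ti]
      worst <- bump(worst, al$status)
    }
  }

  oi <- match(shared, outcome$snp_id)
  al <- align_alleles(ref_ea, ref_oa, ref_eaf,
                      outcome$effect_allele[oi], outcome$other_allele[oi],
                      outcome$eaf[oi], palindrome_eaf_window)
  beta_out <- outcome$beta[oi]
  eaf_out <- outcome$eaf[oi]
  beta_out[al$flip] <- -beta_out[al$flip]
  eaf_out[al$flip] <- 1 - eaf_out[al$flip]

  action <- al$status
  action[worst == "dropped_palindromic" & action != "dropped_mismatch"] <-
    "dropped_palindromic"
  action[worst == "dropped_mismatch"] <- "dropped_mismatch"

  keep <- action %in% c("kept", "flipped")
  exposure_names <- vapply(exposures, trait_name, character(1))

  h <- structure(list(
    exposure_names = exposure_names,
    outcome_name = trait_name(outcome),
    snp = data.frame(
      snp_id = shared[keep],
      chrom = ref$chrom[ri][keep],
      pos = ref$pos[ri][keep],
      effect_allele = ref_ea[keep],
      other_allele = ref_oa[keep],
      action = action[keep],
      stringsAsFactors = FALSE
    ),
    beta_exp = beta_exp[keep, , drop = FALSE],
    se_exp = se_exp[keep, , drop = FALSE],
    eaf_exp = eaf_exp[keep, , drop = FALSE],
    pval_exp = pval_exp[keep, , drop = FALSE],
    beta_out = beta_out[keep],
    se_out = outcome$se[oi][keep],
    eaf_out = eaf_out[keep],
    pval_out = outcome$pval[oi][keep],
    actions = data.frame(snp_id = shared, action = action,
                         stringsAsFactors = FALSE),
    n_exposure = vapply(exposures, function(t) {
      stats::median(t$n, na.rm = TRUE)
    }, numeric(1)),
    ncase = stats::median(outcome$ncase, na.rm = TRUE),
    ncontrol = stats::median(outcome$ncontrol, na.rm = TRUE)
  ), class = "harmonized_set")
  h
}

#' @export
print.harmonized_set <- function(x, ...) {
  tab <- table(factor(x$actions$action,
                      levels = c("kept", "flipped", "dropped_palindromic",
                                 "dropped_mismatch")))
  cat(sprintf("<harmonized_set> %s ~ %s: %d retained SNPs\n",
              paste(x$exposure_names, collapse = "+"), x$outcome_name,
              nrow(x$snp)))
  print(tab)
  invisible(x)
}

#' Number of retained instruments in a harmonized set
#' @param h a `harmonized_set`
#' @return integer count
#' @export
n_instruments <- function(h) nrow(h$snp)

# row-subset a harmonized set (retained SNPs only)
subset_harmonized <- function(h, idx) {
  h$snp <- h$snp[idx, , drop = FALSE]
  rownames(h$snp) <- NULL
  h$beta_exp <- h$beta_exp[idx, , drop = FALSE]
  h$se_exp <- h$se_exp[idx, , drop = FALSE]
  h$eaf_exp <- h$eaf_exp[idx, , drop = FALSE]
  h$pval_exp <- h$pval_exp[idx, , drop = FALSE]
  h$beta_out <- h$beta_out[idx]
  h$se_out <- h$se_out[idx]
  h$eaf_out <- h$eaf_out[idx]
  h$pval_out <- h$pval_out[idx]
  h
}

# assert single-exposure harmonized set and return it
single_exposure <- function(h, caller) {
  if (!inherits(h, "harmonized_set")) {
    stop(caller, ": input must be a harmonized_set")
  }
  if (length(h$exposure_names) != 1) {
    stop(caller, ": requires a single-exposure harmonized_set")
  }
  h
}
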