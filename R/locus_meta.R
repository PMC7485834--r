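#' Define a locus window
#'
#' @param locus_name gene or multi-gene locus label.
#' @param chrom chromosome (character).
#' @param start,end 1-based inclusive gene span.
#' @param flank flanking distance in base pairs added on both sides
#'   (default 100 kb).
#' @return A `locus_definition`.
#' @export
locus_definition <- function(locus_name, chrom, start, end, flank = 100000) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (start > end) stop("locus_definition: start > end")
  if (flank < 0) stop("locus_definition: negative flank")
  structure(list(locus_name = locus_name, chrom = as.character(chrom),
                 start = start, end = end, flank = flank),
            class = "locus_definition")
}

#' Read a locus table (TSV with columns locus_name, chrom, start, end)
#'
#' @param path file path; extra columns (e.g. `trait`) are carried through.
#' @param flank flank applied to every locus.
#' @return list of [locus_definition()]s; names are the locus names, and a
#'   `table` attribute keeps the raw data.frame.
#' @export
read_locus_table <- function(path, flank = 100000) {
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  need <- c("locus_name", "chrom", "start", "end")
  if (!all(need %in% names(raw))) {
    stop("read_locus_table: requires columns ", paste(need, collapse = ", "))
  }
  out <- lapply(seq_len(nrow(raw)), function(i) {
    locus_definition(raw$locus_name[i], raw$chrom[i], raw$start[i],
                     raw$end[i], flank)
  })
  names(out) <- raw$locus_name
  attr(out, "table") <- raw
  out
}

#' Locus-restricted instrument set from conditional association statistics
#'
#' Subsets a table of conditionally independent variants (trusted as
#' mutually independent: no clumping) to the window
#' `[start - flank, end + flank]` on the locus chromosome, inclusive at
#' both boundaries, and harmonizes it to the outcome. Loci retaining fewer
#' than 2 instruments are excluded rather than errored, mirroring the
#' treatment of single-signal genes.
#'
#' @param conditional_table a `gwas_table` of conditional betas/SEs with
#'   `chrom` and `pos` populated.
#' @param outcome a `gwas_table`.
#' @param locus a [locus_definition()].
#' @param palindrome_eaf_window passed to [harmonize()].
#' @return A single-exposure `harmonized_set` (with `locus_name`
#'   attribute), or a `locus_excluded` marker listing the reason.
#' @export
locus_instruments <- function(conditional_table, outcome, locus,
                              palindrome_eaf_window = 0.08) {
  stopifnot(inherits(conditional_table, "gwas_table"),
            inherits(locus, "locus_definition"))
  if (anyNA(conditional_table$chrom) || anyNA(conditional_table$pos)) {
    stop("locus_instruments: conditional table lacks chrom/pos")
  }
  lo <- locus$start - locus$flank
  hi <- locus$end + locus$flank
  inside <- conditional_table$chrom == locus$chrom &
    conditional_table$pos >= lo & conditional_table$pos <= hi
  excluded <- function(reason) {
    structure(list(locus_name = locus$locus_name, reason = reason),
              class = "locus_excluded")
  }
  if (sum(inside) < 2) return(excluded("fewer than 2 variants in window"))
  sub <- subset_gwas(conditional_table, inside)
  h <- tryCatch(harmonize(sub, outcome, palindrome_eaf_window),
                error = function(e) NULL)
  if (is.null(h) || n_instruments(h) < 2) {
    return(excluded("fewer than 2 instruments after harmonization"))
  }
  attr(h, "locus_name") <- locus$locus_name
  h
}

#' Fixed-effects IVW MR for one locus
#'
#' @param h a locus `harmonized_set` with k >= 2 instruments.
#' @return A `locus_estimate`: `locus_name`, `k`, `estimate`
#'   (an `mr_estimate` under the fixed-effects model) and `heterogeneity`.
#' @export
locus_mr <- function(h) {
  if (inherits(h, "locus_excluded")) return(h)
  fit <- mr_ivw(h, model = "fixed")
  structure(list(locus_name = attr(h, "locus_name"),
                 k = fit$estimate$k,
                 estimate = fit$estimate,
                 heterogeneity = fit$heterogeneity),
            class = "locus_estimate")
}

#' Fixed-effects inverse-variance meta-analysis of MR estimates
#'
#' Pools betas with weights `1 / var_i`:
#' `beta = sum(beta_i / var_i) / sum(1 / var_i)`,
#' `se = (sum 1/var_i)^(-1/2)`, with cross-estimate Cochran's Q on
#' n - 1 df.
#'
#' @param estimates list of `mr_estimate` or `locus_estimate` objects (or
#'   any list elements with `beta` and `se`).
#' @return A `meta_result`: pooled `estimate` (an `mr_estimate` with
#'   method `"meta_fixed"`), `heterogeneity`, and `n_inputs`.
#' @export
meta_fixed <- function(estimates) {
  pull <- function(e) {
    if (inherits(e, "locus_estimate")) e <- e$estimate
    c(e$beta, e$se)
  }
  be <- vapply(estimates, pull, numeric(2))
  if (ncol(be) < 2) stop("meta_fixed: needs at least 2 estimates")
  beta_i <- be[1, ]; var_i <- be[2, ]^2
  wi <- 1 / var_i
  beta <- sum(wi * beta_i) / sum(wi)
  se <- 1 / sqrt(sum(wi))
  Q <- sum(wi * (beta_i - beta)^2)
  structure(list(estimate = new_mr_estimate("meta_fixed", length(beta_i), beta, se),
                 heterogeneity = new_heterogeneity(Q, length(beta_i) - 1),
                 n_inputs = length(beta_i)),
            class = "meta_result")
}

#' Per-SNP fixed-effects meta-analysis of two GWAS
#'
#' Aligns study B to study A's effect alleles (same allele logic as
#' [harmonize()]), then pools each shared SNP's betas by inverse variance
#' with a z-based p-value. SNPs present in only one study pass through
#' unchanged; a `meta_status` column flags `pooled`, `only_a`, `only_b`,
#' or `dropped` (shared SNPs lost to palindromic/mismatch alignment).
#'
#' @param study_a,study_b `gwas_table`s for the same trait.
#' @param palindrome_eaf_window passed to the allele alignment.
#' @return A `gwas_table` with an extra `meta_status` column.
#' @export
gwas_meta <- function(study_a, study_b, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(study_a, "gwas_table"), inherits(study_b, "gwas_table"))
  shared <- intersect(study_a$snp_id, study_b$snp_id)
  ia <- match(shared, study_a$snp_id)
  ib <- match(shared, study_b$snp_id)
  al <- align_alleles(study_a$effect_allele[ia], study_a$other_allele[ia],
                      study_a$eaf[ia],
                      study_b$effect_allele[ib], study_b$other_allele[ib],
                      study_b$eaf[ib], palindrome_eaf_window)
  ok <- al$status %in% c("kept", "flipped")
  bb <- study_b$beta[ib]
  bb[al$flip] <- -bb[al$flip]

  va <- study_a$se[ia]^2
  vb <- study_b$se[ib]^2
  wsum <- 1 / va + 1 / vb
  beta <- (study_a$beta[ia] / va + bb / vb) / wsum
  se <- 1 / sqrt(wsum)

  pooled <- data.frame(
    snp_id = shared,
    chrom = study_a$chrom[ia], pos = study_a$pos[ia],
    effect_allele = study_a$effect_allele[ia],
    other_allele = study_a$other_allele[ia],
    eaf = study_a$eaf[ia],
    beta = beta, se = se,
    pval = 2 * stats::pnorm(-abs(beta / se)),
    n = rowSums(cbind(study_a$n[ia], study_b$n[ib]), na.rm = FALSE),
    ncase = study_a$ncase[ia], ncontrol = study_a$ncontrol[ia],
    meta_status = ifelse(ok, "pooled", "dropped"),
    stringsAsFactors = FALSE
  )
  pooled <- pooled[ok, , drop = FALSE]

  pass <- function(tab, which_only) {
    solo <- !(tab$snp_id %in% shared)
    if (!any(solo)) return(NULL)
    d <- as.data.frame(tab)[solo, , drop = FALSE]
    d$meta_status <- which_only
    d
  }
  out <- rbind(pooled, pass(study_a, "only_a"), pass(study_b, "only_b"))
  rownames(out) <- NULL
  tab <- gwas_table(out, trait_name = trait_name(study_a),
                    trait_type = trait_type(study_a), validate = FALSE)
  tab$meta_status <- out$meta_status
  tab
}
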