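# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# minimal gwas_table from parallel vectors
make_tab <- function(snp_id, beta, se, pval = NULL, ea = "A", oa = "G",
                     eaf = NA_real_, chrom = "1", pos = NULL,
                     n = NA_real_, ncase = NA_real_, ncontrol = NA_real_,
                     trait = "trait", type = "quantitative", validate = FALSE) {
  m <- length(snp_id)
  if (is.null(pval)) pval <- 2 * pnorm(-abs(beta / se))
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  gwas_table(data.frame(
    snp_id = snp_id, chrom = rep_len(chrom, m), pos = pos,
    effect_allele = rep_len(ea, m), other_allele = rep_len(oa, m),
    eaf = rep_len(eaf, m), beta = beta, se = se, pval = pval,
    n = rep_len(n, m), ncase = rep_len(ncase, m),
    ncontrol = rep_len(ncontrol, m), stringsAsFactors = FALSE
  ), trait_name = trait, trait_type = type, validate = validate)
}

# single-exposure harmonized set straight from effect vectors: exposure
# beta/se and outcome beta/se per instrument, bypassing table I/O
make_h <- function(bx, sx, by, sy, snp_id = NULL,
                   exposure = "x", outcome = "y",
                   n_exposure = NA_real_, ncase = NA_real_, ncontrol = NA_real_) {
  k <- length(bx)
  if (is.null(snp_id)) snp_id <- sprintf("rs%03d", seq_len(k))
  ex <- make_tab(snp_id, bx, sx, trait = exposure, n = n_exposure)
  out <- make_tab(snp_id, by, sy, trait = outcome, type = "binary",
                  ncase = ncase, ncontrol = ncontrol)
  harmonize(ex, out)
}

# small config for fast replicate loops: one exposure, strong instruments
fast_config <- function(seed, theta = 0.1, m = 300, prop_causal = 0.2,
                        h2 = 0.1, pleiotropy = list(), n_exposure = 2e5,
                        n_case = 6e4, n_control = 5e4) {
  simulation_config(
    m_snps = m, exposure_names = "x", prop_causal = prop_causal,
    h2_x = h2, effect_corr = matrix(1), theta = theta,
    pleiotropy = pleiotropy, n_exposure = n_exposure,
    n_case = n_case, n_control = n_control, seed = seed)
}

# harmonized single-exposure set from a simulated study, instruments at
# genome-wide significance
sim_h <- function(cfg, p_instrument = 5e-8) {
  st <- simulate_gwas_pair(cfg)
  sig <- select_significant(st$exposures[[1]], p_instrument)
  list(h = harmonize(sig, st$outcome), truth = st$truth)
}
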