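# shared report plumbing: write tidy TSVs plus a JSON manifest sufficient
# to re-run bit-identically (config hash, seed, package version)
write_report <- function(out_dir, tables, manifest) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]]) && nrow(tables[[nm]]) > 0) {
      data.table::fwrite(as.data.frame(tables[[nm]]),
                         file.path(out_dir, paste0(nm, ".tsv")),
                         sep = "\t", quote = FALSE, na = "NA")
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

make_manifest <- function(analysis, params, counts) {
  list(analysis = analysis,
       package = "lipidmr",
       version = as.character(utils::packageVersion("lipidmr")),
       config = params,
       config_hash = rlang::hash(params),
       filter_counts = counts,
       timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
}

#' Single-trait MR analysis, end to end
#'
#' Runs the full single-exposure chain: genome-wide significance filter,
#' LD clumping, harmonization to the outcome, the estimator battery (IVW
#' under the requested model, MR-Egger with intercept test, weighted
#' median, weighted mode), Cochran's Q, Steiger directionality (when
#' sample sizes are available), then optional heterogeneity pruning and
#' re-estimation. Emits pre- and post-pruning result tables, the prune
#' log, and a manifest with the seed, parameter hash and reconciling
#' filter counts.
#'
#' @param exposure,outcome `gwas_table`s.
#' @param ld optional [ld_matrix()] (`NULL` = unlinked SNPs).
#' @param p_instrument instrument p-value threshold (default `5e-8`).
#' @param r2_clump clumping threshold (default 0.001).
#' @param q_alpha heterogeneity-pruning stop threshold (default 0.05).
#' @param prune run the heterogeneity pruning pass? (default `TRUE`)
#' @param model IVW error model.
#' @param n_boot,seed bootstrap controls.
#' @param out_dir optional directory for TSV/JSON artifacts.
#' @return list: `results` (tidy table with a `phase` column, pre/post
#'   pruning), `steiger`, `prune_log`, `set` (post-pruning
#'   `harmonized_set`), `manifest`.
#' @export
run_single_trait <- function(exposure, outcome, ld = NULL,
                             p_instrument = 5e-8, r2_clump = 0.001,
                             q_alpha = 0.05, prune = TRUE,
                             model = "multiplicative_random",
                             n_boot = 1000, seed = 1, out_dir = NULL) {
  n_in <- nrow(exposure)
  sig <- select_significant(exposure, p_instrument)
  cl <- ld_clump(sig, ld, r2_clump)
  h <- harmonize(cl$table, outcome)
  pre <- mr_all(h, model = model, n_boot = n_boot, seed = seed)
  pre$phase <- "pre_pruning"

  steiger <- tryCatch(steiger_test(h), error = function(e) NULL)

  prune_log <- new_prune_log()
  post <- NULL
  h_post <- h
  if (prune) {
    pr <- heterogeneity_prune(h, q_alpha = q_alpha)
    h_post <- pr$set
    prune_log <- pr$log
    post <- mr_all(h_post, model = model, n_boot = n_boot, seed = seed)
    post$phase <- "post_pruning"
  }
  results <- rbind(pre, post)

  counts <- list(snps_in = n_in,
                 genome_wide_significant = nrow(sig),
                 dropped_by_clump = nrow(sig) - nrow(cl$table),
                 dropped_by_harmonization = nrow(cl$table) - n_instruments(h),
                 dropped_by_heterogeneity = n_instruments(h) - n_instruments(h_post),
                 instruments_final = n_instruments(h_post))
  stopifnot(counts$instruments_final ==
              counts$genome_wide_significant - counts$dropped_by_clump -
              counts$dropped_by_harmonization - counts$dropped_by_heterogeneity)
  manifest <- make_manifest("single_trait",
                            list(exposure = trait_name(exposure),
                                 outcome = trait_name(outcome),
                                 p_instrument = p_instrument,
                                 r2_clump = r2_clump, q_alpha = q_alpha,
                                 prune = prune, model = model,
                                 n_boot = n_boot, seed = seed),
                            counts)
  write_report(out_dir,
               list(results = results,
                    prune_log = as.data.frame(prune_log),
                    steiger = if (is.null(steiger)) NULL else as.data.frame(steiger)),
               manifest)
  list(results = results, steiger = steiger, prune_log = prune_log,
       set = h_post, manifest = manifest)
}

#' Multivariable MR analysis, end to end
#'
#' Builds the joint instrument set, reports conditional instrument
#' strength, fits the multivariable model, prunes instruments driving
#' global heterogeneity, and refits. The result table carries before- and
#' after-pruning rows per exposure with `cond_F`, `QA`, `QA_df`,
#' `QA_pval` columns.
#'
#' @inheritParams run_single_trait
#' @param exposures list of >= 2 `gwas_table`s.
#' @return list: `results`, `strength`, `prune_log`, `set` (post-pruning
#'   `mvmr_set`), `manifest`.
#' @export
run_mvmr <- function(exposures, outcome, ld = NULL, p_instrument = 5e-8,
                     r2_clump = 0.001, q_alpha = 0.05, prune = TRUE,
                     model = "multiplicative_random", seed = 1,
                     out_dir = NULL) {
  if (inherits(exposures, "gwas_table")) exposures <- list(exposures)
  if (length(exposures) == 1) {
    # one exposure: the multivariable model reduces to single-trait IVW;
    # run the same instrument chain and fit through the K = 1 machinery
    sig <- select_significant(exposures[[1]], p_instrument)
    cl <- ld_clump(sig, ld, r2_clump)
    s <- as_mvmr_set(harmonize(cl$table, outcome))
  } else {
    s <- build_mvmr_set(exposures, outcome, ld, p_instrument, r2_clump)
  }
  strength <- conditional_strength(s)
  tidy <- function(fit, phase, str) {
    out <- fit$estimates
    out$cond_F <- str$cond_F[match(out$exposure, str$exposure)]
    out$QA <- fit$QA
    out$QA_df <- fit$QA_df
    out$QA_pval <- fit$QA_pval
    out$phase <- phase
    out
  }
  pre_fit <- mvmr_fit(s, model = model)
  results <- tidy(pre_fit, "pre_pruning", strength)
  prune_log <- new_prune_log()
  s_post <- s
  if (prune) {
    pr <- mvmr_heterogeneity_prune(s, q_alpha = q_alpha)
    s_post <- pr$set
    prune_log <- pr$log
    str_post <- conditional_strength(s_post)
    results <- rbind(results, tidy(mvmr_fit(s_post, model = model),
                                   "post_pruning", str_post))
  }
  counts <- list(instruments_joint = length(s$snp_ids),
                 dropped_by_heterogeneity = length(s$snp_ids) - length(s_post$snp_ids),
                 instruments_final = length(s_post$snp_ids))
  manifest <- make_manifest("mvmr",
                            list(exposures = s$exposure_names,
                                 outcome = trait_name(outcome),
                                 p_instrument = p_instrument,
                                 r2_clump = r2_clump, q_alpha = q_alpha,
                                 prune = prune, model = model, seed = seed),
                            counts)
  write_report(out_dir,
               list(results = results, strength = strength,
                    prune_log = as.data.frame(prune_log)),
               manifest)
  list(results = results, strength = strength, prune_log = prune_log,
       set = s_post, manifest = manifest)
}

#' Locus-specific MR with cross-locus meta-analysis
#'
#' Runs fixed-effects IVW MR per locus on conditionally independent
#' variants restricted to each gene window, excludes loci with fewer than
#' 2 instruments, and pools the per-locus estimates by fixed-effects
#' inverse-variance meta-analysis with a cross-locus heterogeneity Q. The
#' forest table has one row per locus (locus, k, OR, CI, p) plus a pooled
#' row.
#'
#' @param conditional_table `gwas_table` of conditionally independent
#'   exposure associations (chrom/pos required).
#' @param outcome `gwas_table`.
#' @param loci list of [locus_definition()]s (e.g. from
#'   [read_locus_table()]).
#' @param out_dir optional artifact directory.
#' @param seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return list: `forest` (per-locus + pooled rows), `excluded`
#'   (data.frame of skipped loci), `meta` (a `meta_result`, `NULL` when
#'   fewer than 2 loci survive), `estimates`, `manifest`.
#' @export
run_locus <- function(conditional_table, outcome, loci, out_dir = NULL,
                      seed = 1) {
  ests <- list()
  excluded <- data.frame(locus_name = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (locus in loci) {
    h <- locus_instruments(conditional_table, outcome, locus)
    le <- locus_mr(h)
    if (inherits(le, "locus_excluded")) {
      excluded <- rbind(excluded,
                        data.frame(locus_name = le$locus_name,
                                   reason = le$reason,
                                   stringsAsFactors = FALSE))
    } else {
      ests[[le$locus_name]] <- le
    }
  }
  row_of <- function(name, k, e, Q = NA, Q_df = NA, Q_pval = NA) {
    data.frame(locus = name, k = k, beta = e$beta, se = e$se, or = e$or,
               ci_low = e$ci_low, ci_high = e$ci_high, pval = e$pval,
               Q = Q, Q_df = Q_df, Q_pval = Q_pval, stringsAsFactors = FALSE)
  }
  forest <- do.call(rbind, lapply(ests, function(le) {
    row_of(le$locus_name, le$k, le$estimate, le$heterogeneity$Q,
           le$heterogeneity$df, le$heterogeneity$pval)
  }))
  meta <- NULL
  if (length(ests) >= 2) {
    meta <- meta_fixed(unname(ests))
    forest <- rbind(forest,
                    row_of("pooled", meta$n_inputs, meta$estimate,
                           meta$heterogeneity$Q, meta$heterogeneity$df,
                           meta$heterogeneity$pval))
  }
  if (is.null(forest)) {
    forest <- data.frame(locus = character(0), k = integer(0),
                         beta = numeric(0), se = numeric(0), or = numeric(0),
                         ci_low = numeric(0), ci_high = numeric(0),
                         pval = numeric(0), Q = numeric(0), Q_df = numeric(0),
                         Q_pval = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(forest) <- NULL
  counts <- list(loci_in = length(loci), loci_included = length(ests),
                 loci_excluded = nrow(excluded))
  manifest <- make_manifest("locus",
                            list(exposure = trait_name(conditional_table),
                                 outcome = trait_name(outcome),
                                 loci = vapply(loci, function(l) l$locus_name,
                                               character(1)),
                                 seed = seed),
                            counts)
  write_report(out_dir, list(forest = forest, excluded = excluded), manifest)
  list(forest = forest, excluded = excluded, meta = meta,
       estimates = ests, manifest = manifest)
}
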