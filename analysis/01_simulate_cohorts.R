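#!/usr/bin/env Rscript
# Step 1: generate the synthetic two-sample study that stands in for the
# real cohorts (five exposure GWAS: HDL, LDL, TGs, BMI, age at menarche;
# one case-control outcome GWAS), and write every summary-statistics table
# in the canonical TSV format so later steps consume them exactly as they
# would consume downloaded cohort data.

suppressPackageStartupMessages(library(lipidmr))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260923)
st <- simulate_gwas_pair(cfg)

for (ex in st$exposures) {
  write_gwas_table(ex, file.path(out_dir, paste0(trait_name(ex), ".tsv")),
                   report_path = file.path(out_dir,
                                           paste0(trait_name(ex), ".report.json")))
}
write_gwas_table(st$outcome, file.path(out_dir, "outcome.tsv"))

truth <- data.frame(exposure = cfg$exposure_names,
                    theta_direct = st$truth$theta,
                    theta_marginal = st$truth$theta_marginal,
                    r2_explained = st$truth$r2_explained)
write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message(sprintf(
  "Simulated %d SNPs for %d exposures (n = %s each) and a %s/%s case-control outcome.",
  cfg$m_snps, length(cfg$exposure_names),
  format(cfg$n_exposure[1], big.mark = ","),
  format(cfg$n_case, big.mark = ","), format(cfg$n_control, big.mark = ",")))
message(sprintf("Causal SNPs: %d shared across exposures; direct effects (log-OR/SD): %s",
                sum(st$truth$causal),
                paste(sprintf("%s=%.2f", cfg$exposure_names, cfg$theta),
                      collapse = ", ")))
message("Tables written under ", out_dir)
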