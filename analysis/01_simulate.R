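#!/usr/bin/env Rscript
# Step 1: generate the synthetic two-sample GWAS study.
#
# One quantitative exposure protein (X), one quantitative protein-ratio
# mediator (R), two decoy mediators with no exposure path, and a binary
# outcome (Y, log-odds scale, case fraction 0.1997) are simulated under the
# causal structure R = beta1*X + own SNPs, Y = direct*X + beta2*R, with
# beta1 = -0.1, beta2 = 0.2, direct = -0.12, so the true total effect is
# -0.14 and the true mediated proportion 100*(-0.02)/(-0.14) = 14.286%.
# Summary statistics are written in the package's TSV dialect together with
# a long-format LD file and a truth manifest.

suppressPackageStartupMessages(library(ratiomr))

seed <- 42L
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

sc <- simulate_mediation_scenario(seed = seed)

write_sumstats(sc$exposure, file.path(out_dir, "exposure_X.tsv"))
write_sumstats(sc$mediator, file.path(out_dir, "mediator_R.tsv"))
write_sumstats(sc$outcome, file.path(out_dir, "outcome_Y.tsv"))
for (d in sc$decoys) {
  write_sumstats(d, file.path(out_dir, paste0("mediator_", d$trait_id, ".tsv")))
}

# long-format LD: within-block pairs only (cross-block r is exactly 0)
r <- sc$ld$r
nz <- which(upper.tri(r) & abs(r) > 1e-12, arr.ind = TRUE)
ld_lines <- c("rsid_a\trsid_b\tr",
              sprintf("%s\t%s\t%.10g", sc$ld$snps[nz[, 1]], sc$ld$snps[nz[, 2]],
                      r[nz]))
writeLines(ld_lines, file.path(out_dir, "ld_pairs.tsv"))

truth <- sc$truth
writeLines(c(
  sprintf("seed: %d", truth$seed),
  sprintf("n_snps: %d", truth$n_snps),
  sprintf("beta1_true: %g", truth$beta1_true),
  sprintf("beta2_true: %g", truth$beta2_true),
  sprintf("direct_true: %g", truth$direct_true),
  sprintf("total_true: %g", truth$total_true),
  sprintf("true_mediated_prop_pct: %.3f",
          100 * truth$beta1_true * truth$beta2_true / truth$total_true),
  sprintf("exposure_instruments: %s",
          paste(truth$rsid[truth$instrument_idx], collapse = ",")),
  sprintf("mediator_snps: %s", paste(truth$rsid[truth$mediator_idx], collapse = ",")),
  sprintf("outcome_snps: %s", paste(truth$rsid[truth$outcome_idx], collapse = ","))
), file.path(out_dir, "truth_manifest.txt"))

message(sprintf(
  "Simulated %d SNPs (seed %d): exposure X (%d instruments), mediator R (%d own SNPs), %d decoys, binary outcome Y.",
  truth$n_snps, seed, length(truth$instrument_idx), length(truth$mediator_idx),
  length(sc$decoys)))
message(sprintf("True effects: beta1 = %g, beta2 = %g, total = %g (mediated proportion %.3f%%).",
                truth$beta1_true, truth$beta2_true, truth$total_true,
                100 * truth$beta1_true * truth$beta2_true / truth$total_true))
message("Wrote summary statistics, LD pairs and truth manifest to ", out_dir)
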