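#!/usr/bin/env Rscript
# Step 3: colocalization behaviour on single-region scenarios.
#
# Two 200-SNP regions under a dense AR(1) LD fabric (rho = 0.9): one where
# a single causal variant (marginal z = 8) drives both the quantitative
# trait and the binary outcome, and one where each trait has its own causal
# variant in negligible LD. Posterior probabilities over the five
# single-causal-variant hypotheses (PPH0-PPH4) should concentrate on H4
# (shared variant) in the first case and H3 (distinct variants) in the
# second; PPH4 > 0.75 is the conventional evidence bar.

suppressPackageStartupMessages(library(ratiomr))

dir.create("results", showWarnings = FALSE)
rows <- c(paste("mode", "seed", "n_snp", "PPH0", "PPH1", "PPH2", "PPH3", "PPH4",
                "colocalized", sep = "\t"))
for (mode in c("shared", "distinct")) {
  for (seed in 1:5) {
    sc <- simulate_coloc_scenario(mode, seed = seed)
    h <- harmonize(sc$trait1, sc$trait2)
    res <- colocalize(coloc_input(h$rows$rsid, h$rows$beta_exp, h$rows$se_exp,
                                  h$rows$beta_out, h$rows$se_out))
    rows <- c(rows, sprintf("%s\t%d\t%d\t%.4f\t%.4f\t%.4f\t%.4f\t%.4f\t%s",
                            mode, seed, res$n_snp, res$pph0, res$pph1, res$pph2,
                            res$pph3, res$pph4,
                            ifelse(res$pph4 > 0.75, "yes", "no")))
    message(sprintf("%-8s seed %d: PPH3 = %.4f, PPH4 = %.4f", mode, seed,
                    res$pph3, res$pph4))
  }
}
writeLines(rows, "results/coloc_scenarios.tsv")
message("Scenario posteriors written to results/coloc_scenarios.tsv")
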