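#!/usr/bin/env Rscript

# Step 1 — synthesize the study data.
#
# The real analysis pairs PTSD-trait summary statistics from a large
# veteran cohort with ischemic-stroke summary statistics from two
# consortia (European and African ancestry). Those consortium files are
# not redistributable, so this workflow generates a synthetic stand-in
# pair with known causal structure (true log-OR 0.2 per SD of the
# exposure trait), realistic per-SNP standard errors for the two sample
# sizes, LD blocks for clumping, and allele-coding/strand corruption in
# the outcome file that the harmonizer has to undo.

library(ptsdstrokemr)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_snp = 200, gamma_sd = 0.03, ld_block_size = 4,
                         ld_r2 = 0.6, seed = 20230701L)
sim <- simulate_pair(cfg)
ld <- simulate_ld_blocks(cfg)

write_summary_stats(sim$exposure, file.path(out_dir, "exposure_ptsd.tsv"))
write_summary_stats(sim$outcome, file.path(out_dir, "outcome_stroke.tsv"))
write.table(ld, file.path(out_dir, "ld_matrix.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
truth <- sim$truth
num <- vapply(truth, is.numeric, logical(1))
truth[num] <- lapply(truth[num], function(x) sprintf("%.15g", x))
write.table(truth, file.path(out_dir, "truth_manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

make_fixture_suite(file.path(out_dir, "fixtures"))

message(sprintf("simulated %d SNPs: exposure N=%d, outcome N=%d, true OR=%.3f",
                cfg$n_snp, cfg$n_exposure, cfg$n_outcome, exp(cfg$true_beta)))
message(sprintf("outcome corruption planted: %d sign flips, %d strand flips, %d palindromic SNPs",
                sum(sim$truth$sign_flipped), sum(sim$truth$strand_flipped),
                sum(sim$truth$palindromic)))
message("wrote ", out_dir)
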