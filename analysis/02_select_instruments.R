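#!/usr/bin/env Rscript

# Step 2 — build the genetic instrument.
#
# Three-step construction mirroring the study design: select SNPs below
# the suggestive threshold P < 5e-7 (used instead of 5e-8 to keep enough
# instruments per trait), clump to independent index SNPs within 1000 kb
# at r2 < 0.01 against the supplied LD matrix, and screen instrument
# strength with per-SNP F-statistics (all should exceed 10).

library(ptsdstrokemr)

exposure <- read_summary_stats("results/data/exposure_ptsd.tsv",
                               trait_name = "synthetic PTSD trait",
                               ancestry = "synthetic")
ld <- read_ld_matrix("results/data/ld_matrix.tsv")

selected <- filter_by_pvalue(exposure, 5e-7)
message(sprintf("p < 5e-7: %d of %d SNPs retained",
                n_records(selected), n_records(exposure)))

clumped <- clump(selected, window_kb = 1000, r2_threshold = 0.01, ld = ld)
message(sprintf("clumping: %d independent index SNPs", n_records(clumped)))

rep_ <- instrument_report(clumped)
print(rep_)

dir.create("results/instruments", recursive = TRUE, showWarnings = FALSE)
write_summary_stats(clumped, "results/instruments/instruments.tsv")
write.table(rep_$per_snp, "results/instruments/f_statistics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/instruments")
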