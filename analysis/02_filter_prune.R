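#!/usr/bin/env Rscript
# Step 2 — hard site filters and LD pruning.
#
# Reads the noisy VCFs from step 1, masks low-quality calls, applies the
# missingness / depth / minor-allele-frequency filters, verifies the
# result against the generator's truth sidecar, prunes for linkage
# disequilibrium (50-SNP window, step 10, r2 <= 0.1), and writes the
# filtered-pruned tables for the SFS/ABC and scan steps.

suppressPackageStartupMessages(library(divflow))

fixdir <- "results/fixtures"
out <- "results/filtered"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

for (lab in c("M1", "M5")) {
  vt <- read_vcf(file.path(fixdir, paste0(lab, ".vcf")),
                 popmap = read_popmap(file.path(fixdir,
                                                paste0(lab, ".popmap.tsv"))))
  truth <- read_truth(file.path(fixdir, paste0(lab, ".truth.json")))
  filt <- filter_sites(vt)
  ok <- identical(paste(filt$sites$chrom, filt$sites$pos),
                  paste(truth$chrom, truth$pos)[truth$survives])
  kept <- ld_prune(filt)
  pruned <- subset_sites(filt, kept)
  write_vcf(pruned, file.path(out, paste0(lab, ".filtered.pruned.vcf")))
  write_popmap(pruned, file.path(out, paste0(lab, ".popmap.tsv")))
  # unfiltered-but-parsed table for the window scan (scans use all
  # biallelic sites, not the MAF-filtered set)
  write_vcf(vt, file.path(out, paste0(lab, ".all.vcf")))
  cat(sprintf(
    "%s: %d sites -> %d after filters (truth match: %s) -> %d after LD pruning\n",
    lab, n_sites(vt), n_sites(filt), ok, n_sites(pruned)))
}
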