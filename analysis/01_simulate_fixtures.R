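#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic study data.
#
# Two diploid populations split 1 Ma ago (one generation per year,
# N1 = N2 = N_anc = 1e5). We generate one dataset under complete
# isolation (M1) and one under continuous gene flow until 10 kya (M5,
# 4Nm = 4), inject realistic call-level noise, and write VCF + sample
# maps with a machine-readable truth sidecar. A separate coding-gene
# fixture with planted MKT counts provides the selection-scan input.

suppressPackageStartupMessages(library(divflow))

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
sc <- study_config(n_loci = 500)

for (lab in c("M1", "M5")) {
  vt <- genotypes_from_model(sc$model(lab), sc$cfg(20260000 + match(lab,
                                                                    sc$models)))
  noisy <- inject_noise(vt, noise_config(frac_missing = 0.05,
                                         frac_bad_dp = 0.04,
                                         frac_low_gq = 0.04,
                                         n_low_maf = 50),
                        seed = 1000 + match(lab, sc$models))
  write_vcf(noisy$vt, file.path(out, paste0(lab, ".vcf")))
  write_popmap(noisy$vt, file.path(out, paste0(lab, ".popmap.tsv")))
  write_truth(noisy$truth, file.path(out, paste0(lab, ".truth.json")))
  cat(sprintf("%s: %d sites x %d samples; %d sites should survive filters\n",
              lab, n_sites(noisy$vt), n_samples(noisy$vt),
              sum(noisy$truth$survives)))
}

# coding genes: strong positive selection, strong negative selection,
# and 40 neutral genes
set.seed(3)
planted <- rbind(
  data.frame(Dn = 25L, Ds = 5L, Pn = 3L, Ps = 12L),   # positive
  data.frame(Dn = 3L, Ds = 12L, Pn = 25L, Ps = 5L),   # negative
  data.frame(Dn = rpois(40, 8), Ds = rpois(40, 8),
             Pn = rpois(40, 8), Ps = rpois(40, 8)))    # neutral
fx <- make_coding_fixture(planted, seed = 4)
paths <- write_coding_fixture(fx, out)
# persist alignments as plain text: gene, species, haplotype
aln_df <- do.call(rbind, lapply(fx$alignments, function(g)
  data.frame(gene = g$gene_id, chrom = g$chrom, start = g$start,
             end = g$end, strand = g$strand, species = g$species,
             haplotype = g$haplotypes, stringsAsFactors = FALSE)))
write.table(aln_df, file.path(out, "alignments.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("coding fixture: %d genes on %s (%d bp), written to %s\n",
            length(fx$alignments), names(fx$ref),
            Biostrings::width(fx$ref), out))
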