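aln_from_codons <- function(sp1_codons, sp2_codons, gene = "g") {
  # each argument: list of per-haplotype codon strings
  gene_alignment(gene,
                 c(vapply(sp1_codons, paste0, character(1), collapse = ""),
                   vapply(sp2_codons, paste0, character(1), collapse = "")),
                 rep(c("sp1", "sp2"),
                     c(length(sp1_codons), length(sp2_codons))))
}

test_that("MKT counting classifies fixed and polymorphic changes", {
  # AAA (Lys) vs AAG (Lys): synonymous fixed difference
  a <- aln_from_codons(list(c("ATG", "AAA"), c("ATG", "AAA")),
                       list(c("ATG", "AAG"), c("ATG", "AAG")))
  expect_identical(count_mkt(a)[c("Dn", "Ds", "Pn", "Ps")],
                   list(Dn = 0L, Ds = 1L, Pn = 0L, Ps = 0L))
  # AAA/GAA (Lys/Glu) segregating in one species: Pn
  b <- aln_from_codons(list(c("ATG", "AAA"), c("ATG", "GAA")),
                       list(c("ATG", "AAA"), c("ATG", "AAA")))
  expect_identical(count_mkt(b)[c("Dn", "Ds", "Pn", "Ps")],
                   list(Dn = 0L, Ds = 0L, Pn = 1L, Ps = 0L))
  # a shared allele never counts as divergence even when both segregate
  cc <- aln_from_codons(list(c("GGA", "AAA"), c("GGT", "AAA")),
                        list(c("GGA", "AAA"), c("GGT", "AAA")))
  expect_identical(count_mkt(cc)[c("Dn", "Ds", "Pn", "Ps")],
                   list(Dn = 0L, Ds = 0L, Pn = 0L, Ps = 1L))
})

test_that("MKT counts are invariant to haplotype order and species labels", {
  fx <- make_coding_fixture(
    data.frame(Dn = 6, Ds = 4, Pn = 3, Ps = 5), seed = 13)
  g <- fx$alignments[[1]]
  base <- count_mkt(g)
  set.seed(2)
  for (r in 1:5) {
    perm <- sample(length(g$haplotypes))
    gp <- gene_alignment(g$gene_id, g$haplotypes[perm], g$species[perm])
    expect_identical(count_mkt(gp), base)
  }
  swapped <- gene_alignment(g$gene_id, g$haplotypes,
                            c(sp1 = "sp2", sp2 = "sp1")[g$species])
  expect_identical(count_mkt(swapped)[c("Dn", "Ds", "Pn", "Ps")],
                   base[c("Dn", "Ds", "Pn", "Ps")])
})

test_that("multi-hit codons are skipped, premature stops skip the gene", {
  multi <- aln_from_codons(list(c("ATG", "AAA"), c("ATG", "AGC")),
                           list(c("ATG", "AAA"), c("ATG", "AAA")))
  res <- count_mkt(multi)
  expect_identical(res$Dn + res$Ds + res$Pn + res$Ps, 0L)
  expect_identical(res$n_skipped_codons, 1L)

  stopg <- aln_from_codons(list(c("ATG", "TAA", "AAA"),
                                c("ATG", "TAA", "AAA")),
                           list(c("ATG", "TAA", "GAA"),
                                c("ATG", "TAA", "GAA")))
  expect_warning(res2 <- count_mkt(stopg), "premature stop")
  expect_true(is.na(res2$Dn))
})

test_that("Fisher two-sided p matches enumeration and the base-R test", {
  expect_equal(fisher_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_2x2(0, 0, 0, 0), 1)
  expect_equal(fisher_2x2(20, 10, 5, 10),
               fisher_oracle(20, 10, 5, 10))
  # row-swap symmetry
  expect_equal(fisher_2x2(20, 10, 5, 10), fisher_2x2(5, 10, 20, 10))
  set.seed(7)
  for (r in 1:50) {
    tb <- rpois(4, 8)
    p1 <- fisher_2x2(tb[1], tb[2], tb[3], tb[4])
    p2 <- stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value
    p3 <- fisher_oracle(tb[1], tb[2], tb[3], tb[4])
    expect_equal(p1, p2, tolerance = 1e-9)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("neutrality index and alpha follow their definitions", {
  ni <- neutrality_index(20, 10, 5, 10)
  expect_equal(ni$NI, 0.25)
  expect_equal(ni$alpha, 0.75)
  # proportional table: NI = 1, alpha = 0
  ni2 <- neutrality_index(10, 5, 4, 2)
  expect_equal(ni2$NI, 1)
  expect_equal(ni2$alpha, 0)
  # zero-cell rule
  expect_true(is.na(neutrality_index(5, 0, 3, 2)$NI))
  expect_true(is.na(neutrality_index(0, 4, 3, 2)$NI))
  expect_true(is.na(neutrality_index(5, 4, 3, 0)$NI))
  expect_false(is.na(neutrality_index(5, 4, 0, 2)$NI))
  # pseudo-counts make everything defined
  expect_false(is.na(neutrality_index(5, 0, 3, 0, pseudo = TRUE)$NI))
})

test_that("selection classes combine significance with NI direction", {
  expect_identical(classify_selection(0.001, 0.25), "positive")
  expect_identical(classify_selection(0.001, 4), "negative")
  expect_identical(classify_selection(0.5, 0.25), "none")
  expect_identical(classify_selection(0.001, NA), "undefined")
  expect_identical(classify_selection(c(0.01, 0.2), c(0.5, 0.5)),
                   c("positive", "none"))
})

test_that("gene-window intersection uses any-bp overlap", {
  mkt <- data.frame(gene = c("in", "edge", "out", "weak"),
                    chrom = "c", start = c(100, 995, 2000, 150),
                    end = c(200, 1005, 2500, 250),
                    class = c("positive", "positive", "positive", "none"),
                    stringsAsFactors = FALSE)
  early <- data.frame(chrom = "c", start = c(1, 1001), end = c(300, 1500))
  got <- genes_in_early_windows(mkt, early)
  expect_identical(sort(got), c("edge", "in"))  # 1 bp overlap counts
  expect_identical(genes_in_early_windows(mkt, early[0, ]), character(0))
})

test_that("mkt_table integrates counting, testing and classification", {
  counts <- data.frame(Dn = c(20L, 2L, 5L), Ds = c(10L, 2L, 0L),
                       Pn = c(5L, 2L, 3L), Ps = c(10L, 2L, 4L))
  fx <- make_coding_fixture(counts, seed = 19)
  tb <- mkt_table(fx$alignments)
  expect_identical(tb$Dn, counts$Dn)
  expect_identical(tb$Ps, counts$Ps)
  expect_equal(tb$NI[1], 0.25)
  expect_equal(tb$alpha[1], 0.75)
  expect_identical(tb$class[3], "undefined")  # Ds = 0
  expect_equal(tb$p_fisher,
               fisher_2x2(counts$Dn, counts$Ds, counts$Pn, counts$Ps))
  tb2 <- mkt_table(fx$alignments, fdr = TRUE)
  expect_true(all(tb2$p_fdr >= tb2$p_fisher))
})

test_that("haplotypes rebuilt from a VCF recover planted alignments", {
  fx <- make_coding_fixture(
    data.frame(Dn = c(3, 2), Ds = c(2, 3), Pn = c(2, 1), Ps = c(1, 2)),
    n_hap = 4, seed = 23)
  # encode the fixture's haplotypes as diploid VCF genotypes: individuals
  # are consecutive haplotype pairs within each species
  refchars <- strsplit(as.character(fx$ref[["chrA"]]), "")[[1]]
  H <- lapply(fx$alignments, function(g) do.call(rbind,
                                                 strsplit(g$haplotypes, "")))
  sites <- list(); gts <- list()
  for (gi in seq_along(fx$alignments)) {
    g <- fx$alignments[[gi]]
    segs <- fx$cds[fx$cds$gene == g$gene_id, , drop = FALSE]
    sp <- divflow:::splice_cds(fx$ref[["chrA"]], segs)
    hm <- H[[gi]]
    var_cols <- which(apply(hm, 2, function(x) length(unique(x)) > 1))
    for (vc in var_cols) {
      alleles <- unique(hm[, vc])
      ref_a <- sp$seq[vc]
      alt_a <- setdiff(alleles, ref_a)
      gpos <- sp$gpos[vc]
      # genomic-strand alleles
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      ref_g <- refchars[gpos]
      alt_g <- if (segs$strand[1] == "-") comp[alt_a] else alt_a
      hap_has_alt <- hm[, vc] == alt_a
      gt <- hap_has_alt[c(1, 3, 5, 7)] + hap_has_alt[c(2, 4, 6, 8)]
      sites[[length(sites) + 1]] <-
        data.frame(chrom = "chrA", pos = gpos, ref = unname(ref_g),
                   alt = unname(alt_g), stringsAsFactors = FALSE)
      gts[[length(gts) + 1]] <- as.integer(gt)
    }
  }
  site_df <- do.call(rbind, sites)
  gt <- do.call(rbind, gts)
  ord <- order(site_df$pos)
  vt <- variant_table(site_df[ord, ], gt[ord, , drop = FALSE],
                      samples = data.frame(
                        id = c("a1", "a2", "b1", "b2"),
                        pop = c("sp1", "sp1", "sp2", "sp2")))
  rebuilt <- gene_alignments_from_vcf(vt, fx$ref, fx$cds)
  for (gene in names(fx$alignments)) {
    cnt1 <- count_mkt(fx$alignments[[gene]])
    cnt2 <- count_mkt(rebuilt[[gene]])
    expect_identical(cnt2[c("Dn", "Ds", "Pn", "Ps")],
                     cnt1[c("Dn", "Ds", "Pn", "Ps")],
                     info = gene)
  }
})
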