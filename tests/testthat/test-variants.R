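test_that("site filters apply GQ masking before the site-level rules", {
  # 10 diploids; site 1 clean/common, site 2 low GQ in 2 calls (20%
  # missing after masking), site 3 mean depth 8, site 4 rare allele
  gt <- matrix(1L, 4, 10)
  gt[4, ] <- 0L; gt[4, 1] <- 1L          # MAF = 1/20 = 0.05
  dp <- matrix(30, 4, 10); dp[3, ] <- 8
  gq <- matrix(60, 4, 10); gq[2, 1:2] <- 10
  vt <- toy_vt(gt, dp = dp, gq = gq)
  kept <- filter_sites(vt)
  expect_identical(kept$sites$pos, vt$sites$pos[1])

  # idempotence
  expect_identical(filter_sites(kept), kept)

  # empty table passes through, empty sample set errors
  empty <- subset_sites(vt, integer(0))
  expect_identical(n_sites(filter_sites(empty)), 0L)
  expect_error(filter_sites(subset_samples(vt, integer(0))), "no samples")
})

test_that("GQ-induced missingness counts against the missingness tolerance", {
  gt <- matrix(1L, 1, 10)
  gq <- matrix(60, 1, 10); gq[1, 1:2] <- 29  # 20% masked
  vt <- toy_vt(gt, gq = gq)
  expect_identical(n_sites(filter_sites(vt)), 0L)
  # boundary: exactly 10% missing survives
  gq2 <- matrix(60, 1, 10); gq2[1, 1] <- 29
  expect_identical(n_sites(filter_sites(toy_vt(gt, gq = gq2))), 1L)
})

test_that("LD pruning removes duplicates and keeps equilibrium sites", {
  set.seed(3)
  # many samples so chance r2 between unlinked sites stays tiny
  base <- matrix(rbinom(20 * 120, 2, 0.4), 20, 120)
  gt <- rbind(base[1, , drop = FALSE], base[1, , drop = FALSE], base[-1, ])
  vt <- toy_vt(gt)
  kept <- ld_prune(vt)
  expect_true(sum(kept %in% 1:2) == 1)  # exactly one of the duplicates
  expect_identical(setdiff(seq_len(21), kept), 2L)  # the rest survive

  # independent sites (simulated unlinked, low correlation) all retained
  vt2 <- toy_vt(matrix(rbinom(30 * 40, 2, 0.5), 30, 40))
  r2max <- max(stats::cor(t(vt2$gt))[upper.tri(diag(30))]^2)
  kept2 <- ld_prune(vt2, r2_max = max(0.9, r2max))
  expect_identical(kept2, seq_len(30))

  # pruning is a projection: pruning the pruned set removes nothing
  vt3 <- subset_sites(vt, kept)
  expect_identical(ld_prune(vt3), seq_len(n_sites(vt3)))
})

test_that("no retained pair within any window exceeds the r2 threshold", {
  set.seed(4)
  # strongly structured genotypes to force plenty of LD
  hap <- rbinom(20, 1, 0.5)
  gt <- t(sapply(1:100, function(i) {
    flip <- rbinom(20, 1, 0.12)
    2L * as.integer(xor(hap, flip))
  }))
  vt <- toy_vt(gt, pops = rep(c("sp1", "sp2"), each = 10))
  kept <- ld_prune(vt, window_snps = 50, step_snps = 10, r2_max = 0.1)
  expect_true(length(kept) >= 1)
  # exhaustive brute-force check over every sliding window
  for (s in seq(1, 100, by = 10)) {
    w <- intersect(s:min(s + 49, 100), kept)
    if (length(w) < 2) next
    r2 <- suppressWarnings(stats::cor(t(vt$gt[w, , drop = FALSE])))^2
    r2[!is.finite(r2)] <- 0
    diag(r2) <- 0
    expect_lte(max(r2), 0.1)
  }
})

test_that("fourfold-degenerate extraction matches hand enumeration", {
  # GGN (Gly) and CTN (Leu) are fourfold families; GGA GGT CTC at p = 11
  ref <- Biostrings::DNAStringSet(c(chrZ = paste0(
    paste(rep("A", 10), collapse = ""), "GGAGGTCTC", "TTTT")))
  cds <- data.frame(chrom = "chrZ", start = 11, end = 19, strand = "+",
                    phase = 0L, gene = "g1")
  ff <- fourfold_degenerate_sites(ref, cds)
  expect_identical(ff$pos, c(13L, 16L, 19L))

  # ATG TGG: Met and Trp have no degeneracy
  ref2 <- Biostrings::DNAStringSet(c(chrZ = "ATGTGG"))
  cds2 <- data.frame(chrom = "chrZ", start = 1, end = 6, strand = "+",
                     phase = 0L, gene = "g1")
  expect_identical(nrow(fourfold_degenerate_sites(ref2, cds2)), 0L)
})

test_that("minus-strand genes give the same genomic fourfold positions", {
  seqs <- "GGAGGTCTC"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  pad <- paste(rep("A", 10), collapse = "")
  ref_plus <- Biostrings::DNAStringSet(setNames(paste0(pad, seqs, pad), "c"))
  ref_minus <- Biostrings::DNAStringSet(setNames(paste0(pad, rc, pad), "c"))
  cds_p <- data.frame(chrom = "c", start = 11, end = 19, strand = "+",
                      phase = 0L, gene = "g")
  cds_m <- data.frame(chrom = "c", start = 11, end = 19, strand = "-",
                      phase = 0L, gene = "g")
  ffp <- fourfold_degenerate_sites(ref_plus, cds_p)$pos
  ffm <- fourfold_degenerate_sites(ref_minus, cds_m)$pos
  # third codon positions mirror within the gene footprint
  expect_identical(as.integer(sort(30 - ffm)), ffp)
})

test_that("fourfold calls agree with a mutate-and-retranslate oracle", {
  fx <- make_coding_fixture(
    data.frame(Dn = c(2, 1), Ds = c(2, 3), Pn = c(1, 0), Ps = c(2, 2)),
    min_codons = 12, seed = 77)
  ff <- fourfold_degenerate_sites(fx$ref, fx$cds)
  code <- Biostrings::GENETIC_CODE
  refchars <- strsplit(as.character(fx$ref[["chrA"]]), "")[[1]]
  translate_gene <- function(chars, segs) {
    sp <- divflow:::splice_cds(Biostrings::DNAStringSet(
      setNames(paste0(chars, collapse = ""), "chrA"))[[1]], segs)
    paste(code[apply(matrix(sp$seq, nrow = 3), 2, paste0, collapse = "")],
          collapse = "")
  }
  for (gene in unique(fx$cds$gene)) {
    segs <- fx$cds[fx$cds$gene == gene, , drop = FALSE]
    in_gene <- ff$pos[ff$pos >= segs$start & ff$pos <= segs$end]
    coding <- segs$start:segs$end
    for (pos in coding) {
      prots <- vapply(c("A", "C", "G", "T"), function(b) {
        ch <- refchars; ch[pos] <- b
        translate_gene(ch, segs)
      }, character(1))
      is_ff_oracle <- length(unique(prots)) == 1
      expect_identical(pos %in% in_gene, is_ff_oracle,
                       info = paste(gene, pos))
    }
  }
})

test_that("positions shared by two genes must be fourfold in both frames", {
  # gene A frame makes position 9 fourfold (GGA GGT CTC: pos 3,6,9);
  # gene B overlaps shifted by one codon-position, different frame
  ref <- Biostrings::DNAStringSet(c(c = "GGAGGTCTCGGG"))
  cds <- rbind(
    data.frame(chrom = "c", start = 1, end = 9, strand = "+", phase = 0L,
               gene = "A"),
    data.frame(chrom = "c", start = 2, end = 10, strand = "+", phase = 0L,
               gene = "B"))
  ff <- fourfold_degenerate_sites(ref, cds)
  # oracle: position kept iff fourfold under gene A's frame AND gene B's
  ffA <- fourfold_degenerate_sites(ref, cds[1, ])$pos
  ffB <- fourfold_degenerate_sites(ref, cds[2, ])$pos
  overlap <- 2:9
  expect_identical(ff$pos[ff$pos %in% overlap],
                   intersect(intersect(ffA, ffB), overlap))
  # positions covered by only one gene keep that gene's call
  expect_identical(setdiff(ff$pos, overlap),
                   setdiff(union(ffA, ffB), overlap))
})

test_that("genes with internal stop codons are skipped with a warning", {
  ref <- Biostrings::DNAStringSet(c(c = "ATGTGAGGA"))  # ATG TGA(stop) GGA
  cds <- data.frame(chrom = "c", start = 1, end = 9, strand = "+",
                    phase = 0L, gene = "bad")
  expect_warning(ff <- fourfold_degenerate_sites(ref, cds), "internal stop")
  expect_identical(nrow(ff), 0L)
})

test_that("subsetting is exact and seeded individual draws reproduce", {
  vt <- random_vt(20, n_per_sp = 5, seed = 9)
  expect_identical(subset_sites(vt, seq_len(20)), vt)
  expect_identical(n_sites(subset_sites(vt, integer(0))), 0L)
  bypos <- subset_sites(vt, vt$sites[3:5, c("chrom", "pos")])
  expect_identical(bypos$sites$pos, vt$sites$pos[3:5])
  expect_identical(subset_samples(vt, vt$samples$id), vt)
  expect_error(subset_samples(vt, "nope"), "unknown sample")
  d1 <- sample_individuals(vt, 3, seed = 5)
  d2 <- sample_individuals(vt, 3, seed = 5)
  expect_identical(d1, d2)
  expect_identical(as.integer(table(d1$samples$pop)), c(3L, 3L))
  expect_error(sample_individuals(vt, 9, seed = 1), "fewer than k")
})
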