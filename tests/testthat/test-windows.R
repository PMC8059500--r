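test_that("window pi matches direct arithmetic", {
  # one singleton among 6 diploids (12 alleles) in a 30 kb window
  gt <- matrix(0L, 1, 12)
  gt[1, 1] <- 1L
  vt <- toy_vt(gt, pops = rep(c("sp1", "sp2"), each = 6))
  w <- window_pi(vt, "sp1", 30000)
  expect_equal(w$pi, (2 * 1 * 11 / (12 * 11)) / 30000)
  expect_equal(window_pi(vt, "sp1", 30000,
                         denominator = "variant_sites")$pi, 1 / 6)
  # monomorphic window has pi = 0
  expect_equal(window_pi(vt, "sp2", 30000)$pi, 0)
})

test_that("Tajima's D is positive for balanced sites, negative for singletons", {
  balanced <- toy_vt(matrix(rep(c(2L, 2L, 2L, 0L, 0L, 0L), 10), 10, 6,
                            byrow = TRUE),
                     pops = rep("sp1", 6))
  singles <- toy_vt(cbind(matrix(0L, 10, 5), 1L), pops = rep("sp1", 6))
  expect_gt(tajimas_d(balanced, "sp1", 1000)$tajima_d, 0)
  expect_lt(tajimas_d(singles, "sp1", 1000)$tajima_d, 0)
  # fewer than 4 haploid genomes: undefined
  tiny <- toy_vt(matrix(1L, 1, 1), pops = "sp1")
  expect_true(is.na(tajimas_d(tiny, "sp1", 1000)$tajima_d))
})

test_that("Tajima's D matches the classical formula on a toy window", {
  vt <- random_vt(25, n_per_sp = 5, seed = 21)
  got <- tajimas_d(vt, "sp1", 1e6)$tajima_d
  # independent scalar transcription of the standard estimator
  g <- vt$gt[, vt$samples$pop == "sp1", drop = FALSE]
  n <- 2 * ncol(g)
  ac <- rowSums(g)
  seg <- ac > 0 & ac < n
  S <- sum(seg)
  pisum <- sum((2 * ac * (n - ac) / (n * (n - 1)))[seg])
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  expected <- (pisum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("dxy follows the per-site frequency formula", {
  # fixed difference: d = 1; shared polymorphism: d = 2 p (1 - p)
  gt <- rbind(c(rep(2L, 6), rep(0L, 6)),
              rep(1L, 12))
  vt <- toy_vt(gt, pops = rep(c("sp1", "sp2"), each = 6))
  w <- dxy_windows(vt, 30000, denominator = "variant_sites")
  expect_equal(w$dxy, (1 + 2 * 0.5 * 0.5) / 2)
  w2 <- dxy_windows(vt, 30000, denominator = "window_length")
  expect_equal(w2$dxy, (1 + 0.5) / 30000)
})

test_that("Weir-Cockerham FST hits its boundary cases and the oracle", {
  # reciprocally fixed site
  fixed <- toy_vt(matrix(rep(c(2L, 0L), each = 6), 1, 12),
                  pops = rep(c("sp1", "sp2"), each = 6))
  expect_equal(fst_wc(fixed, 30000)$fst, 1)
  # identical allele frequencies and genotype compositions in large
  # samples: near zero (small negative values permitted)
  half <- rep(rep(c(0L, 1L, 1L, 2L, 1L, 1L), 5), 2)
  same <- toy_vt(matrix(rep(half, 20), 20, 60, byrow = TRUE),
                 pops = rep(c("sp1", "sp2"), each = 30))
  expect_lt(abs(fst_wc(same, 1e6)$fst), 0.05)
  # random data, including missing calls, vs the scalar transcription
  vt <- random_vt(300, n_per_sp = 7, seed = 31)
  set.seed(32); vt$gt[sample(length(vt$gt), 150)] <- NA
  expect_equal(fst_wc(vt, 1e7)$fst,
               wc_fst_oracle(vt$gt, vt$samples$pop), tolerance = 1e-9)
})

test_that("early-diverged classification is boundary-inclusive", {
  st <- data.frame(dxy = c(0.36, 0.10, 0.35, NA))
  out <- classify_early(st)
  expect_identical(out$early, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("planted high-divergence windows are exactly the flagged set", {
  set.seed(41)
  # windows of 10 low-frequency sites; window 2 gets fixed differences
  gt <- matrix(rbinom(30 * 12, 2, 0.1), 30, 12)
  gt[11:20, ] <- rep(c(rep(2L, 6), rep(0L, 6)), each = 10)
  gt[11:20, 1] <- 1L  # keep some variation so sites are usable
  vt <- toy_vt(gt, pops = rep(c("sp1", "sp2"), each = 6),
               pos = c(1:10 * 10, 1000 + 1:10 * 10, 2000 + 1:10 * 10))
  sc <- scan_windows(vt, window_size = 1000)
  expect_identical(sc$early, c(FALSE, TRUE, FALSE))
  expect_identical(nrow(sc), 3L)
  # windows tile without overlap
  expect_true(all(sc$end - sc$start + 1 == 1000))
  expect_true(all(diff(sc$start) >= 1000))
})

test_that("scan_windows carries all statistics on a shared grid", {
  cfg <- sim_config(n1 = 12, n2 = 12, mu = 1e-8, locus_length = 1000,
                    n_loci = 60, seed = 42)
  model <- make_model("M1", 1e6, N1 = 1e5, N2 = 1e5, N_anc = 1e5)
  vt <- genotypes_from_model(model, cfg)
  sc <- scan_windows(vt, window_size = 30000)
  expect_true(all(c("pi_sp1", "pi_sp2", "td_sp1", "td_sp2", "dxy", "fst",
                    "early") %in% names(sc)))
  expect_true(all(sc$n_var > 0))
  expect_true(all(sc$dxy >= 0, na.rm = TRUE))
  expect_true(all(sc$fst <= 1, na.rm = TRUE))
  # deep-split property: per-bp divergence exceeds either species' mean
  # per-bp diversity
  dxy_bp <- dxy_windows(vt, 30000, denominator = "window_length")$dxy
  expect_gt(mean(dxy_bp, na.rm = TRUE),
            max(mean(sc$pi_sp1, na.rm = TRUE),
                mean(sc$pi_sp2, na.rm = TRUE)))
})

test_that("Mann-Whitney matches exact enumeration and behaves under shift", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)  # 2 / choose(6, 3)
  expect_identical(r$method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$U, 8)  # at its null mean
  expect_gte(same$p, 0.9)

  tied <- mann_whitney(rep(1, 5), rep(1, 7))
  expect_equal(tied$p, 1)

  set.seed(5)
  x <- rnorm(50)
  z1 <- abs(mann_whitney(x, rnorm(50, 0.5))$z)
  z2 <- abs(mann_whitney(x, rnorm(50, 3))$z)
  expect_gt(z2, z1)
  # large-sample p agrees with the base-R normal-approximation test
  y <- rnorm(50, 0.5)
  expect_equal(mann_whitney(x, y)$p,
               stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("rare-SNP sharing distinguishes sharing from private rarity", {
  # minor count 2: one copy in each species -> shared
  gt1 <- matrix(0L, 1, 12); gt1[1, 1] <- 1L; gt1[1, 7] <- 1L
  # minor count 2: both copies in sp1 -> rare, not shared
  gt2 <- matrix(0L, 1, 12); gt2[1, 1] <- 1L; gt2[1, 2] <- 1L
  # minor count 1: not rare
  gt3 <- matrix(0L, 1, 12); gt3[1, 1] <- 1L
  vt <- toy_vt(rbind(gt1, gt2, gt3), pops = rep(c("sp1", "sp2"), each = 6))
  r <- rare_shared_fraction(vt)
  expect_identical(r$n_rare, 2L)
  expect_identical(r$n_shared, 1L)
  expect_equal(r$proportion, 0.5)
  # the minor allele can be the reference allele
  gt4 <- matrix(2L, 1, 12); gt4[1, 1] <- 1L; gt4[1, 7] <- 1L
  r4 <- rare_shared_fraction(toy_vt(gt4, pops = rep(c("sp1", "sp2"),
                                                    each = 6)))
  expect_identical(r4$n_shared, 1L)
  # no rare sites: undefined, not zero
  r5 <- rare_shared_fraction(toy_vt(gt3, pops = rep(c("sp1", "sp2"),
                                                    each = 6)))
  expect_true(is.na(r5$proportion))
})

test_that("recent gene flow raises the shared fraction of rare SNPs", {
  sc <- study_config(n_loci = 150)
  vt1 <- genotypes_from_model(sc$model("M1"), sc$cfg(71))
  vt5 <- genotypes_from_model(sc$model("M5"), sc$cfg(71))
  r1 <- rare_shared_fraction(vt1)
  r5 <- rare_shared_fraction(vt5)
  expect_gt(r5$proportion, r1$proportion)
})
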