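# Shared fixture builders and independent test oracles.

# hand-built variant table: `gt` is a sites x samples dosage matrix
toy_vt <- function(gt, pops = NULL, chrom = "chr1", pos = NULL,
                   dp = NULL, gq = NULL) {
  gt <- as.matrix(gt)
  ns <- nrow(gt); nsam <- ncol(gt)
  if (is.null(pops)) pops <- rep(c("sp1", "sp2"), each = nsam / 2)
  if (is.null(pos)) pos <- seq_len(ns) * 10L
  if (is.null(dp)) dp <- matrix(30, ns, nsam)
  if (is.null(gq)) gq <- matrix(60, ns, nsam)
  dp[is.na(gt)] <- NA; gq[is.na(gt)] <- NA
  variant_table(
    data.frame(chrom = rep(chrom, ns), pos = pos,
               ref = rep("A", ns), alt = rep("G", ns),
               stringsAsFactors = FALSE),
    gt, dp, gq,
    data.frame(id = paste0("s", seq_len(nsam)), pop = pops,
               stringsAsFactors = FALSE))
}

# random two-species polymorphic genotype matrix with no missing data
random_vt <- function(n_sites, n_per_sp = 6, seed = 1, maf_min = 0) {
  set.seed(seed)
  n_gen <- n_sites * 4
  p <- runif(n_gen, 0.1, 0.9)
  gt <- matrix(rbinom(n_gen * 2 * n_per_sp, 2, rep(p, 2 * n_per_sp)),
               n_gen, 2 * n_per_sp)
  ac <- rowSums(gt); an <- 2 * ncol(gt)
  maf <- pmin(ac / an, 1 - ac / an)
  ok <- which(ac > 0 & ac < an & maf >= maf_min)
  stopifnot(length(ok) >= n_sites)
  toy_vt(gt[ok[seq_len(n_sites)], , drop = FALSE])
}

# Weir & Cockerham (1984) two-population estimator, scalar transcription
# from the published variance components; independent of the package's
# vectorized implementation.
wc_fst_oracle <- function(gt, pop) {
  num <- den <- 0
  for (i in seq_len(nrow(gt))) {
    g1 <- gt[i, pop == unique(pop)[1]]
    g2 <- gt[i, pop == unique(pop)[2]]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    n1 <- length(g1); n2 <- length(g2)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(g1) / (2 * n1); p2 <- sum(g2) / (2 * n2)
    h1 <- mean(g1 == 1); h2 <- mean(g2 == 1)
    r <- 2
    nbar <- mean(c(n1, n2))
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - 1 / (nbar - 1) *
                          (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# brute-force two-sided Fisher p by enumerating all tables with the
# observed margins, probabilities from choose() directly
fisher_oracle <- function(a, b, cc, d) {
  N <- a + b + cc + d
  if (N == 0) return(1)
  m1 <- a + b; k <- a + cc
  xs <- max(0, k - (N - m1)):min(k, m1)
  pr <- choose(m1, xs) * choose(N - m1, k - xs) / choose(N, k)
  p_obs <- choose(m1, a) * choose(N - m1, k - a) / choose(N, k)
  min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
}

# descendant leaves of every genealogy node (children precede parents)
leaves_below <- function(g) {
  n <- g$n1 + g$n2
  desc <- vector("list", length(g$time))
  for (i in seq_len(n)) desc[[i]] <- i
  for (v in seq_along(g$time)) {
    p <- g$parent[v]
    if (!is.na(p)) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  desc
}

# run the python/tskit oracle if available; returns NULL when python or
# its libraries are unusable (tests then fall back to R-side oracles)
run_msprime_oracle <- function(cfg_list, n_loci, seed) {
  script <- system.file("oracles", "msprime_joint_sfs.py",
                        package = "divflow")
  cfgf <- tempfile(fileext = ".json")
  outf <- tempfile(fileext = ".json")
  jsonlite::write_json(c(cfg_list, list(n_loci = n_loci, seed = seed)),
                       cfgf, auto_unbox = TRUE, digits = NA)
  status <- suppressWarnings(
    system2("python", c(script, cfgf, outf), stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(outf)) return(NULL)
  jsonlite::read_json(outf, simplifyVector = TRUE)
}
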