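# Windowed genome-scan statistics: per-species nucleotide diversity and
# Tajima's D, between-species D_XY and Weir-Cockerham F_ST, early-diverged
# window classification, Mann-Whitney species contrasts, and the
# genome-wide rare-allele sharing statistic.
#
# Window convention: half-open [start, end) of length `window_size`,
# 0-based internally; reported `start`/`end` are 1-based inclusive.

window_index <- function(pos, size) (pos - 1L) %/% size

# per-site quantities for one population: alt count, allele number,
# het-call count, missing fraction
pop_site_stats <- function(vt, cols) {
  sub <- vt$gt[, cols, drop = FALSE]
  nn <- rowSums(!is.na(sub))
  list(ac = rowSums(sub, na.rm = TRUE),
       an = 2L * nn,
       nhet = rowSums(sub == 1L, na.rm = TRUE),
       ncall = nn,
       miss = rowMeans(is.na(sub)))
}

# unbiased per-site heterozygosity 2 j (n - j) / (n (n - 1))
site_het <- function(ac, an) {
  ifelse(an >= 2, 2 * ac * (an - ac) / (an * (an - 1)), NA_real_)
}

window_frame <- function(vt, window_size) {
  w <- window_index(vt$sites$pos, window_size)
  key <- paste(vt$sites$chrom, w)
  uk <- unique(key)
  first <- match(uk, key)
  data.frame(chrom = vt$sites$chrom[first],
             win = w[first],
             start = w[first] * window_size + 1L,
             end = (w[first] + 1L) * window_size,
             key = uk, stringsAsFactors = FALSE)
}

#' Windowed nucleotide diversity for one species
#'
#' Per site, the unbiased heterozygosity `2 j (n - j) / (n (n - 1))` for
#' alt count `j` among `n` non-missing alleles; the window value is the
#' sum over usable sites divided by the chosen denominator.
#'
#' @param vt a [variant_table()].
#' @param population species label (a value of `vt$samples$pop`).
#' @param window_size window length in bp (default 30 kb).
#' @param denominator `"window_length"` (per-bp diversity, assuming
#'   non-variant positions are invariant) or `"variant_sites"` (mean per
#'   variant site).
#' @return data.frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `n_var` (usable sites), `pi` (NA when no usable site).
#' @export
window_pi <- function(vt, population, window_size = 30000,
                      denominator = c("window_length", "variant_sites")) {
  denominator <- match.arg(denominator)
  stopifnot(population %in% vt$samples$pop)
  ps <- pop_site_stats(vt, which(vt$samples$pop == population))
  h <- site_het(ps$ac, ps$an)
  wf <- window_frame(vt, window_size)
  key <- paste(vt$sites$chrom, window_index(vt$sites$pos, window_size))
  use <- !is.na(h)
  n_var <- as.integer(tapply(use, factor(key, wf$key), sum))
  hsum <- as.numeric(tapply(ifelse(use, h, 0), factor(key, wf$key), sum))
  denom <- if (denominator == "window_length") window_size else n_var
  out <- wf[c("chrom", "start", "end")]
  out$n_var <- n_var
  out$pi <- ifelse(n_var > 0, hsum / denom, NA_real_)
  out
}

# Tajima's D normalizing constants for haploid sample size n
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed Tajima's D for one species
#'
#' `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the classical
#' constants evaluated at the species' maximum haploid sample size `n`.
#' Sites with more than `max_missing` missing calls in the species are
#' excluded from both `S` and the pairwise-diversity sum (per-site
#' heterozygosity still uses the site's own non-missing allele count, so
#' it stays unbiased under the residual missingness).
#'
#' @inheritParams window_pi
#' @param max_missing per-site missing-call tolerance within the species.
#' @return data.frame: `chrom`, `start`, `end`, `n_var` (segregating
#'   sites `S`), `tajima_d` (NA when `S = 0` or `n < 4`).
#' @export
tajimas_d <- function(vt, population, window_size = 30000,
                      max_missing = 0.2) {
  stopifnot(population %in% vt$samples$pop)
  cols <- which(vt$samples$pop == population)
  n <- 2L * length(cols)
  ps <- pop_site_stats(vt, cols)
  h <- site_het(ps$ac, ps$an)
  seg <- !is.na(h) & ps$ac > 0 & ps$ac < ps$an & ps$miss <= max_missing
  wf <- window_frame(vt, window_size)
  key <- factor(paste(vt$sites$chrom, window_index(vt$sites$pos, window_size)),
                wf$key)
  S <- as.integer(tapply(seg, key, sum))
  pisum <- as.numeric(tapply(ifelse(seg, h, 0), key, sum))
  out <- wf[c("chrom", "start", "end")]
  out$n_var <- S
  if (n < 4) {
    out$tajima_d <- NA_real_
    return(out)
  }
  k <- tajima_constants(n)
  vr <- k$e1 * S + k$e2 * S * (S - 1)
  out$tajima_d <- ifelse(S > 0 & vr > 0,
                         (pisum - S / k$a1) / sqrt(vr), NA_real_)
  out
}

#' Windowed absolute divergence D_XY between the two species
#'
#' Per site `d = p1 (1 - p2) + p2 (1 - p1)` with `p` the alt-allele
#' frequency over non-missing alleles in each species; the window value is
#' the sum over usable sites divided by the denominator. The default
#' `"variant_sites"` denominator gives the mean per variant site — the
#' scale on which the early-diverged threshold of 0.35 is defined;
#' `"window_length"` gives per-bp divergence.
#'
#' @inheritParams window_pi
#' @return data.frame: `chrom`, `start`, `end`, `n_var`, `dxy`.
#' @export
dxy_windows <- function(vt, window_size = 30000,
                        denominator = c("variant_sites", "window_length")) {
  denominator <- match.arg(denominator)
  pops <- pop_indices(vt)
  if (length(pops) != 2) stop("two species labels required")
  s1 <- pop_site_stats(vt, pops[[1]])
  s2 <- pop_site_stats(vt, pops[[2]])
  use <- s1$an >= 1 & s2$an >= 1
  p1 <- ifelse(use, s1$ac / s1$an, NA_real_)
  p2 <- ifelse(use, s2$ac / s2$an, NA_real_)
  d <- p1 * (1 - p2) + p2 * (1 - p1)
  wf <- window_frame(vt, window_size)
  key <- factor(paste(vt$sites$chrom, window_index(vt$sites$pos, window_size)),
                wf$key)
  n_var <- as.integer(tapply(use, key, sum))
  dsum <- as.numeric(tapply(ifelse(use, d, 0), key, sum))
  denom <- if (denominator == "window_length") window_size else n_var
  out <- wf[c("chrom", "start", "end")]
  out$n_var <- n_var
  out$dxy <- ifelse(n_var > 0, dsum / denom, NA_real_)
  out
}

# Weir & Cockerham (1984) per-site variance components for two
# populations of diploids. Returns a matrix with columns a, b, c.
wc_components <- function(vt, pops) {
  s1 <- pop_site_stats(vt, pops[[1]])
  s2 <- pop_site_stats(vt, pops[[2]])
  n1 <- s1$ncall; n2 <- s2$ncall
  ok <- n1 >= 2 & n2 >= 2
  p1 <- ifelse(ok, s1$ac / s1$an, NA_real_)
  p2 <- ifelse(ok, s2$ac / s2$an, NA_real_)
  h1 <- ifelse(ok, s1$nhet / n1, NA_real_)
  h2 <- ifelse(ok, s2$nhet / n2, NA_real_)
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2v <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - (r - 1) / r * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2v - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  cbind(a = ifelse(ok, a, NA_real_),
        b = ifelse(ok, b, NA_real_),
        c = ifelse(ok, cc, NA_real_))
}

#' Windowed Weir-Cockerham F_ST between the two species
#'
#' Per-site variance components `a` (among populations), `b`, `c` from
#' Weir & Cockerham (1984); the window estimate is the ratio of sums
#' `sum(a) / sum(a + b + c)` over usable sites (those with at least two
#' non-missing diploid calls in each species). Slightly negative window
#' values are possible, as usual for this estimator.
#'
#' @inheritParams window_pi
#' @return data.frame: `chrom`, `start`, `end`, `n_var`, `fst` (NA when
#'   the denominator is zero).
#' @export
fst_wc <- function(vt, window_size = 30000) {
  pops <- pop_indices(vt)
  if (length(pops) != 2) stop("two species labels required")
  comp <- wc_components(vt, pops)
  use <- !is.na(comp[, "a"])
  wf <- window_frame(vt, window_size)
  key <- factor(paste(vt$sites$chrom, window_index(vt$sites$pos, window_size)),
                wf$key)
  n_var <- as.integer(tapply(use, key, sum))
  asum <- as.numeric(tapply(ifelse(use, comp[, "a"], 0), key, sum))
  tsum <- as.numeric(tapply(ifelse(use, rowSums(comp), 0), key, sum))
  out <- wf[c("chrom", "start", "end")]
  out$n_var <- n_var
  out$fst <- ifelse(n_var > 0 & tsum != 0, asum / tsum, NA_real_)
  out
}

#' Flag early-diverged windows
#'
#' Windows whose absolute divergence reaches the threshold (boundary
#' inclusive: `dxy >= threshold`) are classified as having begun diverging
#' earliest (`W_early`). Meaningful on the per-variant-site D_XY scale.
#'
#' @param stats a data.frame with a `dxy` column (e.g. from
#'   [dxy_windows()] or [scan_windows()]).
#' @param threshold early-divergence threshold (default 0.35).
#' @return `stats` with a logical `early` column appended (NA dxy gives
#'   `FALSE`).
#' @export
classify_early <- function(stats, threshold = 0.35) {
  stopifnot("dxy" %in% names(stats))
  stats$early <- !is.na(stats$dxy) & stats$dxy >= threshold
  stats
}

#' Full 30 kb genome scan
#'
#' Runs [window_pi()] and [tajimas_d()] for both species, [dxy_windows()]
#' and [fst_wc()], on the shared window grid, and applies
#' [classify_early()].
#'
#' @param vt a [variant_table()] with two species labels.
#' @param window_size window length in bp.
#' @param dxy_threshold early-diverged threshold on per-variant-site D_XY.
#' @param pi_denominator denominator for [window_pi()].
#' @param dxy_denominator denominator for [dxy_windows()].
#' @return data.frame with one row per window: coordinates, `n_var`,
#'   `pi_<sp>`, `td_<sp>` for each species, `dxy`, `fst`, `early`.
#' @export
scan_windows <- function(vt, window_size = 30000, dxy_threshold = 0.35,
                         pi_denominator = "window_length",
                         dxy_denominator = "variant_sites") {
  pops <- sort(unique(vt$samples$pop))
  if (length(pops) != 2) stop("two species labels required")
  d <- dxy_windows(vt, window_size, denominator = dxy_denominator)
  out <- d[c("chrom", "start", "end", "n_var")]
  for (p in pops) {
    out[[paste0("pi_", p)]] <-
      window_pi(vt, p, window_size, denominator = pi_denominator)$pi
    out[[paste0("td_", p)]] <- tajimas_d(vt, p, window_size)$tajima_d
  }
  out$dxy <- d$dxy
  out$fst <- fst_wc(vt, window_size)$fst
  classify_early(out, dxy_threshold)
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank ties. `U` counts pairs in which an `x` value
#' exceeds a `y` value (ties count one half). The p-value uses the normal
#' approximation with tie-corrected variance and continuity correction;
#' when both samples have at most 8 observations and there are no ties,
#' the exact null distribution is used instead.
#'
#' @param x,y numeric vectors (NAs dropped).
#' @return list with `U`, `z`, `p` (two-sided), and `method`.
#' @export
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("each sample needs at least one value")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  if (v <= 0) return(list(U = U, z = 0, p = 1, method = "degenerate"))
  cc <- if (U != mu) 0.5 * sign(U - mu) else 0
  z <- (U - mu - cc) / sqrt(v)
  if (n1 <= 8 && n2 <= 8 && tie_term == 0) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    return(list(U = U, z = z, p = p, method = "exact"))
  }
  list(U = U, z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal")
}

#' Proportion of rare SNPs shared between the two species
#'
#' A site is rare when its global minor-allele count (over all non-missing
#' alleles in both species) lies inside `count_range`; a rare site is
#' shared when that minor allele is observed at least once in each
#' species. Recent gene flow leaves an excess of shared rare variants, so
#' this proportion is a simple genome-wide gene-flow indicator.
#'
#' @param vt a [variant_table()] with two species labels.
#' @param count_range inclusive minor-allele-count bounds (default 2-5).
#' @return list with `count_range`, `n_rare`, `n_shared`, `proportion`
#'   (NA when no site is rare).
#' @export
rare_shared_fraction <- function(vt, count_range = c(2, 5)) {
  pops <- pop_indices(vt)
  if (length(pops) != 2) stop("two species labels required")
  s1 <- pop_site_stats(vt, pops[[1]])
  s2 <- pop_site_stats(vt, pops[[2]])
  ac <- s1$ac + s2$ac
  an <- s1$an + s2$an
  minor_is_alt <- ac <= an / 2
  mac <- ifelse(minor_is_alt, ac, an - ac)
  rare <- an > 0 & mac >= count_range[1] & mac <= count_range[2]
  in1 <- ifelse(minor_is_alt, s1$ac, s1$an - s1$ac) > 0
  in2 <- ifelse(minor_is_alt, s2$ac, s2$an - s2$ac) > 0
  shared <- rare & in1 & in2
  n_rare <- sum(rare)
  list(count_range = count_range, n_rare = n_rare,
       n_shared = sum(shared),
       proportion = if (n_rare > 0) sum(shared) / n_rare else NA_real_)
}
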