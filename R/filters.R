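#' Hard site-filter configuration
#'
#' Defaults follow common whole-genome re-sequencing practice for
#' moderate-coverage data: mask low-quality calls, then drop sites with
#' more than 10% missing calls, mean depth outside 10-50 reads, or minor
#' allele frequency below 0.1.
#'
#' @param max_missing_frac maximum tolerated fraction of missing calls per
#'   site (after GQ masking).
#' @param min_mean_dp,max_mean_dp bounds on the mean read depth per
#'   individual, computed over non-missing calls.
#' @param min_gq calls with genotype quality below this are set missing.
#' @param min_maf minimum minor-allele frequency over non-missing alleles.
#' @return an object of class `"site_filter_config"`.
#' @export
site_filter_config <- function(max_missing_frac = 0.10, min_mean_dp = 10,
                               max_mean_dp = 50, min_gq = 30,
                               min_maf = 0.10) {
  stopifnot(max_missing_frac >= 0, max_missing_frac <= 1,
            min_maf >= 0, min_maf <= 0.5, min_mean_dp <= max_mean_dp)
  structure(list(max_missing_frac = max_missing_frac,
                 min_mean_dp = min_mean_dp, max_mean_dp = max_mean_dp,
                 min_gq = min_gq, min_maf = min_maf),
            class = "site_filter_config")
}

#' Apply hard site filters to a variant table
#'
#' Order of operations (fixed): (1) individual calls with
#' `GQ < cfg$min_gq` are masked to missing; then a site is dropped if
#' (2) its missing-call fraction exceeds `cfg$max_missing_frac`, or
#' (3) its mean depth over non-missing calls lies outside
#' `[min_mean_dp, max_mean_dp]`, or (4) its minor-allele frequency over
#' non-missing alleles is below `cfg$min_maf`. Masking precedes the site
#' filters, so GQ-induced missingness counts against the missingness
#' tolerance and masked calls do not contribute to depth or frequency.
#'
#' The function is idempotent: filtering an already-filtered table changes
#' nothing.
#'
#' @param vt a [variant_table()].
#' @param cfg a [site_filter_config()].
#' @return the filtered `"variant_table"` (with masked calls set missing).
#' @export
filter_sites <- function(vt, cfg = site_filter_config()) {
  stopifnot(inherits(vt, "variant_table"), inherits(cfg, "site_filter_config"))
  if (n_samples(vt) == 0) stop("variant table has no samples")
  if (n_sites(vt) == 0) return(vt)
  gt <- vt$gt; dp <- vt$dp; gq <- vt$gq
  mask <- !is.na(gq) & gq < cfg$min_gq
  gt[mask] <- NA_integer_
  dp[mask] <- NA_real_
  gq[mask] <- NA_real_

  miss_frac <- rowMeans(is.na(gt))
  mean_dp <- rowMeans(ifelse(is.na(gt), NA, dp), na.rm = TRUE)
  ac <- rowSums(gt, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(gt))
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)

  keep <- miss_frac <= cfg$max_missing_frac &
    !is.na(mean_dp) & mean_dp >= cfg$min_mean_dp & mean_dp <= cfg$max_mean_dp &
    !is.na(maf) & maf >= cfg$min_maf
  out <- vt
  out$gt <- gt; out$dp <- dp; out$gq <- gq
  subset_sites(out, which(keep))
}

#' Prune variants for linkage disequilibrium (PLINK-style)
#'
#' Sliding-window pairwise pruning on genotype dosages: within each
#' `window_snps`-SNP window (per chromosome), while any retained pair has
#' squared Pearson correlation (pairwise-complete observations) above
#' `r2_max`, the member of the currently worst pair with the lower minor
#' allele frequency is removed (tie: the later position); the window then
#' slides by `step_snps` SNPs. A site removed in any window stays removed.
#' Monomorphic-in-overlap pairs have undefined r2 and are treated as
#' uncorrelated. Exact PLINK bit-compatibility is not promised (PLINK's
#' tie-breaking is unspecified); the defaults mirror
#' `--indep-pairwise 50 10 0.1`.
#'
#' @param vt a [variant_table()].
#' @param window_snps window size in SNPs.
#' @param step_snps slide in SNPs.
#' @param r2_max maximum tolerated squared correlation.
#' @return integer vector of retained site indices (ascending).
#' @export
ld_prune <- function(vt, window_snps = 50, step_snps = 10, r2_max = 0.1) {
  stopifnot(inherits(vt, "variant_table"))
  keep <- rep(TRUE, n_sites(vt))
  ac <- rowSums(vt$gt, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(vt$gt))
  p <- ifelse(an > 0, ac / an, 0)
  maf <- pmin(p, 1 - p)

  for (ch in unique(vt$sites$chrom)) {
    idx <- which(vt$sites$chrom == ch)
    if (length(idx) < 2) next
    starts <- seq(1L, length(idx), by = step_snps)
    for (s in starts) {
      w <- idx[s:min(s + window_snps - 1L, length(idx))]
      w <- w[keep[w]]
      if (length(w) < 2) next
      G <- t(vt$gt[w, , drop = FALSE])
      r2 <- suppressWarnings(
        stats::cor(G, use = "pairwise.complete.obs"))^2
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      while (TRUE) {
        worst <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
        if (r2[worst[1], worst[2]] <= r2_max) break
        a <- worst[1]; b <- worst[2]
        # drop the lower-MAF member; tie -> the later position
        drop_local <- if (maf[w[a]] < maf[w[b]]) a
          else if (maf[w[b]] < maf[w[a]]) b
          else max(a, b)
        keep[w[drop_local]] <- FALSE
        r2[drop_local, ] <- 0
        r2[, drop_local] <- 0
      }
    }
  }
  which(keep)
}

# codon prefixes whose third position is fourfold degenerate under the
# standard genetic code
fourfold_prefixes <- function() {
  code <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  pref <- as.vector(outer(bases, bases, paste0))
  pref[vapply(pref, function(p) {
    length(unique(code[paste0(p, bases)])) == 1L
  }, logical(1))]
}

# splice CDS segments of one gene into coding orientation.
# segs: data.frame(start, end, strand, phase) in genomic coordinates.
# Returns list(seq = character vector of bases, gpos = genomic position of
# each coding base, in reading order).
splice_cds <- function(refseq, segs) {
  minus <- segs$strand[1] == "-"
  segs <- segs[order(segs$start, decreasing = minus), , drop = FALSE]
  gpos <- unlist(lapply(seq_len(nrow(segs)), function(i) {
    p <- segs$start[i]:segs$end[i]
    if (minus) rev(p) else p
  }), use.names = FALSE)
  s <- strsplit(as.character(refseq), "")[[1]][gpos]
  if (minus) s <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[s]
  phase <- segs$phase[1]
  if (is.na(phase)) phase <- 0L
  if (phase > 0) {
    s <- s[-seq_len(phase)]
    gpos <- gpos[-seq_len(phase)]
  }
  ncod <- length(s) %/% 3L
  s <- s[seq_len(ncod * 3L)]
  gpos <- gpos[seq_len(ncod * 3L)]
  list(seq = s, gpos = gpos)
}

#' Fourfold-degenerate site extraction
#'
#' Finds genomic positions at which, given the codon context of the
#' reference, all four nucleotides encode the same amino acid (standard
#' genetic code) — the classic proxy for neutrally evolving sites. Minus
#' strand CDS are handled by reverse complement; CDS phase is honoured.
#' Positions covered by the CDS of more than one gene are reported only if
#' they are fourfold degenerate in every covering frame. Genes whose
#' spliced CDS contains an internal stop codon are skipped with a warning;
#' codons containing non-ACGT characters are skipped.
#'
#' @param ref a named `Biostrings::DNAStringSet` (or character vector) of
#'   reference chromosomes.
#' @param ann a `GenomicRanges::GRanges` of CDS features (e.g. from
#'   `rtracklayer::import` of a GFF3) with a `Parent` or `ID` metadata
#'   column grouping segments by gene, or a data.frame with columns
#'   `chrom`, `start`, `end`, `strand`, `phase`, `gene`.
#' @return a data.frame with columns `chrom`, `pos` (1-based), sorted.
#' @export
fourfold_degenerate_sites <- function(ref, ann) {
  if (!methods::is(ref, "DNAStringSet"))
    ref <- Biostrings::DNAStringSet(ref)
  cds <- as_cds_table(ann)
  code <- Biostrings::GENETIC_CODE
  ff_pref <- fourfold_prefixes()

  per_gene <- split(cds, cds$gene)
  keep <- list(); covered <- list()
  for (gene in names(per_gene)) {
    segs <- per_gene[[gene]]
    chrom <- segs$chrom[1]
    if (!chrom %in% names(ref)) stop("chromosome not in reference: ", chrom)
    sp <- splice_cds(ref[[chrom]], segs)
    if (length(sp$seq) < 3) next
    ncod <- length(sp$seq) %/% 3L
    cod <- matrix(sp$seq, nrow = 3L)[, seq_len(ncod), drop = FALSE]
    cod_str <- apply(cod, 2, paste0, collapse = "")
    valid <- !grepl("[^ACGT]", cod_str)
    aa <- rep(NA_character_, ncod)
    aa[valid] <- code[cod_str[valid]]
    stops <- which(!is.na(aa) & aa == "*")
    if (any(stops < ncod)) {
      warning("internal stop codon in gene ", gene, "; gene skipped")
      next
    }
    third <- matrix(sp$gpos, nrow = 3L)[3L, seq_len(ncod)]
    is_ff <- valid & substr(cod_str, 1, 2) %in% ff_pref
    keep[[gene]] <- data.frame(chrom = rep(chrom, sum(is_ff)),
                               pos = as.integer(third[is_ff]))
    covered[[gene]] <- data.frame(chrom = rep(chrom, length(sp$gpos)),
                                  pos = as.integer(sp$gpos))
  }
  if (length(keep) == 0)
    return(data.frame(chrom = character(0), pos = integer(0)))
  ff <- unique(do.call(rbind, keep))
  cov <- do.call(rbind, covered)
  # a position is kept only if fourfold in EVERY frame covering it:
  # count coverage and fourfold votes per position
  ffkey <- paste(ff$chrom, ff$pos)
  covkey <- paste(cov$chrom, cov$pos)
  nff <- table(paste(do.call(rbind, keep)$chrom, do.call(rbind, keep)$pos))
  ncov <- table(covkey)
  ok <- as.integer(nff[ffkey]) == as.integer(ncov[ffkey])
  out <- ff[ok, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# normalize annotation input to data.frame(chrom,start,end,strand,phase,gene)
as_cds_table <- function(ann) {
  if (is.data.frame(ann)) {
    stopifnot(all(c("chrom", "start", "end", "strand", "phase", "gene")
                  %in% names(ann)))
    return(ann)
  }
  stopifnot(methods::is(ann, "GRanges"))
  g <- ann[ann$type == "CDS" | is.null(ann$type)]
  md <- S4Vectors::mcols(g)
  gene <- if ("Parent" %in% names(md)) {
    as.character(unlist(md$Parent))
  } else if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else stop("annotation needs Parent or ID to group CDS by gene")
  phase <- if ("phase" %in% names(md)) {
    ph <- md$phase
    as.integer(if (is.factor(ph)) as.character(ph) else ph)
  } else 0L
  data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
             start = GenomicRanges::start(g),
             end = GenomicRanges::end(g),
             strand = as.character(GenomicRanges::strand(g)),
             phase = phase,
             gene = gene,
             stringsAsFactors = FALSE)
}
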