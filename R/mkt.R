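# Per-gene McDonald-Kreitman analysis: synonymous / non-synonymous
# polymorphism and divergence counts from two-species CDS haplotype
# alignments, Fisher's exact test, neutrality index and alpha, selection
# classification, and intersection with early-diverged windows.

#' Gene alignment container
#'
#' Indel-free CDS haplotypes of one gene from both species, in coding
#' orientation, together with the gene's genomic footprint.
#'
#' @param gene_id gene identifier.
#' @param haplotypes character vector (or `DNAStringSet`) of equal-length
#'   CDS haplotypes, length a multiple of 3, in reading-frame orientation.
#' @param species character vector of species labels, one per haplotype
#'   (exactly two distinct labels, each with >= 2 haplotypes for MKT).
#' @param chrom,start,end,strand genomic footprint of the CDS (1-based
#'   inclusive), used for window intersection; optional.
#' @return an object of class `"gene_alignment"`.
#' @export
gene_alignment <- function(gene_id, haplotypes, species, chrom = NA,
                           start = NA, end = NA, strand = "+") {
  haplotypes <- as.character(haplotypes)
  stopifnot(length(haplotypes) == length(species),
            length(unique(nchar(haplotypes))) == 1,
            nchar(haplotypes[1]) %% 3 == 0)
  structure(list(gene_id = gene_id, haplotypes = haplotypes,
                 species = as.character(species), chrom = chrom,
                 start = start, end = end, strand = strand),
            class = "gene_alignment")
}

#' McDonald-Kreitman counts for one gene
#'
#' Scans every variable codon position of the alignment. A variant is a
#' fixed difference when the two species share no allele at the position,
#' and a polymorphism when it segregates within at least one species; the
#' change is synonymous or non-synonymous judged against the codon context
#' of the within-gene consensus. Codons with more than one variable
#' position, or with more than two alleles at a position, are skipped (and
#' counted in `n_skipped_codons`); this keeps the classification
#' unambiguous without enumerating mutational paths. Genes whose consensus
#' carries a premature stop return NA counts with a warning.
#'
#' @param g a [gene_alignment()] with >= 2 haplotypes per species.
#' @return list with `Dn`, `Ds`, `Pn`, `Ps` and `n_skipped_codons`.
#' @export
count_mkt <- function(g) {
  stopifnot(inherits(g, "gene_alignment"))
  sp <- unique(g$species)
  if (length(sp) != 2) stop("exactly two species required")
  if (any(table(g$species) < 2)) stop(">= 2 haplotypes per species required")
  H <- do.call(rbind, strsplit(g$haplotypes, ""))
  L <- ncol(H)
  code <- Biostrings::GENETIC_CODE
  # within-gene consensus (majority base per position, ties by base order)
  consensus <- apply(H, 2, function(col) names(which.max(table(col))))
  ncod <- L %/% 3L
  cons_cod <- apply(matrix(consensus, nrow = 3L), 2, paste0, collapse = "")
  cons_aa <- ifelse(grepl("[^ACGT]", cons_cod), NA, code[cons_cod])
  if (any(cons_aa == "*" & seq_len(ncod) < ncod, na.rm = TRUE)) {
    warning("premature stop in consensus of gene ", g$gene_id,
            "; gene skipped")
    return(list(Dn = NA_integer_, Ds = NA_integer_, Pn = NA_integer_,
                Ps = NA_integer_, n_skipped_codons = NA_integer_))
  }
  n_alleles <- apply(H, 2, function(col) length(unique(col)))
  var_pos <- which(n_alleles > 1)
  codon_of <- (var_pos - 1L) %/% 3L + 1L
  multi <- codon_of %in% codon_of[duplicated(codon_of)]
  skip_multi <- unique(codon_of[multi])
  too_many <- var_pos[n_alleles[var_pos] > 2]
  skip_alleles <- unique((too_many - 1L) %/% 3L + 1L)
  skipped <- union(skip_multi, skip_alleles)
  use <- var_pos[!(codon_of %in% skipped)]

  Dn <- Ds <- Pn <- Ps <- 0L
  i1 <- g$species == sp[1]; i2 <- g$species == sp[2]
  for (pos in use) {
    cod_i <- (pos - 1L) %/% 3L
    off <- pos - cod_i * 3L        # position within codon, 1..3
    ctx <- consensus[(cod_i * 3L + 1L):(cod_i * 3L + 3L)]
    alleles <- unique(H[, pos])
    if (any(grepl("[^ACGT]", c(ctx, alleles)))) next
    cod_a <- ctx; cod_a[off] <- alleles[1]
    cod_b <- ctx; cod_b[off] <- alleles[2]
    syn <- code[paste0(cod_a, collapse = "")] ==
      code[paste0(cod_b, collapse = "")]
    a1 <- unique(H[i1, pos]); a2 <- unique(H[i2, pos])
    fixed <- length(intersect(a1, a2)) == 0
    if (fixed) {
      if (syn) Ds <- Ds + 1L else Dn <- Dn + 1L
    } else {
      if (syn) Ps <- Ps + 1L else Pn <- Pn + 1L
    }
  }
  list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps,
       n_skipped_codons = length(skipped))
}

#' Fisher's exact two-sided test for a 2x2 MKT table
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' all tables as or less probable than the observed one. Vectorized over
#' its arguments. The all-zero table gives p = 1.
#'
#' @param Dn,Ds,Pn,Ps non-negative counts (recycled to a common length).
#' @return numeric vector of two-sided p-values.
#' @export
fisher_2x2 <- function(Dn, Ds, Pn, Ps) {
  n <- max(length(Dn), length(Ds), length(Pn), length(Ps))
  Dn <- rep_len(Dn, n); Ds <- rep_len(Ds, n)
  Pn <- rep_len(Pn, n); Ps <- rep_len(Ps, n)
  vapply(seq_len(n), function(i) {
    a <- Dn[i]; b <- Ds[i]; cc <- Pn[i]; d <- Ps[i]
    if (anyNA(c(a, b, cc, d))) return(NA_real_)
    N <- a + b + cc + d
    if (N == 0) return(1)
    m1 <- a + b          # divergence margin
    k <- a + cc          # non-synonymous margin
    support <- max(0, k - (N - m1)):min(k, m1)
    pr <- stats::dhyper(support, m1, N - m1, k)
    p_obs <- stats::dhyper(a, m1, N - m1, k)
    min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Neutrality index and alpha
#'
#' `NI = (Pn / Ps) / (Dn / Ds)` and `alpha = 1 - NI`, the fraction of
#' non-synonymous divergence attributable to positive selection. With
#' `Ps = 0`, `Dn = 0` or `Ds = 0` the index is undefined (NA) unless
#' `pseudo = TRUE`, which adds 0.5 to every cell first. Vectorized.
#'
#' @param Dn,Ds,Pn,Ps non-negative counts.
#' @param pseudo add 0.5 to every cell (Haldane correction).
#' @return data.frame with columns `NI` and `alpha`.
#' @export
neutrality_index <- function(Dn, Ds, Pn, Ps, pseudo = FALSE) {
  if (pseudo) {
    Dn <- Dn + 0.5; Ds <- Ds + 0.5; Pn <- Pn + 0.5; Ps <- Ps + 0.5
  }
  ni <- ifelse(Ps == 0 | Dn == 0 | Ds == 0, NA_real_,
               (Pn / Ps) / (Dn / Ds))
  data.frame(NI = ni, alpha = 1 - ni)
}

#' Classify selection from an MKT row
#'
#' Significant departures (`p < alpha_level`) with `NI < 1` (excess
#' non-synonymous divergence) are classified as positive selection, with
#' `NI > 1` as negative selection; non-significant genes are `"none"`,
#' undefined NI gives `"undefined"`. No multiple-testing correction is
#' applied by default (an FDR column can be added downstream with
#' `p.adjust`).
#'
#' @param p Fisher p-values.
#' @param NI neutrality indices.
#' @param alpha_level significance level (default 0.05).
#' @return character vector in
#'   `{"positive", "negative", "none", "undefined"}`.
#' @export
classify_selection <- function(p, NI, alpha_level = 0.05) {
  out <- rep("none", length(p))
  out[is.na(NI) | is.na(p)] <- "undefined"
  sig <- !is.na(p) & !is.na(NI) & p < alpha_level
  out[sig & NI < 1] <- "positive"
  out[sig & NI > 1] <- "negative"
  out
}

#' McDonald-Kreitman table over a set of genes
#'
#' Runs [count_mkt()], [fisher_2x2()], [neutrality_index()] and
#' [classify_selection()] over a list of gene alignments.
#'
#' @param alignments list of [gene_alignment()] objects.
#' @param alpha_level significance level for classification.
#' @param pseudo pass-through to [neutrality_index()].
#' @param fdr also report Benjamini-Hochberg adjusted p-values.
#' @return data.frame: `gene`, `chrom`, `start`, `end`, `Dn`, `Ds`, `Pn`,
#'   `Ps`, `p_fisher`, (`p_fdr`,) `NI`, `alpha`, `class`.
#' @export
mkt_table <- function(alignments, alpha_level = 0.05, pseudo = FALSE,
                      fdr = FALSE) {
  rows <- lapply(alignments, function(g) {
    cnt <- count_mkt(g)
    data.frame(gene = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end, Dn = cnt$Dn, Ds = cnt$Ds, Pn = cnt$Pn,
               Ps = cnt$Ps, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_fisher <- fisher_2x2(out$Dn, out$Ds, out$Pn, out$Ps)
  if (fdr) out$p_fdr <- stats::p.adjust(out$p_fisher, method = "BH")
  ni <- neutrality_index(out$Dn, out$Ds, out$Pn, out$Ps, pseudo = pseudo)
  out$NI <- ni$NI
  out$alpha <- ni$alpha
  out$class <- classify_selection(out$p_fisher, out$NI, alpha_level)
  rownames(out) <- NULL
  out
}

#' Positively selected genes inside early-diverged windows
#'
#' A gene intersects `W_early` when any CDS bp overlaps any early window
#' (1 bp of overlap suffices; intervals are treated as 1-based inclusive).
#'
#' @param mkt data.frame from [mkt_table()] with `chrom`, `start`, `end`
#'   and `class` columns.
#' @param early data.frame of early windows with `chrom`, `start`, `end`
#'   (1-based inclusive, e.g. [scan_windows()] rows with `early = TRUE`).
#' @return character vector of positively selected gene ids intersecting
#'   an early window.
#' @export
genes_in_early_windows <- function(mkt, early) {
  pos <- mkt[mkt$class == "positive" & !is.na(mkt$chrom) &
               !is.na(mkt$start), , drop = FALSE]
  if (nrow(pos) == 0 || nrow(early) == 0) return(character(0))
  gr_genes <- GenomicRanges::GRanges(
    pos$chrom, IRanges::IRanges(pos$start, pos$end))
  gr_early <- GenomicRanges::GRanges(
    early$chrom, IRanges::IRanges(early$start, early$end))
  hit <- GenomicRanges::countOverlaps(gr_genes, gr_early) > 0
  pos$gene[hit]
}

#' Reconstruct per-gene CDS haplotype alignments from a variant table
#'
#' Substitutes each sample's alleles into the reference CDS; every diploid
#' contributes two pseudo-haplotypes, with heterozygous calls placing the
#' ref allele on one and the alt allele on the other (phase is not
#' recoverable from unphased genotypes; MKT counts are phase-robust
#' because multi-hit codons are skipped by [count_mkt()]). Missing calls
#' take the reference allele.
#'
#' @param vt a [variant_table()].
#' @param ref a named `DNAStringSet` (or character vector) of chromosomes.
#' @param ann CDS annotation as accepted by [fourfold_degenerate_sites()].
#' @return list of [gene_alignment()] objects.
#' @export
gene_alignments_from_vcf <- function(vt, ref, ann) {
  if (!methods::is(ref, "DNAStringSet"))
    ref <- Biostrings::DNAStringSet(ref)
  cds <- as_cds_table(ann)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  out <- list()
  for (gene in unique(cds$gene)) {
    segs <- cds[cds$gene == gene, , drop = FALSE]
    chrom <- segs$chrom[1]
    sp <- splice_cds(ref[[chrom]], segs)
    site_idx <- match(sp$gpos, ifelse(vt$sites$chrom == chrom,
                                      vt$sites$pos, NA_integer_))
    hit <- which(!is.na(site_idx))
    haps <- list(); spp <- character(0)
    minus <- segs$strand[1] == "-"
    for (j in seq_len(n_samples(vt))) {
      for (copy in 1:2) {
        s <- sp$seq
        for (h in hit) {
          gti <- vt$gt[site_idx[h], j]
          alt <- vt$sites$alt[site_idx[h]]
          if (minus) alt <- comp[alt]
          use_alt <- !is.na(gti) && (gti == 2L || (gti == 1L && copy == 2L))
          if (use_alt) s[h] <- alt
        }
        haps[[length(haps) + 1L]] <- paste0(s, collapse = "")
        spp <- c(spp, vt$samples$pop[j])
      }
    }
    out[[gene]] <- gene_alignment(gene, unlist(haps), spp, chrom = chrom,
                                  start = min(segs$start),
                                  end = max(segs$end),
                                  strand = segs$strand[1])
  }
  out
}
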