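# Synthetic-data generator: standards-compliant VCF / FASTA / GFF3
# fixtures with machine-readable ground truth, used both as the package's
# test harness and as a way to exercise the full pipeline on data whose
# generating process is known exactly.

#' Default chromosome layout for synthetic genotypes
#'
#' @param n_chrom number of chromosomes.
#' @param length_bp length of each chromosome.
#' @return data.frame with columns `name`, `length`.
#' @export
chrom_layout <- function(n_chrom = 2, length_bp = 5e6) {
  data.frame(name = paste0("chr", seq_len(n_chrom)),
             length = rep(length_bp, n_chrom),
             stringsAsFactors = FALSE)
}

# descendant leaves of every node of a genealogy (children precede parents)
descendant_leaves <- function(g) {
  n <- g$n1 + g$n2
  nnode <- length(g$time)
  desc <- vector("list", nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (v in seq_len(nnode)) {
    p <- g$parent[v]
    if (!is.na(p)) desc[[p]] <- c(desc[[p]], desc[[v]])
  }
  desc
}

#' Simulate diploid genotypes under a divergence model
#'
#' Simulates `cfg$n_loci` independent genealogies, drops infinite-sites
#' mutations, pairs consecutive haploid lineages into diploid individuals
#' (`cfg$n1 / 2` in species 1, `cfg$n2 / 2` in species 2), and places the
#' loci at non-overlapping coordinates on the chromosome layout (tiled
#' left to right with `spacing` bp between loci). The reference allele is
#' the ancestral state; `mispolarize_frac` randomly swaps ref/alt at that
#' fraction of sites to emulate unknown polarization. Clean calls carry
#' depth in 10-50 and genotype quality 30-99 everywhere (noise is injected
#' separately by [inject_noise()]).
#'
#' @param model a [demographic_model()].
#' @param cfg a [sim_config()] with even `n1`, `n2`.
#' @param layout a [chrom_layout()] data.frame.
#' @param spacing gap between consecutive loci in bp.
#' @param mispolarize_frac fraction of sites with ref/alt swapped.
#' @return a [variant_table()]; the generating seed is attached as
#'   attribute `"seed"`.
#' @export
genotypes_from_model <- function(model, cfg, layout = chrom_layout(),
                                 spacing = 1000, mispolarize_frac = 0) {
  stopifnot(inherits(model, "demographic_model"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  L <- cfg$locus_length
  per_chrom <- floor((layout$length + spacing) / (L + spacing))
  if (cfg$n_loci > sum(per_chrom))
    stop("chromosome layout cannot hold ", cfg$n_loci, " loci")
  chrom_of <- rep(layout$name, per_chrom)[seq_len(cfg$n_loci)]
  offset_in <- unlist(lapply(per_chrom, function(k) seq_len(k) - 1L),
                      use.names = FALSE)[seq_len(cfg$n_loci)]
  locus_start <- as.integer(offset_in * (L + spacing))  # 0-based offset

  n_ind <- (cfg$n1 + cfg$n2) / 2
  ids <- c(paste0("sp1_", seq_len(cfg$n1 / 2)),
           paste0("sp2_", seq_len(cfg$n2 / 2)))
  pops <- rep(c("sp1", "sp2"), c(cfg$n1 / 2, cfg$n2 / 2))
  bases <- c("A", "C", "G", "T")

  chroms <- character(0); poss <- integer(0)
  refs <- character(0); alts <- character(0)
  gts <- list()
  for (l in seq_len(cfg$n_loci)) {
    g <- simulate_genealogy(model, cfg$n1, cfg$n2)
    mut <- drop_mutations(g, cfg$mu, L, detail = TRUE)
    if (nrow(mut) == 0) next
    nm <- nrow(mut)
    if (nm > L) {
      warning("locus ", l, ": more mutations than sites; extra dropped")
      mut <- mut[seq_len(L), , drop = FALSE]
      nm <- L
    }
    pos_in <- sort(sample.int(L, nm))
    desc <- descendant_leaves(g)
    for (s in seq_len(nm)) {
      hap <- integer(cfg$n1 + cfg$n2)
      hap[desc[[mut[s, "branch"]]]] <- 1L
      gt <- hap[seq(1, length(hap), 2)] + hap[seq(2, length(hap), 2)]
      ref <- sample(bases, 1)
      alt <- sample(setdiff(bases, ref), 1)
      if (mispolarize_frac > 0 && stats::runif(1) < mispolarize_frac) {
        tmp <- ref; ref <- alt; alt <- tmp
        gt <- 2L - gt
      }
      chroms <- c(chroms, chrom_of[l])
      poss <- c(poss, as.integer(locus_start[l] + pos_in[s]))
      refs <- c(refs, ref); alts <- c(alts, alt)
      gts[[length(gts) + 1L]] <- gt
    }
  }
  samples <- data.frame(id = ids, pop = pops, stringsAsFactors = FALSE)
  if (length(gts) == 0) {
    vt <- variant_table(
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0)),
      matrix(integer(0), 0, n_ind), matrix(numeric(0), 0, n_ind),
      matrix(numeric(0), 0, n_ind), samples)
  } else {
    gt <- do.call(rbind, gts)
    nc <- length(gt)
    dp <- matrix(sample(10:50, nc, replace = TRUE), nrow(gt), ncol(gt))
    gq <- matrix(sample(30:99, nc, replace = TRUE), nrow(gt), ncol(gt))
    sites <- data.frame(chrom = chroms, pos = poss, ref = refs, alt = alts,
                        stringsAsFactors = FALSE)
    ord <- order(sites$chrom, sites$pos)
    vt <- variant_table(sites[ord, , drop = FALSE], gt[ord, , drop = FALSE],
                        dp[ord, , drop = FALSE], gq[ord, , drop = FALSE],
                        samples)
  }
  attr(vt, "seed") <- cfg$seed
  vt
}

#' Noise configuration for filter fixtures
#'
#' @param frac_missing fraction of genotype calls set missing.
#' @param frac_bad_dp fraction of calls whose depth is redrawn below 10 or
#'   above 50.
#' @param frac_low_gq fraction of calls whose genotype quality is redrawn
#'   below 30.
#' @param n_low_maf number of sites whose genotypes are rewritten to a
#'   single heterozygote (forcing minor allele frequency < 0.1 for sample
#'   sizes above 5 diploids).
#' @return an object of class `"noise_config"`.
#' @export
noise_config <- function(frac_missing = 0, frac_bad_dp = 0,
                         frac_low_gq = 0, n_low_maf = 0) {
  stopifnot(frac_missing >= 0, frac_missing <= 1,
            frac_bad_dp >= 0, frac_bad_dp <= 1,
            frac_low_gq >= 0, frac_low_gq <= 1, n_low_maf >= 0)
  structure(list(frac_missing = frac_missing, frac_bad_dp = frac_bad_dp,
                 frac_low_gq = frac_low_gq, n_low_maf = n_low_maf),
            class = "noise_config")
}

#' Inject filter-violating noise into a clean variant table
#'
#' Randomly degrades the configured fractions of calls / sites and records
#' the exact set of sites that must survive the default hard filters
#' ([site_filter_config()]), by direct per-site bookkeeping of each rule
#' on the degraded table.
#'
#' @param vt a clean [variant_table()] (as from [genotypes_from_model()]).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @param cfg the [site_filter_config()] the truth refers to.
#' @return list with `vt` (degraded table) and `truth` — a data.frame with
#'   one row per site: `chrom`, `pos`, per-rule failure flags
#'   (`fail_missing`, `fail_dp`, `fail_maf`) and `survives`.
#' @export
inject_noise <- function(vt, noise, seed = NULL,
                         cfg = site_filter_config()) {
  stopifnot(inherits(vt, "variant_table"), inherits(noise, "noise_config"))
  if (!is.null(seed)) set.seed(seed)
  ns <- n_sites(vt); nsam <- n_samples(vt)
  ncall <- ns * nsam
  gt <- vt$gt; dp <- vt$dp; gq <- vt$gq
  if (ncall > 0) {
    k <- round(noise$frac_missing * ncall)
    if (k > 0) {
      idx <- sample.int(ncall, k)
      gt[idx] <- NA_integer_; dp[idx] <- NA_real_; gq[idx] <- NA_real_
    }
    k <- round(noise$frac_bad_dp * ncall)
    if (k > 0) {
      idx <- sample.int(ncall, k)
      dp[idx] <- sample(c(1:9, 51:80), k, replace = TRUE)
    }
    k <- round(noise$frac_low_gq * ncall)
    if (k > 0) {
      idx <- sample.int(ncall, k)
      gq[idx] <- sample(0:29, k, replace = TRUE)
    }
    if (noise$n_low_maf > 0 && ns > 0) {
      idx <- sample.int(ns, min(noise$n_low_maf, ns))
      for (i in idx) {
        gt[i, ] <- 0L
        gt[i, sample.int(nsam, 1)] <- 1L
        dp[i, ] <- sample(10:50, nsam, replace = TRUE)
        gq[i, ] <- sample(30:99, nsam, replace = TRUE)
      }
    }
  }
  out <- vt
  out$gt <- gt; out$dp <- dp; out$gq <- gq

  # ground-truth bookkeeping: apply each rule's definition directly
  eff_missing <- is.na(gt) | (!is.na(gq) & gq < cfg$min_gq)
  miss_frac <- rowMeans(eff_missing)
  mdp <- rowMeans(ifelse(eff_missing, NA, dp), na.rm = TRUE)
  ac <- rowSums(ifelse(eff_missing, NA, gt), na.rm = TRUE)
  an <- 2 * rowSums(!eff_missing)
  p <- ifelse(an > 0, ac / an, NA_real_)
  maf <- pmin(p, 1 - p)
  fail_missing <- miss_frac > cfg$max_missing_frac
  fail_dp <- !is.finite(mdp) | mdp < cfg$min_mean_dp | mdp > cfg$max_mean_dp
  fail_maf <- !is.finite(maf) | maf < cfg$min_maf
  truth <- data.frame(chrom = vt$sites$chrom, pos = vt$sites$pos,
                      fail_missing = fail_missing, fail_dp = fail_dp,
                      fail_maf = fail_maf,
                      survives = !(fail_missing | fail_dp | fail_maf),
                      stringsAsFactors = FALSE)
  list(vt = out, truth = truth)
}

# non-stop invariant filler codons (no degenerate planting semantics)
filler_codons <- function(n) {
  pool <- c("ATG", "TGG", "GAT", "CAT", "AAC", "TTC", "ATC", "GAG")
  sample(pool, n, replace = TRUE)
}

#' Build a coding-gene fixture with planted MKT counts
#'
#' Constructs `n_genes` single-exon protein-coding genes with exactly the
#' requested numbers of non-synonymous / synonymous fixed differences and
#' polymorphisms between and within two species, each planted in its own
#' codon (one variable position per codon, so the synonymous /
#' non-synonymous classification is unambiguous):
#'
#' * synonymous changes use a fourfold-family third position (GGA vs GGT);
#' * non-synonymous changes use AAA (Lys) vs GAA (Glu);
#' * polymorphic codons segregate at frequency 1/2 within one species
#'   (alternating species across planted codons) while the other species
#'   is fixed for the shared allele.
#'
#' Genes alternate between the + and - strand; the reference carries the
#' species-1 consensus. Intergenic spacers are random sequence.
#'
#' @param counts data.frame (or matrix) with columns `Dn`, `Ds`, `Pn`,
#'   `Ps`, one row per gene.
#' @param n_hap haplotypes per species (even, >= 2).
#' @param min_codons minimum gene length in codons (padding is added with
#'   invariant filler codons).
#' @param intergenic spacer length between genes in bp.
#' @param seed integer seed.
#' @return list with `ref` (named `DNAStringSet`, one chromosome), `cds`
#'   (CDS table as used by [fourfold_degenerate_sites()]), `alignments`
#'   (list of [gene_alignment()]), and `truth` (the planted counts with
#'   gene coordinates).
#' @export
make_coding_fixture <- function(counts, n_hap = 4, min_codons = 10,
                                intergenic = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  counts <- as.data.frame(counts)
  stopifnot(all(c("Dn", "Ds", "Pn", "Ps") %in% names(counts)),
            n_hap >= 2, n_hap %% 2 == 0)
  n_genes <- nrow(counts)
  bases <- c("A", "C", "G", "T")
  n_a <- ceiling(n_hap / 2)  # haplotypes per species in allele class a / b
  n_b <- n_hap - n_a

  ref_parts <- character(0)
  cds_rows <- list(); aln <- list(); truth_rows <- list()
  cursor <- 0L  # 0-based chromosome offset
  for (gidx in seq_len(n_genes)) {
    ct <- counts[gidx, ]
    n_planted <- ct$Dn + ct$Ds + ct$Pn + ct$Ps
    ncod <- max(min_codons, n_planted + 1L)
    # per-codon templates: one row per haplotype class (sp1-a, sp1-b,
    # sp2-a, sp2-b); polymorphic codons split a species into a/b halves
    kinds <- c(rep("Dn", ct$Dn), rep("Ds", ct$Ds),
               rep("Pn", ct$Pn), rep("Ps", ct$Ps),
               rep("fill", ncod - 1L - n_planted))
    kinds <- c("start", sample(kinds))
    poly_in_sp1 <- TRUE  # alternate the polymorphic species
    cod <- matrix("", nrow = 4, ncol = ncod)
    for (ci in seq_along(kinds)) {
      k <- kinds[ci]
      if (k == "start") {
        cod[, ci] <- "ATG"
      } else if (k == "fill") {
        cod[, ci] <- filler_codons(1)
      } else if (k == "Ds") {
        cod[, ci] <- c("GGA", "GGA", "GGT", "GGT")
      } else if (k == "Dn") {
        cod[, ci] <- c("AAA", "AAA", "GAA", "GAA")
      } else if (k == "Ps") {
        cod[, ci] <- if (poly_in_sp1) c("GGA", "GGT", "GGA", "GGA")
          else c("GGA", "GGA", "GGA", "GGT")
        poly_in_sp1 <- !poly_in_sp1
      } else if (k == "Pn") {
        cod[, ci] <- if (poly_in_sp1) c("AAA", "GAA", "AAA", "AAA")
          else c("AAA", "AAA", "AAA", "GAA")
        poly_in_sp1 <- !poly_in_sp1
      }
    }
    hap_class <- apply(cod, 1, paste0, collapse = "")
    haps <- c(rep(hap_class[1], n_a), rep(hap_class[2], n_b),
              rep(hap_class[3], n_a), rep(hap_class[4], n_b))
    species <- rep(c("sp1", "sp2"), each = n_hap)
    strand <- if (gidx %% 2 == 1) "+" else "-"

    spacer <- paste0(sample(bases, intergenic, replace = TRUE),
                     collapse = "")
    cds_seq <- hap_class[1]  # reference = first sp1 haplotype
    gene_ref <- if (strand == "+") cds_seq else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(cds_seq)))
    gstart <- as.integer(cursor + intergenic + 1L)  # 1-based
    gend <- as.integer(gstart + nchar(cds_seq) - 1L)
    ref_parts <- c(ref_parts, spacer, gene_ref)
    cursor <- cursor + intergenic + nchar(cds_seq)

    gene_id <- sprintf("gene%03d", gidx)
    cds_rows[[gidx]] <- data.frame(chrom = "chrA", start = gstart,
                                   end = gend, strand = strand,
                                   phase = 0L, gene = gene_id,
                                   stringsAsFactors = FALSE)
    aln[[gene_id]] <- gene_alignment(gene_id, haps, species,
                                     chrom = "chrA", start = gstart,
                                     end = gend, strand = strand)
    truth_rows[[gidx]] <- data.frame(gene = gene_id, chrom = "chrA",
                                     start = gstart, end = gend,
                                     strand = strand, Dn = ct$Dn,
                                     Ds = ct$Ds, Pn = ct$Pn, Ps = ct$Ps,
                                     stringsAsFactors = FALSE)
  }
  tail_spacer <- paste0(sample(bases, intergenic, replace = TRUE),
                        collapse = "")
  ref <- Biostrings::DNAStringSet(
    stats::setNames(paste0(c(ref_parts, tail_spacer), collapse = ""), "chrA"))
  list(ref = ref,
       cds = do.call(rbind, cds_rows),
       alignments = aln,
       truth = do.call(rbind, truth_rows))
}

#' Write fixture components to standard plain-text formats
#'
#' Writes the reference as FASTA, the CDS table as GFF3 (gene + CDS
#' features, 1-based inclusive), and a truth sidecar as JSON.
#'
#' @param fixture a list as returned by [make_coding_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_coding_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  gff <- file.path(dir, "annotation.gff3")
  tr <- file.path(dir, "truth.json")
  Biostrings::writeXStringSet(fixture$ref, fa)
  write_gff3(fixture$cds, gff)
  jsonlite::write_json(fixture$truth, tr, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, truth = tr))
}

#' Write a CDS table as GFF3
#'
#' @param cds data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `phase`, `gene`.
#' @param path output path.
#' @export
write_gff3 <- function(cds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gene in unique(cds$gene)) {
    segs <- cds[cds$gene == gene, , drop = FALSE]
    writeLines(sprintf("%s\tdivflow\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       segs$chrom[1], min(segs$start), max(segs$end),
                       segs$strand[1], gene), con)
    for (i in seq_len(nrow(segs))) {
      writeLines(sprintf(
        "%s\tdivflow\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds-%s;Parent=%s",
        segs$chrom[i], segs$start[i], segs$end[i], segs$strand[i],
        segs$phase[i], gene, gene), con)
    }
  }
  invisible(path)
}

#' Read / write a truth sidecar
#' @param truth a data.frame.
#' @param path file path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
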