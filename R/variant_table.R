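#' Biallelic variant table
#'
#' The package's in-memory representation of a multi-sample set of
#' biallelic SNPs: per-site metadata, and per-call genotype dosage, read
#' depth and genotype quality matrices, plus a sample-to-species map.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; positions must be strictly increasing within each chromosome.
#' @param gt integer matrix, sites x samples, alt-allele dosage in
#'   `{0, 1, 2}` with `NA` for missing calls.
#' @param dp,gq numeric matrices (same shape): per-call read depth and
#'   phred-scaled genotype quality. `NA` allowed where the call is missing.
#' @param samples data.frame with columns `id` and `pop`; `pop` must take
#'   exactly one or two distinct values (the two species).
#' @return an object of class `"variant_table"`.
#' @export
variant_table <- function(sites, gt, dp = NULL, gq = NULL, samples) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            is.matrix(gt), nrow(gt) == nrow(sites),
            is.data.frame(samples),
            all(c("id", "pop") %in% names(samples)),
            ncol(gt) == nrow(samples))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("positions not strictly increasing on ", ch)
  }
  if (length(unique(samples$pop)) > 2)
    stop("at most two population labels supported")
  if (is.null(dp)) dp <- matrix(NA_real_, nrow(gt), ncol(gt))
  if (is.null(gq)) gq <- matrix(NA_real_, nrow(gt), ncol(gt))
  stopifnot(all(dim(dp) == dim(gt)), all(dim(gq) == dim(gt)))
  storage.mode(gt) <- "integer"
  colnames(gt) <- colnames(dp) <- colnames(gq) <- samples$id
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = samples),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d sites x %d samples (%s)\n",
              n_sites(x), n_samples(x),
              paste(sprintf("%s: %d", names(table(x$samples$pop)),
                            as.integer(table(x$samples$pop))),
                    collapse = ", ")))
  invisible(x)
}

#' @rdname variant_table
#' @param vt a `"variant_table"`.
#' @export
n_sites <- function(vt) nrow(vt$sites)

#' @rdname variant_table
#' @export
n_samples <- function(vt) nrow(vt$samples)

#' Subset a variant table by site index or by (chrom, pos) pairs
#'
#' @param vt a [variant_table()].
#' @param i integer/logical site index, or a data.frame with `chrom` and
#'   `pos` columns selecting sites by coordinate.
#' @return the subset `"variant_table"` (site order preserved).
#' @export
subset_sites <- function(vt, i) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.data.frame(i)) {
    key <- paste(vt$sites$chrom, vt$sites$pos)
    i <- which(key %in% paste(i$chrom, i$pos))
  }
  variant_table(vt$sites[i, , drop = FALSE],
                vt$gt[i, , drop = FALSE],
                vt$dp[i, , drop = FALSE],
                vt$gq[i, , drop = FALSE],
                vt$samples)
}

#' Subset a variant table by sample id
#'
#' @param vt a [variant_table()].
#' @param ids character vector of sample ids (all must be present), or an
#'   integer vector of sample indices.
#' @return the subset `"variant_table"`.
#' @export
subset_samples <- function(vt, ids) {
  stopifnot(inherits(vt, "variant_table"))
  if (is.character(ids)) {
    j <- match(ids, vt$samples$id)
    if (anyNA(j)) stop("unknown sample id(s): ",
                       paste(ids[is.na(j)], collapse = ", "))
  } else {
    j <- ids
  }
  variant_table(vt$sites,
                vt$gt[, j, drop = FALSE],
                vt$dp[, j, drop = FALSE],
                vt$gq[, j, drop = FALSE],
                vt$samples[j, , drop = FALSE])
}

#' Draw a seeded random subset of individuals per species
#'
#' @param vt a [variant_table()].
#' @param k individuals to keep per species.
#' @param seed optional integer seed for a reproducible draw.
#' @return the subset `"variant_table"`.
#' @export
sample_individuals <- function(vt, k, seed = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  if (!is.null(seed)) set.seed(seed)
  keep <- unlist(lapply(split(seq_len(n_samples(vt)), vt$samples$pop),
                        function(idx) {
                          if (length(idx) < k)
                            stop("fewer than k individuals in a species")
                          sort(sample(idx, k))
                        }), use.names = FALSE)
  subset_samples(vt, sort(keep))
}

#' Write a variant table as VCF 4.2
#'
#' Plain-text VCF with `GT:DP:GQ` per call; missing calls are `./.:.:.`.
#' The sample-to-species map is not part of VCF and is written separately
#' by [write_popmap()].
#'
#' @param vt a [variant_table()].
#' @param path output path (plain text; compress externally if wanted).
#' @export
write_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=divflow",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples$id), collapse = "\t")
  ), con)
  if (n_sites(vt) > 0) {
    gt_str <- matrix(c("0/0", "0/1", "1/1")[vt$gt + 1L],
                     nrow(vt$gt), ncol(vt$gt))
    gt_str[is.na(vt$gt)] <- "./."
    dp_str <- ifelse(is.na(vt$dp), ".", format(vt$dp, trim = TRUE))
    gq_str <- ifelse(is.na(vt$gq), ".", format(vt$gq, trim = TRUE))
    calls <- matrix(paste(gt_str, dp_str, gq_str, sep = ":"),
                    nrow(vt$gt), ncol(vt$gt))
    body <- paste(vt$sites$chrom, vt$sites$pos, ".", vt$sites$ref,
                  vt$sites$alt, ".", "PASS", ".", "GT:DP:GQ",
                  apply(calls, 1, paste, collapse = "\t"),
                  sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Uses `vcfR` to parse VCF 4.x (plain or gzipped). Only biallelic SNP
#' records are kept; a warning reports how many records were dropped.
#'
#' @param path VCF path.
#' @param popmap data.frame with columns `id`, `pop` (see
#'   [read_popmap()]); samples absent from the map get pop `NA`.
#' @return a [variant_table()].
#' @export
read_vcf <- function(path, popmap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!keep))
    warning(sum(!keep), " non-biallelic-SNP record(s) dropped")
  v <- v[keep, ]
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  dosage <- function(x) {
    out <- rep(NA_integer_, length(x))
    x <- gsub("\\|", "/", x)
    out[x %in% c("0/0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1")] <- 2L
    out
  }
  gt <- matrix(dosage(gt_raw), nrow(gt_raw), ncol(gt_raw))
  dp <- suppressWarnings(
    matrix(as.numeric(vcfR::extract.gt(v, element = "DP")),
           nrow(gt_raw), ncol(gt_raw)))
  gq <- suppressWarnings(
    matrix(as.numeric(vcfR::extract.gt(v, element = "GQ")),
           nrow(gt_raw), ncol(gt_raw)))
  ids <- colnames(gt_raw)
  pops <- if (is.null(popmap)) rep("sp1", length(ids)) else
    popmap$pop[match(ids, popmap$id)]
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = fix$ALT,
                      stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  variant_table(sites[ord, , drop = FALSE], gt[ord, , drop = FALSE],
                dp[ord, , drop = FALSE], gq[ord, , drop = FALSE],
                data.frame(id = ids, pop = pops, stringsAsFactors = FALSE))
}

#' Write / read a two-column sample-to-species map (TSV: id, pop)
#' @param vt a [variant_table()].
#' @param path file path.
#' @export
write_popmap <- function(vt, path) {
  utils::write.table(vt$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_popmap
#' @export
read_popmap <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# split sample indices by species label, in a stable order
pop_indices <- function(vt) {
  pops <- sort(unique(vt$samples$pop))
  lapply(stats::setNames(pops, pops),
         function(p) which(vt$samples$pop == p))
}

# per-site alt-allele count and non-missing allele number for a set of
# sample columns
allele_counts <- function(gt, cols) {
  sub <- gt[, cols, drop = FALSE]
  ac <- rowSums(sub, na.rm = TRUE)
  an <- 2L * rowSums(!is.na(sub))
  cbind(ac = ac, an = an)
}
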