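#' Observed joint site-frequency spectrum from a variant table
#'
#' Tabulates the two-species joint SFS at haploid resolution `2k + 1` per
#' species, from a (typically filtered, LD-pruned, fourfold-restricted)
#' variant table. Two down-sampling modes are available when the table
#' holds more than `k` individuals per species:
#'
#' * `"subsample"`: a seeded draw of `k` individuals per species; sites
#'   with any missing call in the subsample are dropped.
#' * `"projection"`: hypergeometric down-projection — each site's allele
#'   counts are projected to `2k` alleles per species, spreading one unit
#'   of mass over cells with exact hypergeometric weights; sites with
#'   fewer than `2k` non-missing alleles in either species are dropped.
#'
#' The alt allele is taken as derived (true in synthetic mode, where the
#' reference is the ancestral state); set `fold = TRUE` when polarization
#' is unknown.
#'
#' @param vt a [variant_table()] with two species labels.
#' @param k diploid individuals per species in the output spectrum.
#' @param mode `"subsample"` or `"projection"`.
#' @param fold return the minor-allele (folded) spectrum.
#' @param seed seed for the subsample draw.
#' @return a `"joint_sfs"` (counts; fractional under projection).
#' @export
observed_joint_sfs <- function(vt, k = 6, mode = c("subsample", "projection"),
                               fold = FALSE, seed = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  mode <- match.arg(mode)
  pops <- pop_indices(vt)
  if (length(pops) != 2) stop("two species labels required")
  m <- matrix(0, 2 * k + 1, 2 * k + 1)

  if (mode == "subsample") {
    ks <- vapply(pops, length, integer(1))
    if (any(ks < k)) stop("fewer than k individuals in a species")
    sub <- if (all(ks == k)) vt else sample_individuals(vt, k, seed = seed)
    pops <- pop_indices(sub)
    complete <- rowSums(is.na(sub$gt)) == 0
    a1 <- rowSums(sub$gt[, pops[[1]], drop = FALSE])
    a2 <- rowSums(sub$gt[, pops[[2]], drop = FALSE])
    for (i in which(complete)) m[a1[i] + 1L, a2[i] + 1L] <-
        m[a1[i] + 1L, a2[i] + 1L] + 1
  } else {
    cnt1 <- allele_counts(vt$gt, pops[[1]])
    cnt2 <- allele_counts(vt$gt, pops[[2]])
    usable <- cnt1[, "an"] >= 2 * k & cnt2[, "an"] >= 2 * k
    for (i in which(usable)) {
      w1 <- stats::dhyper(0:(2 * k), cnt1[i, "ac"],
                          cnt1[i, "an"] - cnt1[i, "ac"], 2 * k)
      w2 <- stats::dhyper(0:(2 * k), cnt2[i, "ac"],
                          cnt2[i, "an"] - cnt2[i, "ac"], 2 * k)
      m <- m + outer(w1, w2)
    }
  }
  # monomorphic projections land in the corner cells; the SFS holds
  # segregating sites only
  m[1, 1] <- 0
  m[2 * k + 1, 2 * k + 1] <- 0
  out <- joint_sfs(m, folded = FALSE, seed = seed)
  if (fold) fold_sfs(out) else out
}

#' Parameter priors for the ABC reference table
#'
#' Each of `N1`, `N2`, `N_anc` and `m` gets a distribution: `"uniform"`,
#' `"loguniform"`, or `"fixed"` (bounds equal). `T_split` may be fixed or
#' bounded. The defaults (log-uniform sizes 1e4-1e7, uniform migration
#' 0-1e-4, split fixed at 1e6 generations) are this package's documented
#' choices — wide, weakly informative ranges for invertebrate genomes;
#' no priors are prescribed by the study design itself.
#'
#' @param N1,N2,N_anc,m,T_split each a list `list(dist =, min =, max =)`
#'   or a single number (treated as fixed).
#' @return an object of class `"prior_spec"`.
#' @export
prior_spec <- function(N1 = list(dist = "loguniform", min = 1e4, max = 1e7),
                       N2 = list(dist = "loguniform", min = 1e4, max = 1e7),
                       N_anc = list(dist = "loguniform", min = 1e4, max = 1e7),
                       m = list(dist = "uniform", min = 0, max = 1e-4),
                       T_split = 1e6) {
  norm <- function(x) {
    if (is.numeric(x) && length(x) == 1)
      x <- list(dist = "fixed", min = x, max = x)
    stopifnot(x$dist %in% c("uniform", "loguniform", "fixed"),
              x$min <= x$max)
    if (x$dist == "loguniform") stopifnot(x$min > 0)
    x
  }
  structure(list(N1 = norm(N1), N2 = norm(N2), N_anc = norm(N_anc),
                 m = norm(m), T_split = norm(T_split)),
            class = "prior_spec")
}

draw_prior <- function(p, n = 1) {
  switch(p$dist,
         fixed = rep(p$min, n),
         uniform = stats::runif(n, p$min, p$max),
         loguniform = exp(stats::runif(n, log(p$min), log(p$max))))
}

#' Simulate an ABC reference table under a set of scenarios
#'
#' For each scenario label, draws `n_sims_per_model` parameter vectors
#' from the priors, simulates the joint SFS under the corresponding
#' [make_model()] preset, and stores the mass-normalized SFS (corner
#' cells excluded) together with the parameters.
#'
#' @param models character vector of scenario labels (subset of M1-M5).
#' @param priors a [prior_spec()].
#' @param n_sims_per_model simulations per scenario.
#' @param cfg a [sim_config()] (its `n1`, `n2`, `mu`, `locus_length`,
#'   `n_loci` define every simulation; its seed is ignored here).
#' @param fold simulate folded spectra.
#' @param seed integer seed for the whole table.
#' @return a `"abc_reference"` object: `params` data.frame (model, N1,
#'   N2, N_anc, m, T_split, n_sites) and `sfs` matrix (rows = sims,
#'   columns = normalized non-corner SFS cells).
#' @export
simulate_reference_table <- function(models, priors, n_sims_per_model, cfg,
                                     fold = TRUE, seed = NULL) {
  stopifnot(inherits(priors, "prior_spec"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  rows <- list(); vecs <- list(); r <- 0L
  for (lab in models) {
    for (s in seq_len(n_sims_per_model)) {
      th <- list(N1 = draw_prior(priors$N1), N2 = draw_prior(priors$N2),
                 N_anc = draw_prior(priors$N_anc), m = draw_prior(priors$m),
                 T_split = draw_prior(priors$T_split))
      model <- make_model(lab, T_split = th$T_split, N1 = th$N1, N2 = th$N2,
                          N_anc = th$N_anc, m = th$m)
      sfs <- cpp_sim_joint_sfs(cfg$n1, cfg$n2, model$N1, model$N2,
                               model$N_anc, model$T_split,
                               epochs_matrix(model), cfg$mu,
                               cfg$locus_length, cfg$n_loci)
      sfs <- joint_sfs(sfs, folded = FALSE)
      if (fold) sfs <- fold_sfs(sfs)
      r <- r + 1L
      rows[[r]] <- data.frame(model = lab, N1 = th$N1, N2 = th$N2,
                              N_anc = th$N_anc, m = th$m,
                              T_split = th$T_split, n_sites = sum(sfs))
      vecs[[r]] <- sfs_distance_vector(sfs)
    }
  }
  structure(list(params = do.call(rbind, rows),
                 sfs = do.call(rbind, vecs),
                 folded = fold, n1 = cfg$n1, n2 = cfg$n2, seed = seed),
            class = "abc_reference")
}

# normalized SFS as a vector, excluding the two monomorphic corner cells
sfs_distance_vector <- function(sfs) {
  v <- as.vector(unclass(sfs))
  n1 <- attr(sfs, "n1"); n2 <- attr(sfs, "n2")
  corner <- c(1L, (n1 + 1L) * (n2 + 1L))
  v <- v[-corner]
  tot <- sum(v)
  if (tot > 0) v / tot else v
}

#' Rejection-ABC model selection on the joint SFS
#'
#' Computes the Euclidean distance between the observed and every
#' reference mass-normalized SFS (corner cells excluded), accepts the
#' `round(tolerance * N)` smallest distances over the pooled table, and
#' reports each scenario's share of the accepted set — the "proportion of
#' accepted simulations" presentation of ABC model choice.
#'
#' @param obs a `"joint_sfs"` with the same dimensions and polarization as
#'   the reference table.
#' @param ref an `"abc_reference"` from [simulate_reference_table()].
#' @param tolerance accepted fraction of the pooled table, in (0, 1].
#' @return an `"abc_result"`: `proportions` (named, sums to 1), `counts`,
#'   `n_total`, `accepted` (data.frame of accepted draws with parameters
#'   and distances), `tolerance`.
#' @export
abc_model_select <- function(obs, ref, tolerance = 0.005) {
  stopifnot(inherits(obs, "joint_sfs"), inherits(ref, "abc_reference"))
  if (tolerance <= 0 || tolerance > 1) stop("tolerance outside (0, 1]")
  if (attr(obs, "n1") != ref$n1 || attr(obs, "n2") != ref$n2)
    stop("observed and reference SFS dimensions differ")
  if (!identical(attr(obs, "folded"), ref$folded))
    stop("observed and reference SFS polarization differ")
  ov <- sfs_distance_vector(obs)
  d <- sqrt(rowSums(sweep(ref$sfs, 2, ov)^2))
  n_acc <- max(1L, round(tolerance * length(d)))
  acc_idx <- order(d)[seq_len(n_acc)]
  acc <- ref$params[acc_idx, , drop = FALSE]
  acc$distance <- d[acc_idx]
  labs <- unique(ref$params$model)
  counts <- vapply(labs, function(l) sum(acc$model == l), integer(1))
  structure(list(proportions = counts / n_acc, counts = counts,
                 n_total = length(d), accepted = acc,
                 tolerance = tolerance),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf("ABC rejection model selection: %d accepted of %d (tol %g)\n",
              nrow(x$accepted), x$n_total, x$tolerance))
  pr <- sort(x$proportions, decreasing = TRUE)
  cat(paste(sprintf("%s (%.1f%%)", names(pr), 100 * pr), collapse = " > "),
      "\n")
  invisible(x)
}

#' Posterior summaries of accepted parameter draws for one scenario
#'
#' Standard rejection-ABC posterior: summaries are taken over the accepted
#' draws of the requested scenario only.
#'
#' @param res an `"abc_result"`.
#' @param model scenario label.
#' @param level credible-interval level (equal-tailed quantiles).
#' @return data.frame with one row per parameter: mean, median, lower,
#'   upper.
#' @export
abc_posterior <- function(res, model, level = 0.95) {
  stopifnot(inherits(res, "abc_result"))
  acc <- res$accepted[res$accepted$model == model, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted draws for model ", model)
  pars <- c("N1", "N2", "N_anc", "m", "T_split")
  a <- (1 - level) / 2
  do.call(rbind, lapply(pars, function(p) {
    x <- acc[[p]]
    data.frame(parameter = p, n = length(x), mean = mean(x),
               median = stats::median(x),
               lower = unname(stats::quantile(x, a)),
               upper = unname(stats::quantile(x, 1 - a)))
  }))
}
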