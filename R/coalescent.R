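#' @useDynLib divflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Migration epoch for a two-deme demographic model
#'
#' An interval of time, measured backward from the present in generations,
#' during which lineages migrate between the two demes at constant
#' per-lineage backward rates.
#'
#' @param t_start,t_end epoch bounds in generations before present,
#'   `0 <= t_start < t_end`.
#' @param m12 per-lineage per-generation backward migration rate for
#'   lineages currently in deme 1 (they jump to deme 2 when tracing their
#'   ancestry backward).
#' @param m21 likewise for lineages in deme 2.
#' @return an object of class `"migration_epoch"`.
#' @export
migration_epoch <- function(t_start, t_end, m12, m21 = m12) {
  stopifnot(is.numeric(t_start), is.numeric(t_end),
            t_start >= 0, t_start < t_end, m12 >= 0, m21 >= 0)
  structure(list(t_start = t_start, t_end = t_end, m12 = m12, m21 = m21),
            class = "migration_epoch")
}

#' Two-deme divergence model
#'
#' A demographic model for a pair of sister species: an ancestral
#' population of diploid size `N_anc` splits `T_split` generations ago into
#' deme 1 (size `N1`) and deme 2 (size `N2`), with optional migration
#' epochs between the split and the present.
#'
#' @param T_split split time in generations before present (> 0).
#' @param N1,N2,N_anc diploid effective sizes (> 0).
#' @param epochs list of [migration_epoch()] objects; must be
#'   non-overlapping and contained in `[0, T_split]`.
#' @param label a scenario name; `"custom"` for free-form models.
#' @return an object of class `"demographic_model"`.
#' @seealso [make_model()] for the five preset divergence scenarios.
#' @export
demographic_model <- function(T_split, N1, N2, N_anc, epochs = list(),
                              label = "custom") {
  stopifnot(T_split > 0, N1 > 0, N2 > 0, N_anc > 0)
  for (e in epochs) {
    if (!inherits(e, "migration_epoch"))
      stop("epochs must be migration_epoch objects")
    if (e$t_end > T_split)
      stop("migration epoch [", e$t_start, ", ", e$t_end,
           "] extends beyond T_split = ", T_split)
  }
  if (length(epochs) > 1) {
    ord <- order(vapply(epochs, `[[`, numeric(1), "t_start"))
    epochs <- epochs[ord]
    for (i in seq_len(length(epochs) - 1L)) {
      if (epochs[[i]]$t_end > epochs[[i + 1L]]$t_start)
        stop("migration epochs overlap")
    }
  }
  structure(list(label = label, T_split = T_split, N1 = N1, N2 = N2,
                 N_anc = N_anc, epochs = epochs),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Two-deme divergence model [", x$label, "]\n", sep = "")
  cat("  T_split:", format(x$T_split, big.mark = " "), "generations\n")
  cat("  N1:", x$N1, " N2:", x$N2, " N_anc:", x$N_anc, "(diploid)\n")
  if (length(x$epochs) == 0) {
    cat("  no migration (complete isolation)\n")
  } else {
    for (e in x$epochs)
      cat(sprintf("  gene flow %g-%g gen BP: m12=%g m21=%g\n",
                  e$t_start, e$t_end, e$m12, e$m21))
  }
  invisible(x)
}

#' Preset divergence scenarios M1-M5
#'
#' Builds one of the five canonical divergence-with-gene-flow scenarios for
#' a 1 Ma species split (times are configurable; epoch bounds are fixed by
#' the scenario definitions, in generations, assuming one generation per
#' year):
#'
#' * `M1` - complete isolation, no post-split gene flow.
#' * `M2` - gene flow from the split until ~200 kya, then isolation.
#' * `M3` - secondary contact during the last glaciation (100-10 kya).
#' * `M4` - secondary contact during the last warm phase (150-100 kya).
#' * `M5` - continuous gene flow from the split until ~10 kya.
#'
#' Preset gene flow is symmetric (`m12 = m21 = m`); use
#' [demographic_model()] directly for asymmetric rates.
#'
#' @param label one of `"M1" ... "M5"`.
#' @param T_split split time in generations (default 1e6).
#' @param N1,N2,N_anc diploid effective sizes.
#' @param m symmetric per-lineage backward migration rate per generation
#'   used inside the scenario's gene-flow epoch (ignored for M1).
#' @return a [demographic_model()].
#' @export
make_model <- function(label, T_split = 1e6, N1, N2, N_anc, m = 0) {
  stopifnot(T_split > 0, m >= 0)
  if (!label %in% paste0("M", 1:5))
    stop("unknown scenario label: ", label)
  need <- c(M1 = 0, M2 = 200000, M3 = 100000, M4 = 150000, M5 = 10000)
  if (T_split <= need[label])
    stop(label, " requires T_split > ", need[label], " generations")
  epochs <- switch(label,
    M1 = list(),
    M2 = list(migration_epoch(200000, T_split, m)),
    M3 = list(migration_epoch(10000, 100000, m)),
    M4 = list(migration_epoch(100000, 150000, m)),
    M5 = list(migration_epoch(10000, T_split, m))
  )
  demographic_model(T_split, N1, N2, N_anc, epochs, label = label)
}

epochs_matrix <- function(model) {
  if (length(model$epochs) == 0) {
    matrix(numeric(0), ncol = 4)
  } else {
    do.call(rbind, lapply(model$epochs, function(e)
      c(e$t_start, e$t_end, e$m12, e$m21)))
  }
}

#' Simulation configuration
#'
#' @param n1,n2 haploid sample sizes per deme; must be even so lineages can
#'   be paired into diploid individuals downstream (two consecutive
#'   lineages form one individual).
#' @param mu mutation rate per bp per generation.
#' @param locus_length locus length in bp.
#' @param n_loci number of independent loci (free recombination between
#'   loci, none within).
#' @param seed optional integer seed recorded in outputs; when non-NULL,
#'   simulation entry points call `set.seed(seed)`.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n1 = 12, n2 = 12, mu = 1e-8, locus_length = 1000,
                       n_loci = 100, seed = NULL) {
  stopifnot(n1 >= 2, n2 >= 2, n1 %% 2 == 0, n2 %% 2 == 0,
            mu >= 0, locus_length >= 1, n_loci >= 0)
  structure(list(n1 = n1, n2 = n2, mu = mu, locus_length = locus_length,
                 n_loci = n_loci, seed = seed),
            class = "sim_config")
}

#' Simulate one genealogy under the structured coalescent
#'
#' Backward-in-time simulation: within deme `i`, each pair of lineages
#' coalesces at rate `1/(2 N_i)` per generation; during a migration epoch
#' each lineage leaves its deme at the epoch's backward rate; at `T_split`
#' all lineages merge into the ancestral deme of size `N_anc`. Waiting
#' times are exponential and re-drawn at every epoch/split boundary.
#'
#' @param model a [demographic_model()].
#' @param n1,n2 haploid sample sizes (>= 1) in demes 1 and 2.
#' @return an object of class `"genealogy"`: node `time`s (generations,
#'   leaves at 0), 1-based `parent` pointers (NA at the root), the `deme`
#'   of each leaf (1 or 2) and of each coalescence (1, 2, or 3 for the
#'   ancestral deme), and `n1`, `n2`.
#' @export
simulate_genealogy <- function(model, n1, n2) {
  stopifnot(inherits(model, "demographic_model"), n1 >= 1, n2 >= 1)
  g <- cpp_sim_genealogy(as.integer(n1), as.integer(n2), model$N1, model$N2,
                         model$N_anc, model$T_split, epochs_matrix(model))
  g$deme <- g$deme + 1L
  n_coal <- sum(!is.na(g$parent)) # every non-root node has a parent;
  stopifnot(n_coal == 2L * (n1 + n2) - 2L)
  class(g) <- "genealogy"
  g
}

#' Time to the most recent common ancestor of a genealogy
#' @param g a `"genealogy"`.
#' @return root time in generations.
#' @export
tmrca <- function(g) max(g$time)

#' Total branch length of a genealogy in generations
#' @param g a `"genealogy"`.
#' @export
total_branch_length <- function(g) {
  has_parent <- !is.na(g$parent)
  sum(g$time[g$parent[has_parent]] - g$time[has_parent])
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' The number of mutations is Poisson with mean `mu * L * total branch
#' length`; each mutation lands on a branch with probability proportional
#' to its length and defines one biallelic site whose derived allele is
#' carried by the leaves below that branch.
#'
#' @param g a `"genealogy"`.
#' @param mu mutation rate per bp per generation.
#' @param L locus length in bp.
#' @param detail if `TRUE`, also return the branch (node index) carrying
#'   each mutation, for genotype construction.
#' @return a matrix with one row per site and columns `d1`, `d2`: the
#'   derived-allele counts among the deme-1 and deme-2 leaves (plus
#'   `branch` if `detail`). Counts 0 and `n1 + n2` never occur.
#' @export
drop_mutations <- function(g, mu, L, detail = FALSE) {
  stopifnot(inherits(g, "genealogy"), mu >= 0, L >= 0)
  m <- cpp_drop_mutations(g$n1, g$n2, g$time, g$parent, mu, L)
  colnames(m) <- c("d1", "d2", "branch")
  if (!detail) m <- m[, c("d1", "d2"), drop = FALSE]
  m
}

#' Simulate the joint site-frequency spectrum under a divergence model
#'
#' Aggregates infinite-sites mutations over `cfg$n_loci` independent
#' genealogies into an `(n1 + 1) x (n2 + 1)` count matrix indexed by the
#' derived-allele count in each deme (haploid resolution, unfolded; the
#' reference/ancestral state is known in simulation). Use [fold_sfs()] for
#' the minor-allele (folded) spectrum.
#'
#' @param model a [demographic_model()].
#' @param cfg a [sim_config()].
#' @return a `"joint_sfs"` object: the count matrix with attributes
#'   `folded = FALSE`, `n1`, `n2`, and the generating seed (if any).
#' @export
simulate_joint_sfs <- function(model, cfg) {
  stopifnot(inherits(model, "demographic_model"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- cpp_sim_joint_sfs(cfg$n1, cfg$n2, model$N1, model$N2, model$N_anc,
                         model$T_split, epochs_matrix(model),
                         cfg$mu, cfg$locus_length, cfg$n_loci)
  joint_sfs(m, folded = FALSE, seed = cfg$seed)
}

#' Construct a joint SFS object
#'
#' @param m an `(n1 + 1) x (n2 + 1)` non-negative matrix of site counts,
#'   rows indexed by the allele count 0..n1 in species 1.
#' @param folded logical: minor-allele (folded) or derived-allele
#'   (unfolded) polarization.
#' @param seed optional generating seed, carried as an attribute.
#' @return a `"joint_sfs"` object.
#' @export
joint_sfs <- function(m, folded = FALSE, seed = NULL) {
  stopifnot(is.matrix(m), all(m >= 0))
  dimnames(m) <- list(0:(nrow(m) - 1L), 0:(ncol(m) - 1L))
  structure(m, folded = folded, n1 = nrow(m) - 1L, n2 = ncol(m) - 1L,
            seed = seed, class = c("joint_sfs", "matrix"))
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("Joint SFS (%s), %d x %d, %s segregating sites\n",
              if (attr(x, "folded")) "folded" else "unfolded",
              nrow(x), ncol(x),
              format(sum(x), big.mark = " ")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

#' Fold a joint SFS to minor-allele polarization
#'
#' Cells whose total allele count exceeds half the maximum are added onto
#' their complement `(n1 - i, n2 - j)`; cells exactly at half keep the
#' average of themselves and their complement (so folding is idempotent and
#' mass-preserving).
#'
#' @param sfs a `"joint_sfs"`.
#' @return a folded `"joint_sfs"`.
#' @export
fold_sfs <- function(sfs) {
  stopifnot(inherits(sfs, "joint_sfs"))
  if (attr(sfs, "folded")) return(sfs)
  n1 <- attr(sfs, "n1"); n2 <- attr(sfs, "n2")
  m <- unclass(sfs)
  out <- matrix(0, n1 + 1L, n2 + 1L)
  half <- (n1 + n2) / 2
  for (i in 0:n1) {
    for (j in 0:n2) {
      tot <- i + j
      if (tot < half) {
        out[i + 1L, j + 1L] <- m[i + 1L, j + 1L] + m[n1 - i + 1L, n2 - j + 1L]
      } else if (tot == half) {
        out[i + 1L, j + 1L] <- (m[i + 1L, j + 1L] +
                                  m[n1 - i + 1L, n2 - j + 1L]) / 2
      }
    }
  }
  joint_sfs(out, folded = TRUE, seed = attr(sfs, "seed"))
}

#' Write / read a joint SFS as a dadi-style text matrix
#'
#' The first non-comment line holds the two dimensions and the
#' polarization (`folded`/`unfolded`); the second line the row-major cell
#' values.
#'
#' @param sfs a `"joint_sfs"`.
#' @param path file path.
#' @export
write_sfs <- function(sfs, path) {
  stopifnot(inherits(sfs, "joint_sfs"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("%d %d %s", nrow(sfs), ncol(sfs),
            if (attr(sfs, "folded")) "folded" else "unfolded"),
    paste(format(as.vector(t(unclass(sfs))), trim = TRUE, scientific = FALSE),
          collapse = " ")
  ), con)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nr <- as.integer(hdr[1]); nc <- as.integer(hdr[2])
  folded <- identical(hdr[3], "folded")
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  stopifnot(length(vals) == nr * nc)
  joint_sfs(matrix(vals, nr, nc, byrow = TRUE), folded = folded)
}
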