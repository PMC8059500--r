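#' Canonical synthetic study conditions
#'
#' The package's reference experimental setup for exercising the pipeline
#' on data with known ground truth: a deep split (1 Ma at one generation
#' per year) between two populations of diploid size 1e5, an ancestral
#' population of the same size, strong gene flow (`4 N m = 4`) inside the
#' scenario-specific epochs, six diploid individuals sampled per species,
#' and 100 independent 1 kb loci at a mutation rate of 1e-8 per bp per
#' generation. The ABC reference-table priors are moderately wide
#' log-uniform ranges bracketing the generating values; the rejection
#' tolerance keeps 0.5% of the pooled table.
#'
#' @param n_loci loci per simulated dataset.
#' @param n_sims_per_model reference-table simulations per scenario.
#' @return a list with `T_split`, `N`, `m`, `mu`, `locus_length`,
#'   `n_loci`, `models`, `priors` (a [prior_spec()]), `tolerance`,
#'   `n_sims_per_model`, and helper `cfg(seed)` / `model(label)`
#'   closures.
#' @export
study_config <- function(n_loci = 100, n_sims_per_model = 2000) {
  T_split <- 1e6; N <- 1e5; m <- 1e-5
  mu <- 1e-8; L <- 1000
  list(
    T_split = T_split, N = N, m = m, mu = mu, locus_length = L,
    n_loci = n_loci, models = c("M1", "M2", "M3", "M4", "M5"),
    priors = prior_spec(
      N1 = list(dist = "loguniform", min = 5e4, max = 2e5),
      N2 = list(dist = "loguniform", min = 5e4, max = 2e5),
      N_anc = list(dist = "loguniform", min = 5e4, max = 2e5),
      m = list(dist = "loguniform", min = 5e-6, max = 5e-5),
      T_split = T_split),
    tolerance = 0.005,
    n_sims_per_model = n_sims_per_model,
    cfg = function(seed = NULL) sim_config(n1 = 12, n2 = 12, mu = mu,
                                           locus_length = L,
                                           n_loci = n_loci, seed = seed),
    model = function(label) make_model(label, T_split = T_split, N1 = N,
                                       N2 = N, N_anc = N,
                                       m = if (label == "M1") 0 else m)
  )
}
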