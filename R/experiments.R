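# Pre-registered simulation experiments: each function defines one complete
# study (generator settings, measurement settings, scoring) so that tests,
# scripts and users run the identical design.

#' Branch-recovery experiment
#'
#' Runs the full pipeline on the default three-branch tree (branches 2 m
#' apart, three leaves per branch a few centimetres apart) for a set of
#' seeds and scores recovery of the planted branch partition by the adjusted
#' Rand index of the Ward clustering cut.
#'
#' @param seeds integer vector of master seeds (one pipeline run each).
#' @param config pipeline configuration; defaults to [gp_config()].
#' @return data frame with columns `seed` and `ari`.
#' @export
branch_recovery_experiment <- function(seeds, config = gp_config()) {
  ari <- vapply(seeds, function(s) {
    run_gp_pipeline(config, seed = s)$recovery$ari
  }, numeric(1))
  data.frame(seed = seeds, ari = ari)
}

#' Dose-response (monotone signal) experiment
#'
#' Measures how genomic distance responds to generational separation in the
#' regime around the assay's detection limit.  A single cell lineage is laid
#' out as a ladder of leaves whose separations from the first leaf span
#' expected mutation counts of roughly 3 to 100; every leaf is profiled
#' `n_replicates` times (independent gel distortions) and the mean dG to the
#' first leaf is compared with the true generational separation by Spearman
#' rank correlation over the pairs with expected counts in
#' `[count_range[1], count_range[2]]`.
#'
#' Because the dose-response at these loads is driven by individual
#' detectable events, the experiment profiles the genome densely: short
#' amplicons (200-400 bp, so the 50 bp melting window covers a large part of
#' each fragment) at a relaxed mismatch tolerance, with enough bands to tile
#' the 20 kb genome.  The ladder design makes mutation sets nested along the
#' lineage, so the underlying signal accumulates monotonically.
#'
#' @param seed master seed.
#' @param n_leaves leaves on the ladder (default 31, i.e. 30 pairs).
#' @param n_replicates replicate measurements per leaf (default 20).
#' @param genome_length genome length (default 2e4).
#' @param mu_c substitution rate per base per generation (default 5e-7, so
#'   that one generation step of the ladder adds ~1/100 of the maximum
#'   expected count).
#' @param count_range expected-count window scored (default `c(10, 100)`).
#' @return list with `generations`, `expected_counts`, `mean_dg` (per pair)
#'   and `spearman`.
#' @export
monotone_signal_experiment <- function(seed, n_leaves = 31L,
                                       n_replicates = 20L,
                                       genome_length = 2e4,
                                       mu_c = 5e-7,
                                       count_range = c(10, 100)) {
  step_g <- 666  # ladder step in generations: ~3.3 expected counts
  spec <- tree_spec(trunk_height = 1, branch_attach_heights = 0.5,
                    leaves_per_branch = n_leaves,
                    branch_length = n_leaves * step_g * 20e-6,
                    genome_length = genome_length, mu_c = mu_c,
                    seed = seed)
  tree <- build_lineage(spec)
  gens <- pairwise_generations(tree)
  labs <- leaf_labels(tree)
  seeds <- derive_seeds(seed, 1L + n_replicates * n_leaves)
  genomes <- simulate_leaf_genomes(tree, seed = seeds[1L])
  params <- gp_params(max_mismatch = 6L, n_bands = 60L,
                      min_len = 200L, max_len = 400L)
  dgs <- matrix(0, n_replicates, n_leaves - 1L)
  si <- 1L
  for (r in seq_len(n_replicates)) {
    profs <- lapply(seq_len(n_leaves), function(i) {
      suppressWarnings(
        profile_genome(genomes$sequences[[labs[i]]], labs[i], params,
                       seed = seeds[si + i])
      )
    })
    si <- si + n_leaves
    dgs[r, ] <- vapply(2:n_leaves, function(i) {
      genomic_distance(profs[[1L]], profs[[i]])
    }, numeric(1))
  }
  g_true <- gens[labs[1L], labs[-1L]]
  counts <- g_true * mu_c * genome_length
  keep <- counts >= count_range[1] & counts <= count_range[2]
  mean_dg <- colMeans(dgs)
  list(generations = g_true, expected_counts = counts, mean_dg = mean_dg,
       spearman = stats::cor(g_true[keep], mean_dg[keep],
                             method = "spearman"))
}

#' Normalization-invariance experiment
#'
#' Applies random per-axis affine gel distortions (positive scales, no
#' jitter) to a fixed profile and checks that internal-reference
#' normalization restores the undistorted spiddos exactly.
#'
#' @param seed master seed.
#' @param n_distortions number of random distortions (default 100).
#' @return list with `max_abs_error` (worst coordinate discrepancy over all
#'   distortions) and `n`.
#' @export
normalization_invariance_experiment <- function(seed, n_distortions = 100L) {
  set.seed(seed)
  genome <- paste(sample(DNA_BASES, 2e4, replace = TRUE), collapse = "")
  params <- gp_params(distortion = no_distortion())
  truth <- profile_genome(genome, "truth", params, seed = seed)
  raw0 <- attr(truth, "raw")
  worst <- 0
  for (k in seq_len(n_distortions)) {
    sm <- stats::runif(1, 0.5, 2); om <- stats::runif(1, -0.5, 0.5)
    st <- stats::runif(1, 0.5, 2); ot <- stats::runif(1, -10, 10)
    raw <- raw0
    raw$mobility_raw <- sm * raw$mobility_raw + om
    raw$temp_raw <- st * raw$temp_raw + ot
    prof <- normalize_profile(raw, "distorted")
    err <- max(abs(as.matrix(prof$spiddos) - as.matrix(truth$spiddos)))
    worst <- max(worst, err)
  }
  list(max_abs_error = worst, n = n_distortions)
}

#' Mutation-rate recovery experiment
#'
#' Repeatedly simulates Poisson mutation counts under the constant-rate
#' accumulation model and checks how often the least-squares estimator
#' recovers the true rate within a given factor.
#'
#' @param seed master seed.
#' @param n_trials number of independent trials (default 200).
#' @param n_pairs (generations, count) pairs per trial (default 50).
#' @param mu_c true rate (default 1e-8).
#' @param genome_length genome length (default 1e6).
#' @param g_range generation range, sampled log-uniformly (default
#'   `c(1e3, 1e5)`).
#' @param factor tolerated multiplicative error (default 1.5).
#' @return list with `fraction_within` (trials recovering the rate within
#'   the factor), `estimates`, `n`.
#' @export
rate_recovery_experiment <- function(seed, n_trials = 200L, n_pairs = 50L,
                                     mu_c = 1e-8, genome_length = 1e6,
                                     g_range = c(1e3, 1e5), factor = 1.5) {
  set.seed(seed)
  estimates <- vapply(seq_len(n_trials), function(t) {
    g <- round(10^stats::runif(n_pairs, log10(g_range[1]), log10(g_range[2])))
    counts <- stats::rpois(n_pairs, mu_c * genome_length * g)
    estimate_rate_from_simulation(g, counts, genome_length,
                                  n_boot = 0L)$mu_c_hat
  }, numeric(1))
  within <- estimates >= mu_c / factor & estimates <= mu_c * factor
  list(fraction_within = mean(within), estimates = estimates, n = n_trials)
}
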