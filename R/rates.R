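#' One-sided bound with explicit direction
#'
#' Several quantities of the mutation-rate arithmetic are inequalities (a
#' minimum generation count, a rate lower bound); they are returned as a
#' value together with the direction of the comparison rather than a bare
#' number.
#'
#' @param value the bound value.
#' @param comparison `">="` (lower bound) or `"<="` (upper bound).
#' @param quantity short description of the bounded quantity.
#' @return an object of class `gp_bound`.
#' @export
gp_bound <- function(value, comparison = c(">=", "<="), quantity = "") {
  comparison <- match.arg(comparison)
  structure(list(value = value, comparison = comparison, quantity = quantity),
            class = "gp_bound")
}

#' @export
print.gp_bound <- function(x, ...) {
  cat(x$quantity, x$comparison, format(x$value), "\n")
  invisible(x)
}

#' @export
as.numeric.gp_bound <- function(x, ...) x$value

#' Accumulated per-base mutation load over g generations
#'
#' The mutation load after `g` cell generations is the sum over generations
#' of the replication-dependent rate `mu(i)` plus the repair-dependent rate
#' `gamma(i)`.  Under the constant-rate simplification (`mu(i) = mu_c`,
#' `gamma` negligible) this reduces to `g * mu_c`.
#'
#' @param g number of generations (constant mode).
#' @param mu_c constant per-generation rate (constant mode).
#' @param mu_series,gamma_series per-generation rate series of length `g`
#'   (series mode; `gamma_series` defaults to zeros).
#' @return per-base mutation load `mu(g)`.
#' @export
accumulated_mutations <- function(g = NULL, mu_c = NULL, mu_series = NULL,
                                  gamma_series = NULL) {
  if (!is.null(mu_series)) {
    if (is.null(gamma_series)) gamma_series <- numeric(length(mu_series))
    if (length(gamma_series) != length(mu_series)) {
      stop("mu_series and gamma_series must have equal length", call. = FALSE)
    }
    if (any(mu_series < 0) || any(gamma_series < 0)) {
      stop("rates must be non-negative", call. = FALSE)
    }
    return(sum(mu_series + gamma_series))
  }
  check_scalar_number(g, "g", nonneg = TRUE)
  check_scalar_number(mu_c, "mu_c", nonneg = TRUE)
  g * mu_c
}

#' Detection sensitivity of the profiling assay
#'
#' A profile reads roughly `n_bands` bands of `band_len` bases each, so one
#' detectable substitution among `n_bands * band_len` scanned bases sets the
#' sensitivity: `1 / (n_bands * band_len)` mutations/base/replication.  The
#' canonical 10 bands of 1000 bp give 1e-4.
#'
#' @param n_bands number of bands read per profile.
#' @param band_len band length in bases.
#' @return detection sensitivity in mutations per base.
#' @export
detection_sensitivity <- function(n_bands = 10, band_len = 1000) {
  check_scalar_number(n_bands, "n_bands", positive = TRUE)
  check_scalar_number(band_len, "band_len", positive = TRUE)
  1 / (n_bands * band_len)
}

#' Minimum generation count implied by an observed mutation load
#'
#' If a load of `mu_g` per base is observed and each generation contributes
#' at most `mu_c`, then at least `mu_g / mu_c` generations must have elapsed.
#'
#' @param mu_g observed per-base mutation load.
#' @param mu_c per-generation rate.
#' @return a [gp_bound()] lower bound on the generation count.
#' @export
min_generations <- function(mu_g, mu_c) {
  check_scalar_number(mu_g, "mu_g", nonneg = TRUE)
  check_scalar_number(mu_c, "mu_c", positive = TRUE)
  gp_bound(mu_g / mu_c, ">=", "generations g")
}

#' Cell generations separating two points a given distance apart
#'
#' Under the single-file cell lineage model, tandem consecutive cells of unit
#' length `a` spanning a physical distance `B` imply `g' = B / a` cell
#' generations (an upper-bound lineage model: real lineages are not single
#' files of cells).
#'
#' @param B physical (branch-to-branch) distance in metres.
#' @param a unit cell length in metres.
#' @return generation count `g'`.
#' @export
generations_from_distance <- function(B, a) {
  check_scalar_number(B, "B", nonneg = TRUE)
  check_scalar_number(a, "a", positive = TRUE)
  B / a
}

#' Lower bound on the per-generation mutation rate
#'
#' Combining an observed load `mu_g` with a generation count at most
#' `g_prime` gives `mu_c = mu_g / g >= mu_g / g_prime`.
#'
#' @param mu_g observed per-base mutation load.
#' @param g_prime upper bound on the generation count.
#' @return a [gp_bound()] lower bound on `mu_c`.
#' @export
bound_mutation_rate <- function(mu_g, g_prime) {
  check_scalar_number(mu_g, "mu_g", nonneg = TRUE)
  check_scalar_number(g_prime, "g_prime", positive = TRUE)
  gp_bound(mu_g / g_prime, ">=", "mutation rate mu_c")
}

#' The worked sensitivity-to-rate chain
#'
#' Runs the full arithmetic linking the assay's detection sensitivity to a
#' mutation-rate bound: 10 bands x 1000 bp give a sensitivity of 1e-4
#' mutations/base; at an assumed rate of 1e-8 per generation that load needs
#' at least 1e4 generations; a branch-to-branch distance of 2 m at a unit
#' cell length of 20 um corresponds to 1e5 generations; and dividing the
#' load by that generation count bounds the rate from below at 1e-9.
#'
#' @param n_bands,band_len assay geometry.
#' @param mu_c_assumed assumed per-generation rate for the generation bound.
#' @param B,a branch-to-branch distance and unit cell length (metres).
#' @param quiet suppress printing.
#' @return (invisibly) list with `sensitivity`, `g_min`, `g_prime`,
#'   `mu_c_bound`.
#' @export
worked_example <- function(n_bands = 10, band_len = 1000,
                           mu_c_assumed = 1e-8, B = 2, a = 20e-6,
                           quiet = FALSE) {
  sens <- detection_sensitivity(n_bands, band_len)
  g_min <- min_generations(sens, mu_c_assumed)
  g_prime <- generations_from_distance(B, a)
  bound <- bound_mutation_rate(sens, g_prime)
  if (!quiet) {
    cat("detection sensitivity:", format(sens), "mutations/base",
        sprintf("(%g bands x %g bp)\n", n_bands, band_len))
    cat("generations g", g_min$comparison, format(g_min$value),
        sprintf("(load %g at mu_c = %g)\n", sens, mu_c_assumed))
    cat("generations g' =", format(g_prime),
        sprintf("(B = %g m, a = %g m)\n", B, a))
    cat("mutation rate mu_c", bound$comparison, format(bound$value),
        "per base per generation\n")
  }
  invisible(list(sensitivity = sens, g_min = g_min, g_prime = g_prime,
                 mu_c_bound = bound))
}

#' Estimate the per-generation mutation rate from (generations, count) pairs
#'
#' Fits the constant-rate accumulation model `E[count] = mu_c * L * g` by
#' least squares through the origin: `mu_c_hat = sum(g * count) / (L *
#' sum(g^2))`.  Uncertainty is assessed by a nonparametric bootstrap over
#' pairs.
#'
#' @param generations numeric vector of generation counts.
#' @param counts observed mutation counts, same length.
#' @param genome_length genome length `L` in bases.
#' @param n_boot bootstrap resamples (0 disables the interval).
#' @param conf confidence level for the bootstrap interval.
#' @param seed integer seed for the bootstrap.
#' @return list with `mu_c_hat`, `ci` (or `NULL`), `n`.
#' @export
estimate_rate_from_simulation <- function(generations, counts, genome_length,
                                          n_boot = 1000L, conf = 0.95,
                                          seed = NULL) {
  if (length(generations) != length(counts) || length(generations) < 1L) {
    stop("generations and counts must be non-empty and of equal length",
         call. = FALSE)
  }
  check_scalar_number(genome_length, "genome_length", positive = TRUE)
  if (any(generations <= 0)) stop("generation counts must be positive",
                                  call. = FALSE)
  if (length(generations) >= 2L && length(unique(generations)) < 2L) {
    stop("degenerate design: at least two distinct generation values needed",
         call. = FALSE)
  }
  slope <- function(g, c) sum(g * c) / (genome_length * sum(g^2))
  est <- slope(generations, counts)
  ci <- NULL
  if (n_boot > 0L) {
    ci <- with_seed_maybe(seed, {
      boots <- replicate(n_boot, {
        idx <- sample.int(length(generations), replace = TRUE)
        slope(generations[idx], counts[idx])
      })
      stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                      names = FALSE)
    })
  }
  list(mu_c_hat = est, ci = ci, n = length(generations))
}
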