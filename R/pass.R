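#' Match spiddos between two genome profiles
#'
#' Establishes the correspondence between the spiddo sets of two profiles as
#' the one-to-one assignment minimizing the total Euclidean displacement
#' (optimal bipartite assignment).  With unequal set sizes,
#' `min(nA, nB)` pairs are formed and the extras recorded as unmatched.
#'
#' @param a,b [gp_profile()] objects.
#' @return an object of class `spiddo_pairing`: list with `pairs` (matrix of
#'   (index in `a`, index in `b`)), `n`, `unmatched_a`, `unmatched_b` and
#'   `total_displacement`.
#' @export
match_spiddos <- function(a, b) {
  stopifnot(inherits(a, "gp_profile"), inherits(b, "gp_profile"))
  if (a$n < 1L || b$n < 1L) stop("profiles must be non-empty", call. = FALSE)
  pa <- as.matrix(a$spiddos)
  pb <- as.matrix(b$spiddos)
  cost <- outer(seq_len(nrow(pa)), seq_len(nrow(pb)),
                function(i, j) sqrt((pa[i, 1] - pb[j, 1])^2 +
                                    (pa[i, 2] - pb[j, 2])^2))
  sol <- solve_assignment(cost)
  pairs <- sol$pairs
  colnames(pairs) <- c("a", "b")
  structure(list(pairs = pairs,
                 n = nrow(pairs),
                 unmatched_a = a$n - nrow(pairs),
                 unmatched_b = b$n - nrow(pairs),
                 total_displacement = sol$cost),
            class = "spiddo_pairing")
}

#' Pattern similarity score (PaSS) between two profiles
#'
#' Given matched spiddos, computes
#' `PaSS = 1 - (1/n) * sum_i ||p_i - p'_i|| / (||p_i|| + ||p'_i||)`,
#' where `p_i`, `p'_i` are the normalized positional vectors (mobility,
#' temperature) of the i-th matched pair and the norms are Euclidean.  A pair
#' with both points at the origin contributes zero displacement (the points
#' are identical).  Since `||p - p'|| <= ||p|| + ||p'||`, every term lies in
#' `[0, 1]` and so does PaSS; PaSS equals 1 exactly when the two spiddo sets
#' coincide.
#'
#' @param a,b [gp_profile()] objects.
#' @param pairing a [match_spiddos()] result (computed if missing).
#' @return PaSS in `[0, 1]`.
#' @export
pass_score <- function(a, b, pairing = match_spiddos(a, b)) {
  if (pairing$n == 0L) stop("no matched spiddos: PaSS undefined",
                            call. = FALSE)
  pa <- as.matrix(a$spiddos)[pairing$pairs[, 1L], , drop = FALSE]
  pb <- as.matrix(b$spiddos)[pairing$pairs[, 2L], , drop = FALSE]
  disp <- sqrt(rowSums((pa - pb)^2))
  denom <- sqrt(rowSums(pa^2)) + sqrt(rowSums(pb^2))
  term <- ifelse(denom == 0, 0, disp / denom)
  1 - mean(term)
}

#' Genomic distance between two profiles
#'
#' `dG = 1 - PaSS`, computed over the optimal spiddo correspondence.  It is
#' zero for identical profiles, symmetric, and bounded in `[0, 1]`; small
#' values indicate closely related genomes.  (It is a pseudo-semimetric: the
#' triangle inequality is not guaranteed.)
#'
#' @param a,b [gp_profile()] objects.
#' @return dG in `[0, 1]`.
#' @export
genomic_distance <- function(a, b) {
  1 - pass_score(a, b)
}

#' All-pairs genomic distance matrix
#'
#' @param profiles list of [gp_profile()] objects with unique labels.
#' @return symmetric numeric matrix of dG values with zero diagonal and the
#'   profile labels as dimnames.
#' @export
distance_matrix <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least two profiles", call. = FALSE)
  labels <- vapply(profiles, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("profile labels must be unique",
                                  call. = FALSE)
  n <- length(profiles)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- genomic_distance(profiles[[i]], profiles[[j]])
    }
  }
  d
}

#' Average replicate profiles into a mean-spiddos profile
#'
#' Replicate measurements of the same sample are combined by matching every
#' replicate's spiddos to the first replicate (optimal assignment) and
#' averaging the matched coordinates.  Averaging replicate spiddos before
#' computing distances reduces the measurement variance of dG.
#'
#' @param replicates list of [gp_profile()] objects of the same sample.
#' @param label label for the averaged profile (default: first replicate's).
#' @return a [gp_profile()] of averaged spiddos.
#' @export
average_profiles <- function(replicates, label = replicates[[1L]]$label) {
  stopifnot(length(replicates) >= 1L)
  if (length(replicates) == 1L) return(replicates[[1L]])
  anchor <- replicates[[1L]]
  acc <- as.matrix(anchor$spiddos)
  cnt <- rep(1, nrow(acc))
  for (r in replicates[-1L]) {
    pairing <- match_spiddos(anchor, r)
    pr <- as.matrix(r$spiddos)[pairing$pairs[, 2L], , drop = FALSE]
    ia <- pairing$pairs[, 1L]
    acc[ia, ] <- acc[ia, ] + pr
    cnt[ia] <- cnt[ia] + 1
  }
  gp_profile(acc / cnt, label = label,
             metadata = list(n_replicates = length(replicates)))
}
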