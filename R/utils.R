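# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' @param x a single DNA string over A, C, G, T.
#' @return the reverse complement as a single string.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                               collapse = ""))
}

# Validate that a string is non-empty uppercase ACGT.
check_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    stop(what, " must be a single non-empty DNA string", call. = FALSE)
  }
  if (grepl("[^ACGT]", x)) {
    stop(what, " contains characters outside A/C/G/T", call. = FALSE)
  }
  invisible(x)
}

check_scalar_number <- function(x, what, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(what, " must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) stop(what, " must be > 0", call. = FALSE)
  if (nonneg && x < 0) stop(what, " must be >= 0", call. = FALSE)
  invisible(x)
}

# Set the RNG state reproducibly when a seed is supplied; otherwise leave the
# current state alone.
with_seed_maybe <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

# Deterministic derivation of sub-seeds from a master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# ceiling() with a small tolerance so that exact ratios computed in floating
# point (e.g. 2 / 2e-5) do not round up spuriously.
safe_ceiling <- function(x, tol = 1e-9) {
  as.integer(ceiling(x - tol))
}
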