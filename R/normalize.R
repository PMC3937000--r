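#' Genome profile (spiddos set) container
#'
#' A genome profile is an ordered set of spiddos — species identification
#' dots, i.e. normalized (mobility, temperature) feature points — for one
#' sample.
#'
#' @param points a matrix or data frame with two columns (`mobility`,
#'   `temp`), one row per spiddo.
#' @param label sample label.
#' @param metadata optional named list carried along (primer, seed, source).
#' @return an object of class `gp_profile`: list with `label`, `spiddos`
#'   (data frame with columns `mobility`, `temp`) and `n`.
#' @export
gp_profile <- function(points, label, metadata = list()) {
  pts <- as.data.frame(points)
  if (ncol(pts) != 2L) stop("points must have two columns", call. = FALSE)
  names(pts) <- c("mobility", "temp")
  if (nrow(pts) < 1L) stop("a profile needs at least one spiddo",
                           call. = FALSE)
  if (any(!is.finite(pts$mobility)) || any(!is.finite(pts$temp))) {
    stop("spiddo coordinates must be finite", call. = FALSE)
  }
  # exact duplicates carry no extra information; merge them
  pts <- unique(pts)
  rownames(pts) <- NULL
  structure(list(label = label, spiddos = pts, n = nrow(pts),
                 metadata = metadata),
            class = "gp_profile")
}

#' @export
print.gp_profile <- function(x, ...) {
  cat("gp_profile", x$label, "with", x$n, "spiddos\n")
  invisible(x)
}

# The two-point linear map sending observed reference coordinates to their
# nominal ones; errors if degenerate or orientation-reversing.
two_point_map <- function(obs, nominal, axis) {
  if (abs(obs[2] - obs[1]) < .Machine$double.eps * 16) {
    stop("degenerate calibration: references coincide on the ", axis,
         " axis", call. = FALSE)
  }
  scale <- (nominal[2] - nominal[1]) / (obs[2] - obs[1])
  if (scale <= 0) {
    stop("reference order is reversed on the ", axis,
         " axis (flipped gel?); refusing to calibrate", call. = FALSE)
  }
  offset <- nominal[1] - scale * obs[1]
  function(x) scale * x + offset
}

#' Normalize raw gel points into spiddos
#'
#' Internal-reference-mediated normalization: per axis, the unique linear map
#' taking the two observed reference points to their nominal coordinates
#' (`mobility(200)`, `mobility(900)` on the mobility axis; 60.0 C and 61.4 C
#' on the temperature axis) is applied to every sample point.  Any per-axis
#' affine gel distortion shared by samples and references is thereby exactly
#' cancelled, which is what makes spiddos reproducible across runs.  The
#' reference points are dropped from the returned profile.
#'
#' @param raw data frame of raw points as produced by [profile_fragments()]
#'   (columns `mobility_raw`, `temp_raw`, `is_reference`, `source`).
#' @param label sample label for the resulting profile.
#' @param mobility_bounds calibration bounds used for the nominal reference
#'   mobilities; must match the simulation settings.
#' @param refs nominal references, as [reference_fragments()].
#' @return a [gp_profile()] of normalized spiddos.
#' @export
normalize_profile <- function(raw, label = "sample",
                              mobility_bounds = c(100, 3000),
                              refs = reference_fragments()) {
  need <- c("mobility_raw", "temp_raw", "is_reference", "source")
  if (!all(need %in% names(raw))) {
    stop("raw profile must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  rr <- raw[raw$is_reference, , drop = FALSE]
  if (nrow(rr) != 2L) {
    stop("raw profile must contain exactly two reference points, found ",
         nrow(rr), call. = FALSE)
  }
  idx <- match(refs$name, rr$source)
  if (anyNA(idx)) stop("reference points must be labelled ",
                       paste(refs$name, collapse = " and "), call. = FALSE)
  rr <- rr[idx, ]
  map_m <- two_point_map(rr$mobility_raw, mobility(refs$length,
                                                   mobility_bounds),
                         "mobility")
  map_t <- two_point_map(rr$temp_raw, refs$tm, "temperature")
  smp <- raw[!raw$is_reference, , drop = FALSE]
  if (nrow(smp) < 1L) stop("no sample points to normalize", call. = FALSE)
  gp_profile(data.frame(mobility = map_m(smp$mobility_raw),
                        temp = map_t(smp$temp_raw)),
             label = label)
}
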