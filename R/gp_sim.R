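#' Primers for in-silico random PCR
#'
#' Random PCR uses a single short primer under low-stringency annealing, so
#' that it binds genomic DNA with mismatches and samples fragments
#' independently of primer design.  `primer_hunt()` and `primer_pfm12()` are
#' the two 12-mers commonly used for genome profiling.
#'
#' @param name primer name.
#' @param sequence primer sequence, 5' to 3', ACGT only.
#' @return an object of class `gp_primer` with fields `name` and `sequence`.
#' @export
gp_primer <- function(name, sequence) {
  check_dna(sequence, "primer sequence")
  structure(list(name = name, sequence = sequence), class = "gp_primer")
}

#' @rdname gp_primer
#' @export
primer_hunt <- function() gp_primer("HUNT", "TGCTGCTGCTGC")

#' @rdname gp_primer
#' @export
primer_pfm12 <- function() gp_primer("Pfm12", "AGAACGCGCCTG")

#' Find mismatch-tolerant primer binding sites
#'
#' Scans both strands of a genome for primer footprints with at most
#' `max_mismatch` mismatches overall and a perfectly matched 3'-terminal
#' anchor of `anchor3` bases (polymerase extension requires a matched 3' end).
#' Positions are 0-based starts of the footprint in forward-strand
#' coordinates; on the minus strand the primer's 3' end maps to the left end
#' of the footprint.
#'
#' @param genome a single ACGT string.
#' @param primer a [gp_primer()].
#' @param max_mismatch maximum total mismatches tolerated.
#' @param anchor3 number of 3'-terminal primer bases that must match exactly.
#' @return a data frame with columns `position` (0-based), `strand`
#'   (`"+"`/`"-"`) and `mismatches`, sorted by position then strand.  A primer
#'   longer than the genome yields zero rows.
#' @export
find_binding_sites <- function(genome, primer, max_mismatch = 4L,
                               anchor3 = 3L) {
  check_dna(genome, "genome")
  if (!inherits(primer, "gp_primer")) stop("primer must be a gp_primer",
                                           call. = FALSE)
  k <- nchar(primer$sequence)
  if (anchor3 > k) stop("anchor3 cannot exceed the primer length",
                        call. = FALSE)
  L <- nchar(genome)
  empty <- data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (k > L) return(empty)

  g <- utf8ToInt(genome)
  scan_strand <- function(pat, anchor_pos) {
    pr <- utf8ToInt(pat)
    npos <- L - k + 1L
    mm <- integer(npos)
    amm <- integer(npos)
    for (j in seq_len(k)) {
      neq <- g[j:(j + npos - 1L)] != pr[j]
      mm <- mm + neq
      if (j %in% anchor_pos) amm <- amm + neq
    }
    hit <- which(mm <= max_mismatch & amm == 0L)
    data.frame(position = hit - 1L, mismatches = mm[hit],
               stringsAsFactors = FALSE)
  }
  # plus strand: 3' anchor is the rightmost anchor3 bases of the footprint
  plus <- scan_strand(primer$sequence, seq.int(k - anchor3 + 1L, k))
  # minus strand: match the reverse complement; the 3' anchor becomes the
  # leftmost anchor3 bases of the forward-strand footprint
  minus <- scan_strand(revcomp(primer$sequence), seq_len(anchor3))
  plus$strand <- rep("+", nrow(plus))
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out <- out[order(out$position, out$strand),
             c("position", "strand", "mismatches")]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate amplicons from binding sites
#'
#' Pairs every plus-strand site with every convergent minus-strand site (the
#' minus footprint at or downstream of the plus footprint) whose implied
#' product length falls within `[min_len, max_len]`.  The fragment runs from
#' the plus footprint start to the minus footprint end; its score is the sum
#' of the two priming sites' mismatch counts (lower = better primed).
#'
#' @param sites a data frame from [find_binding_sites()].
#' @param genome the genome the sites were found on.
#' @param min_len,max_len product length window in bases.
#' @param primer_length footprint length in bases (default 12).
#' @return a data frame with columns `start`, `end` (0-based half-open),
#'   `length`, `score` and `sequence`; zero rows when no convergent pair fits.
#' @export
enumerate_amplicons <- function(sites, genome, min_len = 200L,
                                max_len = 2000L, primer_length = 12L) {
  check_dna(genome, "genome")
  empty <- data.frame(start = integer(), end = integer(), length = integer(),
                      score = integer(), sequence = character(),
                      stringsAsFactors = FALSE)
  plus <- sites[sites$strand == "+", , drop = FALSE]
  minus <- sites[sites$strand == "-", , drop = FALSE]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(empty)
  out <- vector("list", nrow(plus))
  for (i in seq_len(nrow(plus))) {
    p <- plus$position[i]
    ends <- minus$position + primer_length
    len <- ends - p
    ok <- minus$position >= p & len >= min_len & len <= max_len
    if (!any(ok)) next
    out[[i]] <- data.frame(
      start = p,
      end = ends[ok],
      length = len[ok],
      score = plus$mismatches[i] + minus$mismatches[ok],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty)
  out <- out[order(out$start, out$end), ]
  out$sequence <- substring(genome, out$start + 1L, out$end)
  rownames(out) <- NULL
  out
}

#' Select the amplified band set
#'
#' Models amplification bias: the best-primed products dominate the gel.
#' Fragments are ranked by (mismatch score, length, start) ascending and the
#' first `n_bands` kept; the ordering is fully deterministic.
#'
#' @param fragments data frame from [enumerate_amplicons()].
#' @param n_bands number of bands to retain (default 10, the typical number
#'   of bands in a genome profile).
#' @return the selected fragments, in rank order.  If fewer than `n_bands`
#'   fragments exist, all are returned with a warning.
#' @export
select_fragments <- function(fragments, n_bands = 10L) {
  if (n_bands < 1L) stop("n_bands must be >= 1", call. = FALSE)
  if (nrow(fragments) < n_bands) {
    warning("only ", nrow(fragments), " fragments available for ", n_bands,
            " bands; returning all", call. = FALSE)
  }
  ord <- order(fragments$score, fragments$length, fragments$start)
  out <- fragments[utils::head(ord, n_bands), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Melting temperature of a fragment's lowest-melting domain
#'
#' The observable in temperature-gradient electrophoresis is the onset of the
#' double-strand to single-strand transition, governed by the lowest-melting
#' domain of the fragment.  This is modelled as the minimum over all sliding
#' windows of the GC-content melting formula
#' `Tm(w) = 64.9 + 41 * (GC(w) - 16.4) / |w|` (GC(w) = number of G/C bases in
#' window `w`).  A substitution changes the result only when it lands in a
#' window governing the minimum.
#'
#' @param seq a single ACGT string.
#' @param window window length in bases (default 50); when the sequence is
#'   shorter than `window`, the whole sequence is used.
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, window = 50L) {
  check_dna(seq, "fragment sequence")
  n <- nchar(seq)
  w <- min(as.integer(window), n)
  gc <- utf8ToInt(seq)
  gc <- as.integer(gc == 67L | gc == 71L)  # C or G
  cs <- c(0L, cumsum(gc))
  counts <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]
  64.9 + 41 * (min(counts) - 16.4) / w
}

#' Electrophoretic mobility of a fragment
#'
#' Size-dependent migration: shorter fragments run further.  Modelled as
#' `1 - log10(length / l_min) / log10(l_max / l_min)`, clipped to `[0, 1]`,
#' so `mobility(l_min) = 1` and `mobility(l_max) = 0`.
#'
#' @param length fragment length(s) in bases, > 0 (vectorised).
#' @param bounds `c(l_min, l_max)` calibration lengths for the gel.
#' @return dimensionless mobility in `[0, 1]`, strictly decreasing in length
#'   inside the bounds.
#' @export
mobility <- function(length, bounds = c(100, 3000)) {
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop("fragment length must be > 0", call. = FALSE)
  }
  m <- 1 - log10(length / bounds[1]) / log10(bounds[2] / bounds[1])
  pmin(pmax(m, 0), 1)
}

#' Internal reference fragments
#'
#' Two reference DNAs of known size and melting temperature are co-migrated
#' in every run: Ref1 (200 bp, Tm 60.0 C) and Ref2 (900 bp, Tm 61.4 C).
#' Their observed positions calibrate each profile (see
#' [normalize_profile()]).
#'
#' @return data frame with columns `name`, `length`, `tm`.
#' @export
reference_fragments <- function() {
  data.frame(name = c("Ref1", "Ref2"), length = c(200L, 900L),
             tm = c(60.0, 61.4), stringsAsFactors = FALSE)
}

#' Per-gel distortion model
#'
#' Each electrophoretic run distorts all co-migrating points (samples and
#' references alike) by a per-axis affine transform with scale and offset
#' drawn uniformly from the given ranges, plus i.i.d. Gaussian jitter.  The
#' affine component is what internal-reference normalization cancels; jitter
#' is irreducible reading noise.
#'
#' @param scale_mobility,scale_temp ranges `c(lo, hi)` for the per-axis scale.
#' @param offset_mobility,offset_temp ranges for the per-axis offset
#'   (mobility units / degrees Celsius).
#' @param jitter_mobility,jitter_temp Gaussian jitter standard deviations.
#' @return an object of class `distortion_spec`.
#' @export
distortion_spec <- function(scale_mobility = c(0.9, 1.1),
                            offset_mobility = c(-0.05, 0.05),
                            scale_temp = c(0.95, 1.05),
                            offset_temp = c(-1, 1),
                            jitter_mobility = 0.005,
                            jitter_temp = 0.005) {
  if (min(scale_mobility) <= 0 || min(scale_temp) <= 0) {
    stop("distortion scales must be positive (a flipped gel is not modelled)",
         call. = FALSE)
  }
  structure(list(scale_mobility = scale_mobility,
                 offset_mobility = offset_mobility,
                 scale_temp = scale_temp,
                 offset_temp = offset_temp,
                 jitter_mobility = jitter_mobility,
                 jitter_temp = jitter_temp),
            class = "distortion_spec")
}

#' Zero-noise distortion (identity transform)
#' @return a `distortion_spec` whose affine part is the identity and whose
#'   jitter is zero.
#' @export
no_distortion <- function() {
  distortion_spec(scale_mobility = c(1, 1), offset_mobility = c(0, 0),
                  scale_temp = c(1, 1), offset_temp = c(0, 0),
                  jitter_mobility = 0, jitter_temp = 0)
}

#' Render fragments as raw gel feature points (pre-spiddos)
#'
#' Maps each selected fragment to its model coordinates
#' `(mobility(length), melting_temperature(sequence))`, appends the two
#' internal references at `(mobility(length), nominal Tm)`, and applies one
#' per-profile random distortion (shared affine transform per axis, then
#' point-wise jitter) to all points — references included, since they
#' co-migrate in the same run.
#'
#' @param fragments selected fragments (see [select_fragments()]).
#' @param refs reference fragments, as [reference_fragments()].
#' @param distortion a [distortion_spec()].
#' @param seed integer seed for the distortion draw; same seed, same output.
#' @param tm_window window for [melting_temperature()].
#' @param mobility_bounds bounds for [mobility()].
#' @return data frame of raw points: `point_id`, `source`, `mobility_raw`,
#'   `temp_raw`, `is_reference`.
#' @export
profile_fragments <- function(fragments, refs = reference_fragments(),
                              distortion = distortion_spec(), seed = NULL,
                              tm_window = 50L,
                              mobility_bounds = c(100, 3000)) {
  if (nrow(refs) != 2L) stop("both internal references are required",
                             call. = FALSE)
  n <- nrow(fragments)
  tm <- vapply(fragments$sequence, melting_temperature, numeric(1),
               window = tm_window, USE.NAMES = FALSE)
  pts <- data.frame(
    point_id = c(sprintf("b%02d", seq_len(n)), refs$name),
    source = c(sprintf("%d-%d", fragments$start, fragments$end), refs$name),
    mobility_raw = c(mobility(fragments$length, mobility_bounds),
                     mobility(refs$length, mobility_bounds)),
    temp_raw = c(tm, refs$tm),
    is_reference = c(rep(FALSE, n), rep(TRUE, 2L)),
    stringsAsFactors = FALSE
  )
  with_seed_maybe(seed, {
    sm <- stats::runif(1, distortion$scale_mobility[1],
                       distortion$scale_mobility[2])
    om <- stats::runif(1, distortion$offset_mobility[1],
                       distortion$offset_mobility[2])
    st <- stats::runif(1, distortion$scale_temp[1], distortion$scale_temp[2])
    ot <- stats::runif(1, distortion$offset_temp[1], distortion$offset_temp[2])
    m <- nrow(pts)
    pts$mobility_raw <- sm * pts$mobility_raw + om +
      stats::rnorm(m, 0, distortion$jitter_mobility)
    pts$temp_raw <- st * pts$temp_raw + ot +
      stats::rnorm(m, 0, distortion$jitter_temp)
    pts
  })
}

#' Measure a genome: full in-silico genome profiling of one sample
#'
#' Convenience wrapper running the whole measurement for one genome: binding
#' site search, amplicon enumeration, band selection, gel rendering with
#' distortion, and internal-reference normalization.
#'
#' @param genome a single ACGT string.
#' @param label sample label for the resulting profile.
#' @param params a [gp_params()] bundle of measurement settings.
#' @param seed integer seed controlling the gel distortion draw.
#' @return a [gp_profile()]; the raw pre-spiddo table is attached as
#'   attribute `"raw"`.
#' @export
profile_genome <- function(genome, label, params = gp_params(), seed = NULL) {
  sites <- find_binding_sites(genome, params$primer, params$max_mismatch,
                              params$anchor3)
  frags <- enumerate_amplicons(sites, genome, params$min_len, params$max_len,
                               primer_length = nchar(params$primer$sequence))
  if (nrow(frags) == 0L) {
    stop("no amplifiable fragments for sample ", label,
         "; consider a higher max_mismatch", call. = FALSE)
  }
  sel <- select_fragments(frags, params$n_bands)
  raw <- profile_fragments(sel, refs = params$refs,
                           distortion = params$distortion, seed = seed,
                           tm_window = params$tm_window,
                           mobility_bounds = params$mobility_bounds)
  prof <- normalize_profile(raw, label,
                            mobility_bounds = params$mobility_bounds,
                            refs = params$refs)
  attr(prof, "raw") <- raw
  prof
}

#' Measurement parameter bundle
#'
#' Collects the settings of the in-silico measurement: the random-PCR primer
#' model (primer, mismatch tolerance, 3' anchor, product length window, band
#' count) and the gel model (Tm window, mobility calibration bounds,
#' distortion).  Defaults are calibrated so a random 100 kb genome yields on
#' the order of a hundred candidate amplicons, of which the 10 best-primed
#' form the profile — roughly 10 bands of about 1 kb.
#'
#' @param primer a [gp_primer()].
#' @param max_mismatch,anchor3 see [find_binding_sites()].
#' @param min_len,max_len product length window (bases).
#' @param n_bands bands retained per profile.
#' @param tm_window melting window (bases).
#' @param mobility_bounds gel calibration lengths `c(l_min, l_max)`.
#' @param distortion a [distortion_spec()].
#' @param refs internal references.
#' @return an object of class `gp_params`.
#' @export
gp_params <- function(primer = primer_hunt(), max_mismatch = 4L, anchor3 = 3L,
                      min_len = 200L, max_len = 2000L, n_bands = 10L,
                      tm_window = 50L, mobility_bounds = c(100, 3000),
                      distortion = distortion_spec(),
                      refs = reference_fragments()) {
  structure(list(primer = primer, max_mismatch = as.integer(max_mismatch),
                 anchor3 = as.integer(anchor3), min_len = as.integer(min_len),
                 max_len = as.integer(max_len), n_bands = as.integer(n_bands),
                 tm_window = as.integer(tm_window),
                 mobility_bounds = mobility_bounds,
                 distortion = distortion, refs = refs),
            class = "gp_params")
}
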