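# Independent oracles used across the suite: deliberately naive
# implementations that share no code with the package internals.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc <- function(x) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Per-position substring scan for primer binding sites.
naive_sites <- function(genome, primer_seq, max_mismatch, anchor3) {
  k <- nchar(primer_seq)
  L <- nchar(genome)
  out <- NULL
  pr <- strsplit(primer_seq, "")[[1]]
  prm <- strsplit(rc(primer_seq), "")[[1]]
  for (pos in seq_len(L - k + 1)) {
    win <- strsplit(substring(genome, pos, pos + k - 1), "")[[1]]
    mm_plus <- sum(win != pr)
    if (mm_plus <= max_mismatch &&
        all(win[(k - anchor3 + 1):k] == pr[(k - anchor3 + 1):k])) {
      out <- rbind(out, data.frame(position = pos - 1, strand = "+",
                                   mismatches = mm_plus))
    }
    mm_minus <- sum(win != prm)
    if (mm_minus <= max_mismatch && all(win[1:anchor3] == prm[1:anchor3])) {
      out <- rbind(out, data.frame(position = pos - 1, strand = "-",
                                   mismatches = mm_minus))
    }
  }
  if (is.null(out)) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer()))
  }
  out <- out[order(out$position, out$strand), ]
  rownames(out) <- NULL
  out
}

# O(n^2) convergent-pair enumeration.
naive_amplicons <- function(sites, min_len, max_len, k = 12) {
  plus <- sites[sites$strand == "+", ]
  minus <- sites[sites$strand == "-", ]
  out <- NULL
  for (i in seq_len(nrow(plus))) {
    for (j in seq_len(nrow(minus))) {
      len <- minus$position[j] + k - plus$position[i]
      if (minus$position[j] >= plus$position[i] &&
          len >= min_len && len <= max_len) {
        out <- rbind(out, data.frame(start = plus$position[i],
                                     end = minus$position[j] + k,
                                     length = len,
                                     score = plus$mismatches[i] +
                                       minus$mismatches[j]))
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), score = integer()))
  }
  out[order(out$start, out$end), ]
}

# All permutations of 1..n (n small).
perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# Exhaustive minimum assignment cost for a square cost matrix.
brute_min_cost <- function(cost) {
  n <- nrow(cost)
  pm <- perms(n)
  min(apply(pm, 1, function(p) sum(cost[cbind(seq_len(n), p)])))
}

# Random profile with positive coordinates on realistic scales.
random_profile <- function(n, label = "p") {
  gp_profile(cbind(runif(n, 0, 1), runif(n, 58, 66)), label)
}

# Hand-applied Lance-Williams recurrence for Ward.D merge heights.
ward_d_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA)
    bestv <- Inf
    for (i in active) for (j in active) {
      if (i < j && d[i, j] < bestv) { bestv <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bestv)
    for (k in setdiff(active, best)) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      d[i, k] <- d[k, i] <-
        ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] - nk * d[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# profile_genome without the small-genome band-count warning
quiet_profile <- function(...) suppressWarnings(profile_genome(...))
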