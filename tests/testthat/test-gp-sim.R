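test_that("an exact primer occurrence is found on both strands", {
  primer <- gp_primer("toy", "ACGTACGTACGT")
  genome <- paste0(random_dna(50), "ACGTACGTACGT", random_dna(50))
  sites <- find_binding_sites(genome, primer, max_mismatch = 0, anchor3 = 3)
  plus <- sites[sites$strand == "+", ]
  expect_true(50 %in% plus$position)
  expect_true(all(sites$mismatches == 0))
  # same result as the exhaustive per-position oracle
  expect_equal(sites, naive_sites(genome, "ACGTACGTACGT", 0, 3),
               ignore_attr = TRUE)
})

test_that("site finder matches the exhaustive scan oracle on random genomes", {
  set.seed(11)
  primer <- primer_pfm12()
  for (rep in 1:5) {
    genome <- random_dna(1000)
    got <- find_binding_sites(genome, primer, max_mismatch = 2, anchor3 = 3)
    want <- naive_sites(genome, primer$sequence, 2, 3)
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # and on larger genomes at the default tolerance
  genome <- random_dna(2000)
  got <- find_binding_sites(genome, primer, max_mismatch = 4, anchor3 = 3)
  want <- naive_sites(genome, primer$sequence, 4, 3)
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("site finder agrees with Biostrings matchPattern plus anchor filter", {
  set.seed(12)
  genome <- random_dna(1500)
  primer <- primer_hunt()
  mm <- 3; anchor <- 3
  got <- find_binding_sites(genome, primer, max_mismatch = mm,
                            anchor3 = anchor)
  subj <- Biostrings::DNAString(genome)
  check_strand <- function(pat, anchor_left) {
    hits <- Biostrings::matchPattern(pat, subj, max.mismatch = mm)
    pos <- BiocGenerics::start(hits) - 1L
    k <- nchar(pat)
    keep <- vapply(pos, function(p) {
      win <- substring(genome, p + 1, p + k)
      idx <- if (anchor_left) 1:anchor else (k - anchor + 1):k
      all(strsplit(win, "")[[1]][idx] == strsplit(pat, "")[[1]][idx])
    }, logical(1))
    sort(pos[keep])
  }
  expect_identical(sort(got$position[got$strand == "+"]),
                   as.integer(check_strand(primer$sequence, FALSE)))
  expect_identical(sort(got$position[got$strand == "-"]),
                   as.integer(check_strand(rc(primer$sequence), TRUE)))
})

test_that("repeat genomes yield perfect sites at the repeat period", {
  genome <- paste(rep("TGC", 60), collapse = "")
  sites <- find_binding_sites(genome, primer_hunt(), max_mismatch = 0,
                              anchor3 = 3)
  plus <- sites[sites$strand == "+" & sites$mismatches == 0, ]
  expect_true(all(diff(plus$position) == 3))
  # primer longer than genome is an empty result, not an error
  expect_identical(nrow(find_binding_sites("ACGT", primer_hunt(), 0, 3)), 0L)
})

test_that("amplicon enumeration produces exactly the convergent in-window pairs", {
  # one + site at 0 and one convergent - site giving a 500 bp product
  genome <- random_dna(600)
  sites <- data.frame(position = c(0L, 488L), strand = c("+", "-"),
                      mismatches = c(1L, 2L))
  fr <- enumerate_amplicons(sites, genome, min_len = 100, max_len = 2000)
  expect_identical(nrow(fr), 1L)
  expect_identical(fr$length, 500L)
  expect_identical(fr$score, 3L)
  expect_identical(fr$sequence, substring(genome, 1, 500))

  # all sites on one strand cannot prime a product
  one_strand <- data.frame(position = c(0L, 100L), strand = c("+", "+"),
                           mismatches = c(0L, 0L))
  expect_identical(nrow(enumerate_amplicons(one_strand, genome, 100, 2000)),
                   0L)
})

test_that("amplicon enumeration matches the quadratic pairing oracle", {
  set.seed(21)
  genome <- random_dna(5000)
  for (rep in 1:5) {
    n <- sample(5:25, 1)
    sites <- data.frame(
      position = sort(sample.int(4900, n)) - 1L,
      strand = sample(c("+", "-"), n, replace = TRUE),
      mismatches = sample(0:4, n, replace = TRUE)
    )
    got <- enumerate_amplicons(sites, genome, 200, 2000)
    want <- naive_amplicons(sites, 200, 2000)
    expect_equal(got[, c("start", "end", "length", "score")], want,
                 ignore_attr = TRUE)
  }
})

test_that("band selection is deterministic and score-ranked", {
  fr <- data.frame(start = c(10L, 5L, 7L, 1L), end = c(310L, 305L, 307L, 301L),
                   length = c(300L, 300L, 300L, 300L),
                   score = c(2L, 1L, 1L, 3L),
                   sequence = rep(strrep("A", 300), 4))
  sel <- select_fragments(fr, 3)
  # score ascending, then start breaks the tie between the two score-1 rows
  expect_identical(sel$start, c(5L, 7L, 10L))
  expect_warning(all_of_them <- select_fragments(fr, 10), "only 4 fragments")
  expect_identical(nrow(all_of_them), 4L)
})

test_that("melting temperature tracks GC content of the coolest window", {
  expect_gt(melting_temperature(strrep("GC", 50), 50),
            melting_temperature(strrep("AT", 50), 50))
  # window covering the whole sequence reduces to the global GC formula
  s <- random_dna(80)
  gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C"))
  expect_equal(melting_temperature(s, 80), 64.9 + 41 * (gc - 16.4) / 80)
  expect_error(melting_temperature(""), "non-empty")
})

test_that("windowed melting minimum matches a brute-force window scan", {
  set.seed(5)
  for (rep in 1:5) {
    s <- random_dna(300)
    w <- sample(c(20, 50, 120), 1)
    chars <- strsplit(s, "")[[1]]
    brute <- min(vapply(1:(300 - w + 1), function(i) {
      gc <- sum(chars[i:(i + w - 1)] %in% c("G", "C"))
      64.9 + 41 * (gc - 16.4) / w
    }, numeric(1)))
    expect_equal(melting_temperature(s, w), brute)
  }
})

test_that("a substitution changes Tm only through a governing window", {
  # AT-rich 50 bp core (10 G) flanked by pure G/C runs: the minimal window
  # is exactly the core, and flanking windows have dozens of GC units of
  # slack above it
  s <- paste0(strrep("G", 100), strrep("ATATG", 10), strrep("C", 100))
  w <- 50
  base <- melting_temperature(s, w)
  # G -> A inside the minimal window lowers the minimum strictly
  inside <- s
  substr(inside, 105, 105) <- "A"  # a G within the AT-rich core
  expect_equal(melting_temperature(inside, w), base - 41 / 50)
  # G -> A far outside every minimal window leaves the minimum unchanged
  outside <- s
  substr(outside, 1, 1) <- "A"
  expect_equal(melting_temperature(outside, w), base)
})

test_that("mobility is a calibrated strictly decreasing function of size", {
  b <- c(100, 3000)
  expect_gt(mobility(200, b), mobility(900, b))  # Ref1 runs ahead of Ref2
  expect_identical(mobility(500, b), mobility(500, b))
  expect_equal(mobility(100, b), 1)
  expect_equal(mobility(3000, b), 0)
  lens <- seq(150, 2900, by = 50)
  expect_true(all(diff(mobility(lens, b)) < 0))
  expect_error(mobility(0), "length")
})

test_that("undistorted profiles sit at model coordinates with nominal refs", {
  set.seed(33)
  genome <- random_dna(20000)
  params <- gp_params(distortion = no_distortion())
  sites <- find_binding_sites(genome, params$primer, params$max_mismatch,
                              params$anchor3)
  frags <- select_fragments(
    enumerate_amplicons(sites, genome, params$min_len, params$max_len),
    params$n_bands
  )
  raw <- profile_fragments(frags, distortion = no_distortion(), seed = 1)
  refs <- raw[raw$is_reference, ]
  expect_equal(refs$mobility_raw[refs$source == "Ref1"], mobility(200))
  expect_equal(refs$temp_raw[refs$source == "Ref1"], 60.0)
  expect_equal(refs$mobility_raw[refs$source == "Ref2"], mobility(900))
  expect_equal(refs$temp_raw[refs$source == "Ref2"], 61.4)
  smp <- raw[!raw$is_reference, ]
  expect_equal(smp$mobility_raw, mobility(frags$length))
  expect_equal(smp$temp_raw,
               vapply(frags$sequence, melting_temperature, numeric(1),
                      window = 50, USE.NAMES = FALSE))
})

test_that("a pure affine distortion is recoverable from the two references", {
  set.seed(34)
  genome <- random_dna(20000)
  params <- gp_params(distortion = distortion_spec(jitter_mobility = 0,
                                                   jitter_temp = 0))
  prof <- quiet_profile(genome, "x", params, seed = 9)
  raw <- attr(prof, "raw")
  refs <- raw[raw$is_reference, ]
  # solve the per-axis 2-point system and check it maps refs to nominal
  obs <- refs$temp_raw[match(c("Ref1", "Ref2"), refs$source)]
  sc <- (61.4 - 60.0) / (obs[2] - obs[1])
  off <- 60.0 - sc * obs[1]
  expect_equal(sc * obs + off, c(60.0, 61.4))
})

test_that("the measurement is a pure function of genome, params and seed", {
  set.seed(35)
  genome <- random_dna(20000)
  params <- gp_params()
  p1 <- quiet_profile(genome, "x", params, seed = 4)
  p2 <- quiet_profile(genome, "x", params, seed = 4)
  p3 <- quiet_profile(genome, "x", params, seed = 5)
  expect_identical(p1$spiddos, p2$spiddos)
  expect_false(identical(p1$spiddos, p3$spiddos))
})
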