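#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end pipeline with its default.  The
#' blocks mirror the pipeline stages: `tree` (geometry and mutation process),
#' `pcr` (random-PCR emulation), `tgge` (gel rendering and distortion),
#' `analysis` (clustering and replicate handling), plus the master `seed`.
#' Defaults describe a three-branch tree with branches 2 m apart and three
#' leaves per branch.
#'
#' @param tree,pcr,tgge,analysis named lists overriding individual defaults;
#'   unknown keys are rejected.
#' @param seed master seed.
#' @return an object of class `gp_config` (a nested named list).
#' @export
gp_config <- function(tree = list(), pcr = list(), tgge = list(),
                      analysis = list(), seed = 1L) {
  defaults <- list(
    tree = list(trunk_height = 5, branch_attach_heights = c(1, 3, 5),
                leaves_per_branch = 3L, branch_length = 0.1,
                unit_cell_length = 20e-6, genome_length = 1e5,
                mu_c = 1e-7, tree_label = "A"),
    pcr = list(primer_name = "HUNT", primer = "TGCTGCTGCTGC",
               max_mismatch = 4L, anchor3 = 3L, min_len = 200L,
               max_len = 2000L, n_bands = 10L),
    tgge = list(tm_window = 50L, mobility_min = 100, mobility_max = 3000,
                scale_mobility = c(0.9, 1.1), offset_mobility = c(-0.05, 0.05),
                scale_temp = c(0.95, 1.05), offset_temp = c(-1, 1),
                jitter_mobility = 0.005, jitter_temp = 0.005),
    analysis = list(ward_method = "ward.D", n_replicates = 1L,
                    replicate_mode = "mean")
  )
  merge_block <- function(block, override) {
    unknown <- setdiff(names(override), names(block))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    utils::modifyList(block, override)
  }
  cfg <- list(tree = merge_block(defaults$tree, tree),
              pcr = merge_block(defaults$pcr, pcr),
              tgge = merge_block(defaults$tgge, tgge),
              analysis = merge_block(defaults$analysis, analysis),
              seed = as.integer(seed))
  class(cfg) <- "gp_config"
  cfg
}

#' @export
print.gp_config <- function(x, ...) {
  for (block in c("tree", "pcr", "tgge", "analysis")) {
    for (key in names(x[[block]])) {
      cat(sprintf("%s.%s = %s\n", block, key,
                  paste(format(x[[block]][[key]]), collapse = ",")))
    }
  }
  cat("seed =", x$seed, "\n")
  invisible(x)
}

#' Read / write a run configuration as a plain key-value file
#'
#' The on-disk format is one `block.key = value` pair per line (comments
#' start with `#`); vector values are comma-separated.  Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path file path.
#' @return `read_gp_config()`: a [gp_config()].
#' @export
read_gp_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  blocks <- list(tree = list(), pcr = list(), tgge = list(),
                 analysis = list())
  seed <- 1L
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    if (anyNA(parsed)) parsed <- val  # keep strings (primer, labels) as-is
    if (key == "seed") { seed <- as.integer(parsed); next }
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% names(blocks)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    blocks[[parts[1]]][[parts[2]]] <- parsed
  }
  gp_config(tree = blocks$tree, pcr = blocks$pcr, tgge = blocks$tgge,
            analysis = blocks$analysis, seed = seed)
}

#' @rdname read_gp_config
#' @param config a [gp_config()].
#' @export
write_gp_config <- function(config, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (block in c("tree", "pcr", "tgge", "analysis")) {
    for (key in names(config[[block]])) {
      writeLines(sprintf("%s.%s = %s", block, key,
                         paste(format(config[[block]][[key]],
                                      scientific = FALSE, trim = TRUE),
                               collapse = ",")),
                 con)
    }
  }
  writeLines(sprintf("seed = %d", config$seed), con)
  invisible(path)
}

# Expand config blocks into the objects the stage functions expect.
config_tree_spec <- function(config, seed = config$seed) {
  t <- config$tree
  tree_spec(trunk_height = t$trunk_height,
            branch_attach_heights = t$branch_attach_heights,
            leaves_per_branch = t$leaves_per_branch,
            branch_length = t$branch_length,
            unit_cell_length = t$unit_cell_length,
            genome_length = t$genome_length,
            mu_c = t$mu_c,
            tree_label = t$tree_label,
            seed = seed)
}

config_gp_params <- function(config) {
  p <- config$pcr; tg <- config$tgge
  gp_params(primer = gp_primer(p$primer_name, p$primer),
            max_mismatch = p$max_mismatch, anchor3 = p$anchor3,
            min_len = p$min_len, max_len = p$max_len, n_bands = p$n_bands,
            tm_window = tg$tm_window,
            mobility_bounds = c(tg$mobility_min, tg$mobility_max),
            distortion = distortion_spec(
              scale_mobility = tg$scale_mobility,
              offset_mobility = tg$offset_mobility,
              scale_temp = tg$scale_temp,
              offset_temp = tg$offset_temp,
              jitter_mobility = tg$jitter_mobility,
              jitter_temp = tg$jitter_temp))
}
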