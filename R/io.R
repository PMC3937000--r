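#' Read and write multi-FASTA genome files
#'
#' Sequences are uppercased on read and validated as ACGT; labels are the
#' FASTA headers.  Writing then reading returns identical labels and
#' sequences.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences (possibly
#'   empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- names(set)
  for (i in seq_along(seqs)) check_dna(seqs[[i]], paste0("sequence ", i))
  seqs
}

#' @rdname read_fasta
#' @param seqs named character vector of ACGT sequences.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write / read raw pre-spiddo profiles as TSV
#'
#' One row per gel point with columns `sample`, `point_id`, `mobility_raw`,
#' `temp_raw`, `is_reference`, `source`.
#'
#' @param raws named list of raw-point data frames (one per sample), as
#'   produced by [profile_fragments()].
#' @param path file path.
#' @export
write_raw_tsv <- function(raws, path) {
  rows <- do.call(rbind, lapply(names(raws), function(s) {
    cbind(sample = s, raws[[s]][, c("point_id", "mobility_raw", "temp_raw",
                                    "is_reference", "source")])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_raw_tsv
#' @return `read_raw_tsv()`: named list of raw-point data frames.
#' @export
read_raw_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  split(tab[, setdiff(names(tab), "sample")], tab$sample)
}

#' Write / read spiddos tables as TSV
#'
#' The interchange format for normalized profiles (also the entry point for
#' user-digitized real gel data): columns `sample`, `point_id`,
#' `mobility_norm`, `temp_norm`.
#'
#' @param profiles list of [gp_profile()] objects.
#' @param path file path.
#' @export
write_spiddos_tsv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample = p$label,
               point_id = seq_len(p$n),
               mobility_norm = p$spiddos$mobility,
               temp_norm = p$spiddos$temp,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_spiddos_tsv
#' @return `read_spiddos_tsv()`: list of [gp_profile()] objects, one per
#'   sample, in file order.
#' @export
read_spiddos_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "mobility_norm", "temp_norm")
  if (!all(need %in% names(tab))) {
    stop("spiddos TSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  samples <- unique(tab$sample)
  lapply(samples, function(s) {
    sub <- tab[tab$sample == s, ]
    gp_profile(sub[, c("mobility_norm", "temp_norm")], label = s)
  })
}

#' Write / read a labelled square genomic distance matrix as TSV
#'
#' The matrix is stored with a header row and a leading label column, in
#' matching order.  On read the matrix is validated as square and symmetric
#' (tolerance 1e-9) with matching row/column labels.
#'
#' @param d symmetric distance matrix with dimnames.
#' @param path file path.
#' @export
write_dg_tsv <- function(d, path) {
  d <- as.matrix(d)
  tab <- data.frame(sample = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dg_tsv
#' @return `read_dg_tsv()`: the validated symmetric matrix.
#' @export
read_dg_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  labels <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (nrow(m) != ncol(m)) stop("distance matrix is not square",
                               call. = FALSE)
  if (!identical(labels, colnames(m))) {
    stop("row labels do not match column header order", call. = FALSE)
  }
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries",
                               call. = FALSE)
  if (max(abs(m - t(m))) > 1e-9) {
    stop("distance matrix is asymmetric beyond tolerance 1e-9",
         call. = FALSE)
  }
  m
}

#' Write a Newick dendrogram to file
#'
#' @param hc an [stats::hclust] object, or a Newick string.
#' @param path file path.
#' @export
write_newick <- function(hc, path) {
  nwk <- if (inherits(hc, "hclust")) to_newick(hc) else hc
  writeLines(nwk, path)
  invisible(path)
}
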