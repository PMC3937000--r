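#' Ward hierarchical clustering of a genomic distance matrix
#'
#' Agglomerative Ward clustering applied to the dG matrix.  The default
#' convention (`"ward.D"`) runs the Ward Lance-Williams update directly on
#' the supplied distances; `"ward.D2"` squares them first.  Samples are
#' ordered lexicographically by label before clustering so that ties resolve
#' deterministically regardless of input order.
#'
#' @param d symmetric distance matrix with zero diagonal and labelled
#'   dimnames (e.g. from [distance_matrix()] or [read_dg_tsv()]).
#' @param method `"ward.D"` (default) or `"ward.D2"`.
#' @return an [stats::hclust] object.
#' @export
ward_cluster <- function(d, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  if (any(!is.finite(d))) stop("distance matrix contains non-finite entries",
                               call. = FALSE)
  if (nrow(d) < 2L) stop("need at least two samples", call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  ord <- order(rownames(d))
  d <- d[ord, ord]
  stats::hclust(stats::as.dist(d), method = method)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from the merge heights (each merge height is
#' split evenly between the two joined subtrees), so cophenetic distances
#' between leaves are preserved by the export.
#'
#' @param hc an [stats::hclust] object (e.g. from [ward_cluster()]).
#' @return a single Newick string, terminated by `";"`.
#' @export
to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Merge table of a dendrogram
#'
#' @param hc an [stats::hclust] object.
#' @return data frame with one row per merge: `cluster_a`, `cluster_b`
#'   (negative = singleton leaf index, positive = earlier merge), `height`
#'   and `size` of the merged cluster.
#' @export
merge_table <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  sizes <- integer(nrow(hc$merge))
  size_of <- function(x) if (x < 0) 1L else sizes[x]
  for (i in seq_len(nrow(hc$merge))) {
    sizes[i] <- size_of(hc$merge[i, 1]) + size_of(hc$merge[i, 2])
  }
  data.frame(cluster_a = hc$merge[, 1], cluster_b = hc$merge[, 2],
             height = hc$height, size = sizes)
}

#' Branch labels implied by leaf labels
#'
#' Leaf labels follow the `"<tree><branch>-<leaf>"` scheme (`"A1-2"` = leaf 2
#' of branch 1 of tree A); the branch label is everything before the final
#' dash.
#'
#' @param labels character vector of leaf labels.
#' @return named character vector of branch labels.
#' @export
branch_labels <- function(labels) {
  out <- sub("-[^-]*$", "", labels)
  names(out) <- labels
  out
}

#' Planted-topology recovery score of a clustering
#'
#' Cuts the dendrogram into as many clusters as there are planted branches
#' and scores the agreement with the planted branch partition by the
#' adjusted Rand index (ARI; 1 = perfect recovery, 0 = chance level, negative
#' = worse than chance).  `score` rescales the ARI from `[-1, 1]` to
#' `[0, 1]` for reporting; assertions about recovery use the raw ARI.
#'
#' @param hc an [stats::hclust] object whose labels are leaf labels.
#' @param planted named character vector mapping each leaf label to its true
#'   branch (e.g. from [branch_labels()]).
#' @return list with `ari` (raw adjusted Rand index), `score`
#'   (`(ari + 1) / 2`), `k` (number of planted branches) and `clusters`
#'   (named cut assignment).
#' @export
topology_recovery <- function(hc, planted) {
  stopifnot(inherits(hc, "hclust"))
  if (!all(hc$labels %in% names(planted))) {
    stop("every leaf needs a planted branch label", call. = FALSE)
  }
  truth <- planted[hc$labels]
  k <- length(unique(truth))
  if (k > length(hc$labels)) stop("more planted branches than leaves",
                                  call. = FALSE)
  cl <- stats::cutree(hc, k = k)
  ari <- mclust::adjustedRandIndex(cl, truth)
  list(ari = ari, score = (ari + 1) / 2, k = k, clusters = cl)
}
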