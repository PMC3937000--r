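#' Specify a synthetic tree lineage experiment
#'
#' A `tree_spec` describes the physical geometry of a (botanical) tree and the
#' parameters of the somatic mutation process along its cell lineages.  The
#' geometry is a trunk with side branches attached at given heights; each
#' branch carries `leaves_per_branch` leaves spaced evenly along its length.
#' Physical distance is converted to cell generations through the unit cell
#' length `a`: a path of length `B` metres corresponds to `g' = B / a` cell
#' divisions under the single-file ("longitudinally tandem") cell lineage
#' model.
#'
#' @param trunk_height trunk height in metres.
#' @param branch_attach_heights heights (metres, nondecreasing, within
#'   `[0, trunk_height]`) at which branches attach to the trunk, ordered from
#'   the ground up.
#' @param leaves_per_branch number of leaves on each branch.
#' @param branch_length branch length in metres; leaf `j` of a branch sits at
#'   distance `j * branch_length / leaves_per_branch` from the trunk.
#' @param unit_cell_length unit cell length `a` in metres (default 20 um).
#' @param genome_length genome length `L` in bases.
#' @param mu_c per-base per-generation substitution rate.
#' @param tree_label single-letter tree label used in leaf names; leaf `j` of
#'   branch `b` of tree `A` is labelled `"Ab-j"` (e.g. `"A1-2"`).
#' @param seed integer seed used when the spec is simulated.
#'
#' @return an object of class `tree_spec`.
#' @seealso [build_lineage()], [simulate_leaf_genomes()]
#' @export
tree_spec <- function(trunk_height,
                      branch_attach_heights,
                      leaves_per_branch,
                      branch_length,
                      unit_cell_length = 20e-6,
                      genome_length = 1e5,
                      mu_c = 1e-7,
                      tree_label = "A",
                      seed = 1L) {
  check_scalar_number(trunk_height, "trunk_height", positive = TRUE)
  check_scalar_number(branch_length, "branch_length", positive = TRUE)
  check_scalar_number(unit_cell_length, "unit_cell_length", positive = TRUE)
  check_scalar_number(genome_length, "genome_length", positive = TRUE)
  check_scalar_number(mu_c, "mu_c", nonneg = TRUE)
  if (!is.numeric(branch_attach_heights) || length(branch_attach_heights) < 1L) {
    stop("branch_attach_heights must be a non-empty numeric vector",
         call. = FALSE)
  }
  if (any(branch_attach_heights < 0) ||
      any(branch_attach_heights > trunk_height)) {
    stop("branch_attach_heights must lie in [0, trunk_height]", call. = FALSE)
  }
  if (is.unsorted(branch_attach_heights)) {
    stop("branch_attach_heights must be nondecreasing (ground to top)",
         call. = FALSE)
  }
  leaves_per_branch <- as.integer(leaves_per_branch)
  if (leaves_per_branch < 1L) stop("leaves_per_branch must be >= 1",
                                   call. = FALSE)
  structure(
    list(trunk_height = trunk_height,
         branch_attach_heights = branch_attach_heights,
         leaves_per_branch = leaves_per_branch,
         branch_length = branch_length,
         unit_cell_length = unit_cell_length,
         genome_length = as.integer(genome_length),
         mu_c = mu_c,
         tree_label = tree_label,
         seed = as.integer(seed)),
    class = "tree_spec"
  )
}

#' @export
print.tree_spec <- function(x, ...) {
  cat("tree_spec:", length(x$branch_attach_heights), "branches x",
      x$leaves_per_branch, "leaves; trunk", x$trunk_height, "m\n")
  cat("  a =", format(x$unit_cell_length), "m; L =", x$genome_length,
      "b; mu_c =", format(x$mu_c), "/base/generation\n")
  invisible(x)
}

#' Build the cell-lineage tree of a tree specification
#'
#' Expands a [tree_spec()] into an explicit rooted lineage tree: trunk nodes at
#' each branch attachment height, a chain of nodes along each branch at the
#' leaf positions, and one leaf per position.  Every edge carries its physical
#' length and its cell-generation count `ceiling(length / a)` (so a 2 m edge
#' with `a` = 20 um contributes 1e5 generations).
#'
#' @param spec a [tree_spec()].
#' @return an object of class `lineage_tree`: a list with data frames `nodes`
#'   (`id`, `label`, `type`) and `edges` (`parent`, `child`, `length`,
#'   `generations`), plus the originating `spec`.
#' @export
build_lineage <- function(spec) {
  if (!inherits(spec, "tree_spec")) stop("spec must be a tree_spec",
                                         call. = FALSE)
  a <- spec$unit_cell_length
  nb <- length(spec$branch_attach_heights)
  nl <- spec$leaves_per_branch

  nodes <- data.frame(id = 1L, label = "root", type = "root",
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = integer(), child = integer(),
                      length = numeric(), generations = integer())
  add_node <- function(label, type) {
    id <- nrow(nodes) + 1L
    nodes[id, ] <<- list(id, label, type)
    id
  }
  add_edge <- function(parent, child, len) {
    edges[nrow(edges) + 1L, ] <<- list(parent, child, len,
                                       safe_ceiling(len / a))
    invisible(NULL)
  }

  prev <- 1L
  prev_h <- 0
  for (b in seq_len(nb)) {
    h <- spec$branch_attach_heights[b]
    attach <- add_node(sprintf("%s%d_attach", spec$tree_label, b), "trunk")
    add_edge(prev, attach, h - prev_h)
    prev <- attach
    prev_h <- h
    # chain of positions along the branch, one leaf hanging at each
    spacing <- spec$branch_length / nl
    chain <- attach
    for (j in seq_len(nl)) {
      pos <- add_node(sprintf("%s%d_p%d", spec$tree_label, b, j), "branch")
      add_edge(chain, pos, spacing)
      chain <- pos
      leaf <- add_node(sprintf("%s%d-%d", spec$tree_label, b, j), "leaf")
      add_edge(pos, leaf, 0)
    }
  }

  if (anyDuplicated(nodes$label[nodes$type == "leaf"])) {
    stop("leaf labels are not unique", call. = FALSE)  # defensive
  }
  structure(list(nodes = nodes, edges = edges, spec = spec),
            class = "lineage_tree")
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat("lineage_tree:", sum(x$nodes$type == "leaf"), "leaves,",
      nrow(x$edges), "edges,",
      sum(x$edges$generations), "total generations\n")
  invisible(x)
}

#' Leaf labels of a lineage tree
#' @param tree a `lineage_tree`.
#' @return character vector of leaf labels, in construction order.
#' @export
leaf_labels <- function(tree) {
  tree$nodes$label[tree$nodes$type == "leaf"]
}

# Root-to-node generation depth for every node, plus parent map.
node_depths <- function(tree) {
  parent <- integer(nrow(tree$nodes))
  gdepth <- integer(nrow(tree$nodes))
  ord <- tree$edges[order(tree$edges$child), ]
  parent[ord$child] <- ord$parent
  # nodes are created parent-before-child, so a single forward pass works
  for (i in seq_len(nrow(ord))) {
    gdepth[ord$child[i]] <- gdepth[ord$parent[i]] + ord$generations[i]
  }
  list(parent = parent, gdepth = gdepth)
}

# Set of ancestors (including self) of a node id.
ancestor_path <- function(parent, id) {
  path <- id
  while (id != 1L) {
    id <- parent[id]
    path <- c(path, id)
  }
  path
}

#' Ground-truth pairwise generational separations
#'
#' Computes, for every pair of leaves, the number of cell generations along
#' the unique tree path connecting them (sum of edge generation counts).  This
#' is the ground truth against which measured genomic distances are compared.
#'
#' @param tree a `lineage_tree` from [build_lineage()].
#' @param labels leaf labels to include (default: all leaves).
#' @return a symmetric integer matrix with zero diagonal, dimnames = labels.
#' @export
pairwise_generations <- function(tree, labels = leaf_labels(tree)) {
  if (!inherits(tree, "lineage_tree")) stop("tree must be a lineage_tree",
                                            call. = FALSE)
  all_labels <- tree$nodes$label
  idx <- match(labels, all_labels)
  if (anyNA(idx)) {
    stop("unknown leaf label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  nd <- node_depths(tree)
  paths <- lapply(idx, ancestor_path, parent = nd$parent)
  n <- length(idx)
  g <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(n)[-seq_len(i)]) {
      common <- intersect(paths[[i]], paths[[j]])
      lca <- common[which.max(nd$gdepth[common])]
      gij <- nd$gdepth[idx[i]] + nd$gdepth[idx[j]] - 2L * nd$gdepth[lca]
      g[i, j] <- g[j, i] <- as.integer(gij)
    }
  }
  g
}

#' Simulate leaf genomes by mutation accumulation along the lineage
#'
#' Starting from a root genome, walks the lineage tree and, on every edge,
#' draws a Poisson number of substitution events with mean
#' `mu_c * L * generations`, places each event at a uniformly random position
#' and substitutes a uniformly chosen different base.  Descendant edges
#' inherit the mutated sequence, so divergence between two leaves reflects
#' their generational separation.  Back mutations can occur (events are a true
#' Poisson process), so the event count from the root can exceed the Hamming
#' distance.
#'
#' @param tree a `lineage_tree`.
#' @param root optional root genome (single ACGT string).  When `NULL`, a
#'   uniform random genome of length `spec$genome_length` is generated.
#' @param mu_c per-base per-generation substitution rate (default: the
#'   spec's `mu_c`).
#' @param seed integer seed; identical seeds give byte-identical genomes.
#' @return an object of class `leaf_genomes`: list with `sequences` (named
#'   character vector, one per leaf), `mutations_from_root` (named integer
#'   event counts), `root` (the root sequence) and `genome_length`.
#' @export
simulate_leaf_genomes <- function(tree, root = NULL,
                                  mu_c = tree$spec$mu_c,
                                  seed = tree$spec$seed) {
  if (!inherits(tree, "lineage_tree")) stop("tree must be a lineage_tree",
                                            call. = FALSE)
  check_scalar_number(mu_c, "mu_c", nonneg = TRUE)
  with_seed_maybe(seed, {
    if (is.null(root)) {
      L <- tree$spec$genome_length
      root_vec <- sample.int(4L, L, replace = TRUE)
    } else {
      check_dna(root, "root genome")
      root_vec <- match(strsplit(root, "", fixed = TRUE)[[1]], DNA_BASES)
      L <- length(root_vec)
    }
    nd <- node_depths(tree)
    max_g <- max(nd$gdepth)
    if (mu_c * max_g > 1) {
      warning("expected substitution load exceeds one per base; ",
              "the Poisson substitution model is saturating", call. = FALSE)
    }
    seqs <- vector("list", nrow(tree$nodes))
    nmut <- integer(nrow(tree$nodes))
    seqs[[1L]] <- root_vec
    ord <- tree$edges[order(tree$edges$child), ]
    for (i in seq_len(nrow(ord))) {
      p <- ord$parent[i]; ch <- ord$child[i]
      s <- seqs[[p]]
      k <- stats::rpois(1L, mu_c * L * ord$generations[i])
      if (k > 0L) {
        pos <- sample.int(L, k, replace = TRUE)
        # events applied sequentially so repeated hits at one site compose
        for (q in seq_len(k)) {
          s[pos[q]] <- sample((1:4)[-s[pos[q]]], 1L)
        }
      }
      seqs[[ch]] <- s
      nmut[ch] <- nmut[p] + k
    }
    leaf_idx <- which(tree$nodes$type == "leaf")
    sequences <- vapply(
      seqs[leaf_idx],
      function(v) paste(DNA_BASES[v], collapse = ""), character(1)
    )
    names(sequences) <- tree$nodes$label[leaf_idx]
    mutations <- nmut[leaf_idx]
    names(mutations) <- names(sequences)
    structure(list(sequences = sequences,
                   mutations_from_root = mutations,
                   root = paste(DNA_BASES[root_vec], collapse = ""),
                   genome_length = L),
              class = "leaf_genomes")
  })
}

#' @export
print.leaf_genomes <- function(x, ...) {
  cat("leaf_genomes:", length(x$sequences), "leaves, L =", x$genome_length,
      "b; events from root:",
      paste(range(x$mutations_from_root), collapse = "-"), "\n")
  invisible(x)
}
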