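test_that("edge generation counts follow physical length over cell length", {
  spec <- tree_spec(trunk_height = 2, branch_attach_heights = 2,
                    leaves_per_branch = 1L, branch_length = 1e-9,
                    unit_cell_length = 20e-6, genome_length = 100)
  tree <- build_lineage(spec)
  trunk_edge <- tree$edges[tree$edges$parent == 1L, ]
  # 2 m at a = 20 um is exactly 1e5 cell generations
  expect_identical(trunk_edge$generations, 100000L)
  # a zero-length edge (leaf attachment) contributes zero generations
  expect_true(all(tree$edges$generations[tree$edges$length == 0] == 0L))
})

test_that("invalid tree specifications are rejected", {
  expect_error(tree_spec(2, 1, 1, 0.5, unit_cell_length = 0),
               "unit_cell_length")
  expect_error(tree_spec(2, c(1, 3), 1, 0.5), "trunk_height")
  expect_error(tree_spec(2, c(1.5, 1), 1, 0.5), "nondecreasing")
  expect_error(tree_spec(2, 1, 1, 0.5, mu_c = -1), "mu_c")
})

test_that("pairwise generations equal brute-force path sums over the tree", {
  spec <- tree_spec(trunk_height = 3, branch_attach_heights = c(0.5, 1.7, 3),
                    leaves_per_branch = 3L, branch_length = 0.31,
                    genome_length = 100)
  tree <- build_lineage(spec)
  g <- pairwise_generations(tree)

  # brute force: undirected adjacency walk between every leaf pair
  edges <- tree$edges
  adj <- lapply(seq_len(nrow(tree$nodes)), function(i) {
    rbind(edges[edges$parent == i, c("child", "generations")],
          stats::setNames(edges[edges$child == i, c("parent", "generations")],
                          c("child", "generations")))
  })
  path_gen <- function(from, to) {
    # BFS carrying cumulative generations (tree => unique path)
    seen <- rep(FALSE, nrow(tree$nodes))
    queue <- list(list(node = from, g = 0L))
    seen[from] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      if (cur$node == to) return(cur$g)
      nb <- adj[[cur$node]]
      for (r in seq_len(nrow(nb))) {
        if (!seen[nb$child[r]]) {
          seen[nb$child[r]] <- TRUE
          queue <- c(queue, list(list(node = nb$child[r],
                                      g = cur$g + nb$generations[r])))
        }
      }
    }
    stop("unreachable")
  }
  leaves <- which(tree$nodes$type == "leaf")
  labs <- tree$nodes$label[leaves]
  for (i in seq_along(leaves)) {
    for (j in seq_along(leaves)) {
      expect_equal(g[labs[i], labs[j]],
                   if (i == j) 0L else path_gen(leaves[i], leaves[j]))
    }
  }
})

test_that("generational separation is a metric on the leaves", {
  spec <- tree_spec(trunk_height = 4, branch_attach_heights = c(1, 2, 4),
                    leaves_per_branch = 2L, branch_length = 0.2,
                    genome_length = 100)
  g <- pairwise_generations(build_lineage(spec))
  expect_true(all(g >= 0))
  expect_identical(g, t(g))
  expect_true(all(diag(g) == 0))
  n <- nrow(g)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_true(g[i, j] <= g[i, k] + g[k, j])
  }
  expect_error(pairwise_generations(build_lineage(spec), labels = "nope"),
               "unknown leaf")
})

test_that("zero mutation rate leaves every genome identical to the root", {
  spec <- tree_spec(trunk_height = 2, branch_attach_heights = c(1, 2),
                    leaves_per_branch = 2L, branch_length = 0.1,
                    genome_length = 500, mu_c = 0)
  tree <- build_lineage(spec)
  gen <- simulate_leaf_genomes(tree, seed = 5)
  expect_true(all(gen$sequences == gen$root))
  expect_true(all(gen$mutations_from_root == 0L))
})

test_that("substitution counts follow the Poisson accumulation model", {
  # single 2 cm edge: 1000 generations; mu_c 1e-6 on a 1e5 base genome
  # gives expected count lambda = 100 per replicate
  spec <- tree_spec(trunk_height = 0.02, branch_attach_heights = 0.02,
                    leaves_per_branch = 1L, branch_length = 1e-9,
                    genome_length = 1e5, mu_c = 1e-6)
  tree <- build_lineage(spec)
  lambda <- 1e-6 * 1e5 * sum(tree$edges$generations)
  counts <- vapply(1:200, function(s) {
    simulate_leaf_genomes(tree, seed = s)$mutations_from_root[[1]]
  }, numeric(1))
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # event count can exceed Hamming distance only through back mutation
  gen <- simulate_leaf_genomes(tree, seed = 1)
  expect_gte(gen$mutations_from_root[[1]],
             hamming(gen$root, gen$sequences[[1]]))
})

test_that("identical seeds give byte-identical genomes", {
  spec <- tree_spec(trunk_height = 2, branch_attach_heights = c(1, 2),
                    leaves_per_branch = 2L, branch_length = 0.1,
                    genome_length = 2000, mu_c = 1e-6)
  tree <- build_lineage(spec)
  g1 <- simulate_leaf_genomes(tree, seed = 7)
  g2 <- simulate_leaf_genomes(tree, seed = 7)
  g3 <- simulate_leaf_genomes(tree, seed = 8)
  expect_identical(g1$sequences, g2$sequences)
  expect_false(all(g1$sequences == g3$sequences))
})

test_that("Hamming distance grows with generational separation", {
  # 50 pairs spanning expected counts ~1..100
  set.seed(31)
  L <- 2000
  root <- random_dna(L)
  g_vals <- round(10^seq(log10(500), log10(50000), length.out = 50))
  mu <- 1e-6
  hd <- vapply(seq_along(g_vals), function(i) {
    spec <- tree_spec(trunk_height = 1, branch_attach_heights = 0.5,
                      leaves_per_branch = 1L,
                      branch_length = g_vals[i] * 20e-6,
                      genome_length = L, mu_c = mu)
    tree <- build_lineage(spec)
    gen <- simulate_leaf_genomes(tree, root = root, mu_c = mu, seed = 100 + i)
    hamming(root, gen$sequences[[1]])
  }, numeric(1))
  expect_gt(cor(g_vals, hd, method = "spearman"), 0.9)
})

test_that("non-ACGT root genomes are rejected", {
  spec <- tree_spec(trunk_height = 1, branch_attach_heights = 1,
                    leaves_per_branch = 1L, branch_length = 0.1,
                    genome_length = 100)
  tree <- build_lineage(spec)
  expect_error(simulate_leaf_genomes(tree, root = "ACGTN"), "A/C/G/T")
})
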