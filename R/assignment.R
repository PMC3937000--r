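#' Minimum-cost bipartite assignment
#'
#' Solves the rectangular linear assignment problem (Hungarian algorithm,
#' shortest-augmenting-path formulation with potentials).  Every row is
#' assigned to a distinct column so that the total cost is minimal; when
#' there are more rows than columns the problem is solved on the transpose,
#' so `min(nrow, ncol)` pairs are always produced.
#'
#' @param cost numeric cost matrix (finite entries).
#' @return list with `pairs` (two-column integer matrix of (row, col)
#'   indices, ordered by row) and `cost` (the minimal total cost).
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) stop("cost matrix must be finite", call. = FALSE)
  transposed <- FALSE
  if (nrow(cost) > ncol(cost)) {
    cost <- t(cost)
    transposed <- TRUE
  }
  n <- nrow(cost)
  m <- ncol(cost)
  # potentials u (rows), v (columns); p[j+1] = row matched to column j,
  # column 0 is the sentinel that carries the row being inserted.
  u <- numeric(n + 1L)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1L])  # unused column indices (1-based)
      cur <- cost[i0, free] - u[i0 + 1L] - v[free + 1L]
      upd <- cur < minv[free + 1L]
      if (any(upd)) {
        minv[free[upd] + 1L] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      sel <- which.min(minv[free + 1L])
      delta <- minv[free[sel] + 1L]
      j1 <- free[sel]
      used_idx <- which(used)
      u[p[used_idx] + 1L] <- u[p[used_idx] + 1L] + delta
      v[used_idx] <- v[used_idx] - delta
      minv[free + 1L] <- minv[free + 1L] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  pairs <- cbind(row = p[-1L], col = seq_len(m))
  pairs <- pairs[pairs[, 1L] != 0L, , drop = FALSE]
  total <- sum(cost[pairs])
  if (transposed) pairs <- pairs[, 2:1, drop = FALSE]
  colnames(pairs) <- c("row", "col")
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  list(pairs = pairs, cost = total)
}
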