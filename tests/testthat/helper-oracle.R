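# Independent brute-force oracle for theta-WTA, written against the
# definition rather than the implementation: threshold the admissible values,
# label candidate components by union-find (the implementation uses flood
# fill), and return the component containing the lexicographic argmax.
oracle_theta_wta <- function(grid, theta, mask = NULL, connectivity = 8) {
  nr <- nrow(grid); nc <- ncol(grid)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  vals <- grid[mask]
  m <- max(vals)
  if (m <= 0) return(list(region = matrix(0L, 0, 2), peak = NULL))
  # lexicographic argmax among admissible units (smallest row, then column)
  hits <- which(mask & grid == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  best <- unname(c(hits[1, 1], hits[1, 2]))
  # union-find over candidate cells
  cand <- which(mask & grid >= (1 - theta) * m, arr.ind = TRUE)
  n <- nrow(cand)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  idx_of <- function(r, c) which(cand[, 1] == r & cand[, 2] == c)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    dr <- abs(cand[i, 1] - cand[j, 1]); dc <- abs(cand[i, 2] - cand[j, 2])
    adj <- if (connectivity == 8) max(dr, dc) == 1 else dr + dc == 1
    if (adj) { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
  }
  pk <- idx_of(best[1], best[2])
  root <- find(pk)
  keep <- vapply(seq_len(n), function(i) find(i) == root, TRUE)
  region <- cand[keep, , drop = FALSE]
  region <- region[order(region[, 1], region[, 2]), , drop = FALSE]
  dimnames(region) <- NULL
  list(region = region, peak = best)
}

# enumerate all n x n grids over a value alphabet as an iterator-free matrix
all_grids <- function(n, values) {
  g <- expand.grid(rep(list(values), n * n))
  as.matrix(g)
}
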