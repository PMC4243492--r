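# Small shared numerics: seeded evaluation, connected components, Chebyshev
# dilation, box filtering, rasterization. These are deliberately dependency-free;
# everything operates on plain numeric/logical matrices indexed (row, col).

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the global RNG state so generators are pure functions of
#' their seed and never perturb a caller's random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Lexicographically smallest argmax of a matrix
#'
#' Ties are broken by smallest row, then smallest column.
#' @param m numeric matrix
#' @return c(row, col) of the maximum, or NULL if all values are -Inf/NA
#' @keywords internal
argmax_lex <- function(m) {
  mx <- suppressWarnings(max(m, na.rm = TRUE))
  if (!is.finite(mx)) return(NULL)
  hits <- which(m == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(hits[1, 1], hits[1, 2])
}

#' Label connected components of a logical matrix
#'
#' Iterative flood fill (no recursion), 4- or 8-connectivity.
#' @param mask logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of component labels (0 = background)
#' @keywords internal
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  if (!any(mask)) return(lab)
  if (connectivity == 8) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  nextlab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    stack <- start
    lab[start] <- nextlab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      cc <- ((cur - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r2 <- r + dr[k]; c2 <- cc + dc[k]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          j <- (c2 - 1L) * nr + r2
          if (mask[j] && lab[j] == 0L) {
            lab[j] <- nextlab
            stack <- c(stack, j)
          }
        }
      }
    }
  }
  lab
}

#' Chebyshev (square) dilation of a logical mask
#' @param mask logical matrix
#' @param radius integer >= 0
#' @return logical matrix, TRUE within Chebyshev distance `radius` of mask
#' @keywords internal
dilate_chebyshev <- function(mask, radius) {
  if (radius <= 0 || !any(mask)) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- mask
  # separable: dilate rows then columns
  for (d in seq_len(radius)) {
    shifted_up <- rbind(out[-1, , drop = FALSE], matrix(FALSE, 1, nc))
    shifted_dn <- rbind(matrix(FALSE, 1, nc), out[-nr, , drop = FALSE])
    out <- out | shifted_up | shifted_dn
  }
  for (d in seq_len(radius)) {
    shifted_l <- cbind(out[, -1, drop = FALSE], matrix(FALSE, nr, 1))
    shifted_r <- cbind(matrix(FALSE, nr, 1), out[, -nc, drop = FALSE])
    out <- out | shifted_l | shifted_r
  }
  out
}

#' Box-mean filter with replicate padding
#'
#' Mean over a (2*half+1)^2 window; edges use replicated borders so constant
#' inputs stay constant (a uniform image has zero center--surround contrast).
#' @param m numeric matrix
#' @param half half-width of the square window
#' @return filtered matrix, same dimensions
#' @keywords internal
box_mean <- function(m, half) {
  if (half <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2 * half) - half, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * half) - half, 1L), nc)
  p <- m[ri, ci, drop = FALSE]
  # integral image
  s <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  w <- 2L * half + 1L
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  tot <- s[r0 + w, c0 + w, drop = FALSE] - s[r0, c0 + w, drop = FALSE] -
    s[r0 + w, c0, drop = FALSE] + s[r0, c0, drop = FALSE]
  tot / (w * w)
}

#' Disk mask around a center
#' @param nr,nc matrix dims
#' @param center c(row, col)
#' @param radius Euclidean radius in pixels
#' @return logical matrix
#' @keywords internal
disk_mask <- function(nr, nc, center, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

#' Rasterize a line segment (Bresenham)
#' @param p0,p1 endpoints c(row, col), integer
#' @return matrix of pixel coords, one row per pixel, inclusive of endpoints
#' @keywords internal
bresenham <- function(p0, p1) {
  r0 <- p0[1]; c0 <- p0[2]; r1 <- p1[1]; c1 <- p1[2]
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  out <- matrix(0L, dr + dc + 1L, 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    out[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  out[seq_len(n), , drop = FALSE]
}

#' Set pixels in a matrix from an n x 2 coordinate matrix, clipped to bounds
#' @keywords internal
set_pixels <- function(m, coords, value = 1) {
  if (is.null(coords) || nrow(coords) == 0) return(m)
  keep <- coords[, 1] >= 1 & coords[, 1] <= nrow(m) &
    coords[, 2] >= 1 & coords[, 2] <= ncol(m)
  coords <- coords[keep, , drop = FALSE]
  m[cbind(coords[, 1], coords[, 2])] <- value
  m
}

#' Coordinates of TRUE cells as an n x 2 matrix (row, col)
#' @keywords internal
mask_coords <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  dimnames(w) <- NULL
  w[order(w[, 1], w[, 2]), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
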