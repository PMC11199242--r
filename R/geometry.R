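#' Synthetic unit-sphere sensor layout
#'
#' Places `n` sensors quasi-uniformly on the upper ~3/4 of the unit sphere
#' (a Fibonacci lattice restricted to z > z_min), emulating a scalp montage:
#' real nets do not cover the lower face/neck region.
#'
#' @param n number of channels.
#' @param z_min lowest allowed z coordinate (default -0.4).
#' @return n x 3 matrix of unit vectors; row 1 is the vertex-most sensor.
#' @export
sphere_layout <- function(n, z_min = -0.4) {
  stopifnot(n >= 2L)
  i <- seq_len(n) - 0.5
  # map onto the spherical cap z in (z_min, 1)
  z <- 1 - (1 - z_min) * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pos <- cbind(r * cos(phi), r * sin(phi), z, deparse.level = 0)
  dimnames(pos) <- NULL
  pos[order(-pos[, 3]), , drop = FALSE]
}

#' Nearest-neighbor graph on the sensor sphere
#'
#' For every channel, its `k` nearest neighbors by great-circle distance.
#' The relation is not symmetrized; no channel is its own neighbor.
#'
#' @param positions n x 3 unit-sphere coordinates.
#' @param k neighbors per channel (default 6).
#' @return object of class `"neighbor_graph"`: list with `neighbors`
#'   (n x k integer matrix) and `k`.
#' @export
neighbor_graph <- function(positions, k = 6L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must be in [1, n_channels - 1]")
  nrm <- sqrt(rowSums(positions^2))
  u <- positions / nrm
  # great-circle distance is monotone in -cosine similarity
  cs <- tcrossprod(u)
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(-cs[i, ])
    nb[i, ] <- ord[ord != i][seq_len(k)]
  }
  structure(list(neighbors = nb, k = k), class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph: %d channels, k = %d>\n",
              nrow(x$neighbors), x$k))
  invisible(x)
}
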