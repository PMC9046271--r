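# Independent brute-force oracles and small fixture builders. The oracles
# deliberately avoid the package's expanding-box / half-neighborhood code
# paths: they enumerate everything.

# corrected distance from `point` to every background voxel of the whole
# volume; mean of the 4 smallest (or of all, if fewer exist)
oracle_radius <- function(volume, point, correction = TRUE) {
  d <- dim(volume$data)
  bg <- which(volume$data == 0L)
  if (length(bg) == 0L) return(NA_real_)
  idx <- arrayInd(bg, d) - 1L
  del <- abs(sweep(idx, 2, as.integer(point)))
  phys <- sweep(del, 2, volume$resolution, `*`)
  dist <- sqrt(rowSums(phys^2))
  if (correction) {
    ax <- which(rowSums(del != 0) == 1L)
    if (length(ax)) {
      a <- max.col(del[ax, , drop = FALSE] != 0, ties.method = "first")
      r <- volume$resolution[a]
      dist[ax] <- del[cbind(ax, a)] * r - r / 2
    }
  }
  mean(sort(dist)[seq_len(min(4L, length(dist)))])
}

# all-pairs 26-adjacency edge set (sorted two-column matrix of indices)
oracle_edges <- function(coords) {
  n <- nrow(coords)
  out <- matrix(integer(0), ncol = 2)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    ch <- pmax(
      abs(coords[(i + 1L):n, 1] - coords[i, 1]),
      abs(coords[(i + 1L):n, 2] - coords[i, 2]),
      abs(coords[(i + 1L):n, 3] - coords[i, 3]))
    j <- which(ch <= 1L) + i
    if (length(j)) out <- rbind(out, cbind(i, j))
  }
  out
}

sorted_edges <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  storage.mode(el) <- "integer"
  if (nrow(el) == 0L) return(matrix(integer(0), ncol = 2))
  el <- t(apply(el, 1, sort))
  el[order(el[, 1], el[, 2]), , drop = FALSE]
}

# random multi-tube phantom in a small volume, deterministic per seed
random_tube_phantom <- function(seed, dims = c(32, 32, 32), n_tubes = 2,
                                radius = c(1.5, 2.5)) {
  set.seed(seed)
  prims <- lapply(seq_len(n_tubes), function(i) {
    r <- stats::runif(1, radius[1], radius[2])
    lo <- r + 2.5
    a <- stats::runif(3, lo, dims - 1 - lo)
    b <- stats::runif(3, lo, dims - 1 - lo)
    tube_primitive(a, b, r)
  })
  render_phantom(phantom_spec(prims, dims = dims, seed = seed))
}

# toy vessel graph straight from coordinates/radii/edges (bypasses
# volumes entirely; for clique/prune unit tests)
make_vgraph <- function(coords, radii, edges = NULL) {
  g <- igraph::make_empty_graph(n = nrow(coords), directed = FALSE)
  igraph::V(g)$z <- coords[, 1]
  igraph::V(g)$y <- coords[, 2]
  igraph::V(g)$x <- coords[, 3]
  igraph::V(g)$radius <- radii
  if (!is.null(edges) && length(edges)) {
    g <- igraph::add_edges(g, as.vector(t(edges)))
  }
  g
}

# straight 1-voxel-thick line volume along x
line_volume <- function(n = 20, pad = 2, resolution = 1) {
  d <- c(1 + 2 * pad, 1 + 2 * pad, n + 2 * pad)
  m <- array(0L, d)
  m[pad + 1, pad + 1, pad + seq_len(n)] <- 1L
  vasc_volume(m, resolution)
}

# vasc_skeleton from 0-based coordinates
skeleton_from_coords <- function(coords, dims) {
  m <- array(0L, dims)
  m[coords + 1L] <- 1L
  vascnet:::skeleton_from_mask(m)
}
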