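#' The 13-offset half neighborhood
#'
#' The half of the 26-neighborhood oriented towards `(z_max, y_max,
#' x_max)`: of every antipodal offset pair exactly one member is included,
#' so scanning each centerline point against only these offsets visits
#' every neighbor pair once and cannot create parallel edges.
#'
#' @return a `(13, 3)` integer matrix of `(z, y, x)` offsets.
#' @export
half_neighborhood <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1,
                             KEEP.OUT.ATTRS = FALSE))
  keep <- g[, 1] > 0 |
    (g[, 1] == 0 & g[, 2] > 0) |
    (g[, 1] == 0 & g[, 2] == 0 & g[, 3] > 0)
  m <- g[keep, , drop = FALSE]
  dimnames(m) <- list(NULL, c("z", "y", "x"))
  m
}

#' Build the undirected centerline graph
#'
#' Creates one vertex per skeleton point (indexed in the lexicographic
#' coordinate emission order) carrying `z`, `y`, `x` voxel coordinates and
#' a `radius` attribute, then scans the 13-offset half neighborhood of
#' every point through a spatial hash to connect 26-adjacent points.
#' Unidirectional scanning guarantees no self-loops or parallel edges.
#'
#' @param skeleton a [skeletonize()] result.
#' @param radii numeric radius per skeleton point (index-aligned), e.g.
#'   from [estimate_radii()].
#' @return an [igraph::graph] with vertex attributes `z`, `y`, `x`
#'   (0-based voxel indices) and `radius`.
#' @export
build_graph <- function(skeleton, radii) {
  stopifnot(inherits(skeleton, "vasc_skeleton"))
  coords <- skeleton$coords
  n <- nrow(coords)
  if (length(radii) != n) {
    stop("`radii` length (", length(radii),
         ") does not match skeleton point count (", n, ")", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 0L) {
    igraph::V(g)$z <- coords[, 1]
    igraph::V(g)$y <- coords[, 2]
    igraph::V(g)$x <- coords[, 3]
    igraph::V(g)$radius <- as.numeric(radii)
  } else {
    g <- igraph::set_vertex_attr(g, "z", value = numeric(0))
    g <- igraph::set_vertex_attr(g, "y", value = numeric(0))
    g <- igraph::set_vertex_attr(g, "x", value = numeric(0))
    g <- igraph::set_vertex_attr(g, "radius", value = numeric(0))
    return(g)
  }
  # spatial hash: linearized coordinate key matched against vertex keys
  d <- apply(coords, 2, max) + 2
  key <- function(m) m[, 1] + d[1] * (m[, 2] + d[2] * m[, 3])
  k0 <- key(coords)
  offs <- half_neighborhood()
  from <- integer(0); to <- integer(0)
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(coords, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 0 & nb[, 2] >= 0 & nb[, 3] >= 0
    hit <- rep(NA_integer_, n)
    hit[ok] <- match(key(nb[ok, , drop = FALSE]), k0)
    src <- which(!is.na(hit))
    if (length(src)) {
      from <- c(from, src)
      to <- c(to, hit[src])
    }
  }
  if (length(from)) {
    g <- igraph::add_edges(g, rbind(from, to))
  }
  g
}

#' Classify vertices by degree
#'
#' Endpoints are degree-1 vertices (isolated degree-0 vertices are
#' reported as endpoints too), path vertices have degree 2, branchpoints
#' have degree > 2.
#'
#' @param graph a vessel graph from [build_graph()].
#' @return character vector (`"endpoint"`, `"path"`, `"branchpoint"`) per
#'   vertex.
#' @export
classify_vertices <- function(graph) {
  deg <- igraph::degree(graph)
  out <- rep("path", length(deg))
  out[deg <= 1L] <- "endpoint"
  out[deg > 2L] <- "branchpoint"
  out
}

# vertex coordinate matrix (n, 3), 0-based (z, y, x)
vertex_coords <- function(graph) {
  cbind(z = igraph::V(graph)$z, y = igraph::V(graph)$y, x = igraph::V(graph)$x)
}

#' Export a vessel graph
#'
#' Writes a graph (centerline-level or reduced segment-level) as GraphML
#' or as edge-list plus vertex-table CSV, keeping the coordinate and
#' radius attributes.
#'
#' @param graph an igraph vessel graph.
#' @param path output path; for `format = "csv"` two files are written,
#'   `<path>_vertices.csv` and `<path>_edges.csv` (any `.csv` extension on
#'   `path` is stripped first).
#' @param format `"graphml"` or `"csv"`.
#' @return the path(s) written, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  stem <- sub("\\.csv$", "", path)
  vdf <- igraph::as_data_frame(graph, what = "vertices")
  vdf <- cbind(vertex = seq_len(igraph::vcount(graph)), vdf)
  edf <- igraph::as_data_frame(graph, what = "edges")
  vp <- paste0(stem, "_vertices.csv")
  ep <- paste0(stem, "_edges.csv")
  utils::write.csv(vdf, vp, row.names = FALSE)
  utils::write.csv(edf, ep, row.names = FALSE)
  invisible(c(vp, ep))
}
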