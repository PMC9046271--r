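#' Segment length along a B-spline
#'
#' Fits a clamped uniform B-spline of degree `min(3, n - 1)` using the
#' segment's physically scaled centerline coordinates as control points
#' (Cox-de Boor basis via [splines::splineDesign()]), samples `k` points
#' along the curve and returns the polyline length. Chained voxel-to-voxel
#' edges overestimate length on diagonal staircases; the spline smooths
#' the path the way the vessel actually runs.
#'
#' @param path_coords `(n, 3)` matrix of voxel coordinates, `(z, y, x)`
#'   order, in path order.
#' @param resolution length-3 physical units per voxel, `(z, y, x)`.
#' @param k number of sample points along the spline; default
#'   `max(2, 2 * n)`.
#' @return length in physical units (0 for a single point).
#' @export
segment_length <- function(path_coords, resolution = c(1, 1, 1), k = NULL) {
  if (is.null(dim(path_coords))) path_coords <- matrix(path_coords, ncol = 3)
  n <- nrow(path_coords)
  if (n < 2L) return(0)
  pts <- spline_points(path_coords, resolution, k)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Sample points along the segment B-spline
#'
#' Short paths (up to 6 vertices) use the vertex coordinates directly as
#' control points of a clamped B-spline of degree `min(3, n - 1)`. Longer
#' paths are fitted by least-squares B-spline approximation with one
#' control point per `control_div` path vertices under chord-length
#' parameterization, with the curve clamped to the exact path endpoints:
#' voxel centerlines carry half-voxel staircase jitter, and an
#' interpolating spline through every voxel systematically inflates the
#' measured length, while the approximating spline runs through the
#' middle of the staircase.
#'
#' @inheritParams segment_length
#' @param control_div path vertices per control point in the
#'   least-squares fit.
#' @return a `(k, 3)` matrix of physically scaled points along the curve.
#' @export
spline_points <- function(path_coords, resolution = c(1, 1, 1), k = NULL,
                          control_div = 3) {
  if (is.null(dim(path_coords))) path_coords <- matrix(path_coords, ncol = 3)
  n <- nrow(path_coords)
  P <- sweep(path_coords, 2, rep_len(resolution, 3L), `*`)
  if (n == 1L) return(P)
  if (is.null(k)) k <- max(2L, 2L * n)
  bspline_eval <- function(ctrl, p) {
    m <- nrow(ctrl)
    knots <- c(rep(0, p + 1L), seq_len(m - p - 1L) / (m - p), rep(1, p + 1L))
    u <- seq(0, 1, length.out = k)
    u[k] <- 1 - 1e-10 # right-boundary support convention
    pts <- splines::splineDesign(knots, u, ord = p + 1L) %*% ctrl
    pts[k, ] <- ctrl[m, ] # clamped: curve ends at the last control point
    pts
  }
  if (n <= 6L) {
    return(bspline_eval(P, min(3L, n - 1L)))
  }
  m <- max(4L, ceiling(n / control_div))
  p <- 3L
  fit <- tryCatch({
    # chord-length parameters of the path vertices
    d <- c(0, cumsum(sqrt(rowSums(diff(P)^2))))
    u <- pmin(d / d[n], 1 - 1e-10)
    knots <- c(rep(0, p + 1L), seq_len(m - p - 1L) / (m - p), rep(1, p + 1L))
    B <- splines::splineDesign(knots, u, ord = p + 1L)
    ctrl <- qr.solve(B, P)
    ctrl[1L, ] <- P[1L, ]; ctrl[m, ] <- P[n, ]
    ctrl
  }, error = function(e) NULL)
  if (is.null(fit)) return(bspline_eval(P, p)) # degenerate fit: interpolate
  bspline_eval(fit, p)
}

#' Arc-chord tortuosity
#'
#' Segment spline length divided by the Euclidean distance between the
#' segment start and end points. Closed loops (zero chord) have undefined
#' tortuosity and return `NA`; they are excluded from network averages.
#'
#' @param length segment length in physical units.
#' @param start,end length-3 physical coordinates of the segment ends.
#' @return dimensionless tortuosity >= 1 (up to spline tolerance), or
#'   `NA` for a closed loop.
#' @export
segment_tortuosity <- function(length, start, end) {
  chord <- sqrt(sum((as.numeric(start) - as.numeric(end))^2))
  if (chord == 0) return(NA_real_)
  length / chord
}

#' Extract vessel segments from the filtered graph
#'
#' Removes branchpoints (degree > 2 vertices) and treats every remaining
#' connected component as one vessel segment, ordered end to end.
#' Adjoining branchpoints are recorded as segment boundaries, and their
#' coordinates are appended to the segment path (so inter-junction
#' lengths are not underestimated); radius statistics later use interior
#' vertices only.
#'
#' @param graph a filtered, pruned vessel graph.
#' @return list of segment records: `vertex_path` (full-graph vertex
#'   ids, interior only), `boundary` (adjoining branchpoint ids, 0-2),
#'   `path_coords` (voxel coordinates including appended boundaries) and
#'   `interior_idx` (rows of `path_coords` that are interior vertices).
#' @export
extract_segments <- function(graph) {
  if (igraph::vcount(graph) == 0L) return(list())
  deg <- igraph::degree(graph)
  co <- vertex_coords(graph)
  out <- list()
  for (seg in .segment_components(graph)) {
    path <- .order_component(graph, seg$vids)
    # branchpoint attached to each end of the path (if any)
    ends <- unique(c(path[1], path[length(path)]))
    bnd_first <- bnd_last <- integer(0)
    nb1 <- as.integer(igraph::neighbors(graph, path[1]))
    bp1 <- sort(nb1[deg[nb1] > 2L])
    if (length(bp1)) bnd_first <- bp1[1]
    nbl <- as.integer(igraph::neighbors(graph, path[length(path)]))
    bpl <- sort(nbl[deg[nbl] > 2L])
    bpl <- setdiff(bpl, bnd_first)
    if (length(bpl)) bnd_last <- bpl[1]
    if (length(path) == 1L && length(bnd_first) && length(bnd_last) == 0L) {
      # single interior vertex bridging two branchpoints
      rest <- setdiff(bp1, bnd_first)
      if (length(rest)) bnd_last <- rest[1]
    }
    pc <- co[path, , drop = FALSE]
    interior <- seq_len(nrow(pc))
    if (length(bnd_first)) {
      pc <- rbind(co[bnd_first, ], pc)
      interior <- interior + 1L
    }
    if (length(bnd_last)) pc <- rbind(pc, co[bnd_last, ])
    # cycle component (edges == vertices): close the loop so the zero
    # chord marks its tortuosity as undefined
    if (length(path) > 2L && length(bnd_first) == 0L &&
        length(bnd_last) == 0L &&
        igraph::ecount(igraph::induced_subgraph(graph, path)) ==
          length(path)) {
      pc <- rbind(pc, pc[1L, ])
    }
    anchor_first <- if (length(bnd_first)) bnd_first else path[1]
    anchor_last <- if (length(bnd_last)) bnd_last else path[length(path)]
    out[[length(out) + 1L]] <- list(
      vertex_path = path,
      boundary = c(bnd_first, bnd_last),
      anchor = c(anchor_first, anchor_last),
      path_coords = pc,
      interior_idx = interior
    )
  }
  out
}

#' Per-segment morphometric features
#'
#' Computes for every extracted segment the B-spline length, arc-chord
#' tortuosity, radius statistics over interior vertices, and the lateral
#' surface area `2*pi*r_mean*length` and volume `pi*r_mean^2*length` of
#' the equivalent cylinder.
#'
#' @param graph a filtered, pruned vessel graph.
#' @param resolution length-3 physical units per voxel, `(z, y, x)`.
#' @param segments optional precomputed [extract_segments()] result.
#' @return a data.frame with one row per segment: `segment`,
#'   `n_vertices`, `length`, `tortuosity`, `radius_mean`, `radius_min`,
#'   `radius_max`, `radius_sd`, `surface_area`, `volume`.
#' @export
segment_features <- function(graph, resolution = c(1, 1, 1),
                             segments = NULL) {
  if (is.null(segments)) segments <- extract_segments(graph)
  rad <- igraph::V(graph)$radius
  res <- rep_len(resolution, 3L)
  rows <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    len <- segment_length(s$path_coords, res)
    pc <- sweep(s$path_coords, 2, res, `*`)
    tort <- if (nrow(pc) < 2L) NA_real_ else
      segment_tortuosity(len, pc[1, ], pc[nrow(pc), ])
    r <- rad[s$vertex_path]
    r <- r[is.finite(r)]
    if (length(r) == 0L) r <- NA_real_
    rm <- mean(r)
    data.frame(
      segment = i, n_vertices = length(s$vertex_path), length = len,
      tortuosity = tort, radius_mean = rm, radius_min = min(r),
      radius_max = max(r), radius_sd = if (length(r) > 1L) stats::sd(r) else 0,
      surface_area = 2 * pi * rm * len, volume = pi * rm^2 * len
    )
  })
  if (length(rows) == 0L) {
    return(data.frame(segment = integer(0), n_vertices = integer(0),
                      length = numeric(0), tortuosity = numeric(0),
                      radius_mean = numeric(0), radius_min = numeric(0),
                      radius_max = numeric(0), radius_sd = numeric(0),
                      surface_area = numeric(0), volume = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Network-level report
#'
#' Aggregates the final graph and segment table into whole-network
#' features: branchpoint and endpoint counts (degree > 2 and degree 1 on
#' the final graph), segment count, total length / lateral surface area /
#' volume, segment partitioning (segments per unit network length),
#' vascular area fraction, and per-radius-bin segment counts with mean
#' features. Segments with undefined (loop) tortuosity are excluded from
#' the tortuosity mean and counted in `undefined_tortuosity`.
#'
#' @param graph the final vessel graph.
#' @param segments a [segment_features()] data.frame.
#' @param volume the analyzed [vasc_volume()].
#' @param bin_edges radius bin boundaries in physical units; default
#'   unit-width bins spanning the observed radius range.
#' @return an object of class `vasc_report`: list with `network` (one-row
#'   data.frame), `bins` (per-bin data.frame) and `segments`.
#' @export
network_report <- function(graph, segments, volume, bin_edges = NULL) {
  deg <- igraph::degree(graph)
  total_length <- sum(segments$length)
  nseg <- nrow(segments)
  if (is.null(bin_edges)) {
    top <- if (nseg && any(is.finite(segments$radius_mean)))
      max(1, ceiling(max(segments$radius_mean, na.rm = TRUE))) else 1
    bin_edges <- 0:top
  }
  bin_id <- if (nseg) {
    cut(segments$radius_mean, breaks = bin_edges, include.lowest = TRUE,
        labels = FALSE, right = TRUE)
  } else integer(0)
  nb <- length(bin_edges) - 1L
  bin_id[is.na(bin_id)] <- nb # radii beyond the top edge fall in the last bin
  bins <- do.call(rbind, lapply(seq_len(nb), function(b) {
    sel <- segments[bin_id == b, , drop = FALSE]
    data.frame(
      bin = b, lower = bin_edges[b], upper = bin_edges[b + 1L],
      segment_count = nrow(sel),
      mean_length = if (nrow(sel)) mean(sel$length) else NA_real_,
      mean_tortuosity = if (any(is.finite(sel$tortuosity)))
        mean(sel$tortuosity[is.finite(sel$tortuosity)]) else NA_real_,
      mean_radius = if (nrow(sel)) mean(sel$radius_mean) else NA_real_
    )
  }))
  network <- data.frame(
    branchpoint_count = sum(deg > 2L),
    endpoint_count = sum(deg == 1L),
    segment_count = nseg,
    total_length = total_length,
    total_surface_area = sum(segments$surface_area),
    total_volume = sum(segments$volume),
    segment_partitioning = if (total_length > 0) nseg / total_length else 0,
    area_fraction = foreground_fraction(volume),
    mean_tortuosity = if (any(is.finite(segments$tortuosity)))
      mean(segments$tortuosity[is.finite(segments$tortuosity)]) else NA_real_,
    undefined_tortuosity = sum(nseg > 0 & !is.finite(segments$tortuosity))
  )
  structure(list(network = network, bins = bins, segments = segments),
            class = "vasc_report")
}

#' @export
print.vasc_report <- function(x, ...) {
  n <- x$network
  cat(sprintf(
    "<vasc_report> %d segments, %d branchpoints, %d endpoints\n",
    n$segment_count, n$branchpoint_count, n$endpoint_count))
  cat(sprintf("  total length %.4g, surface area %.4g, volume %.4g\n",
              n$total_length, n$total_surface_area, n$total_volume))
  cat(sprintf("  partitioning %.4g segments/unit, area fraction %.4g\n",
              n$segment_partitioning, n$area_fraction))
  invisible(x)
}

#' Reduce the centerline graph to a branchpoint graph
#'
#' Builds the segment-level graph: vertices are branchpoints and segment
#' termini (endpoints), one edge per segment carrying its features, with
#' the full segment path coordinates serialized into the `coords` edge
#' attribute (`"z,y,x;z,y,x;..."`) since most graph formats do not allow
#' array attributes.
#'
#' @param graph the final centerline graph.
#' @param segments optional [extract_segments()] result.
#' @param features optional [segment_features()] data.frame.
#' @param resolution physical units per voxel, `(z, y, x)`.
#' @return an igraph: vertex attributes `z`, `y`, `x`, `radius`, `kind`;
#'   edge attributes `length`, `tortuosity`, `radius_mean`,
#'   `surface_area`, `volume`, `coords`.
#' @export
reduce_graph <- function(graph, segments = NULL, features = NULL,
                         resolution = c(1, 1, 1)) {
  if (is.null(segments)) segments <- extract_segments(graph)
  if (is.null(features)) features <- segment_features(graph, resolution, segments)
  deg <- igraph::degree(graph)
  co <- vertex_coords(graph)
  rad <- igraph::V(graph)$radius
  # anchor of a segment end: the boundary branchpoint if present, else
  # the terminal path vertex itself (recorded by extract_segments)
  anchors <- lapply(segments, function(s) s$anchor)
  vids <- sort(unique(c(unlist(anchors), which(deg > 2L))))
  if (length(vids) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::make_empty_graph(n = length(vids), directed = FALSE)
  igraph::V(g)$z <- co[vids, 1]; igraph::V(g)$y <- co[vids, 2]
  igraph::V(g)$x <- co[vids, 3]; igraph::V(g)$radius <- rad[vids]
  igraph::V(g)$kind <- ifelse(deg[vids] > 2L, "branchpoint", "endpoint")
  if (length(segments)) {
    em <- t(vapply(anchors, function(a) match(a, vids), integer(2)))
    g <- igraph::add_edges(g, as.vector(t(em)))
    igraph::E(g)$length <- features$length
    igraph::E(g)$tortuosity <- features$tortuosity
    igraph::E(g)$radius_mean <- features$radius_mean
    igraph::E(g)$surface_area <- features$surface_area
    igraph::E(g)$volume <- features$volume
    igraph::E(g)$coords <- vapply(segments, function(s)
      paste(apply(s$path_coords, 1, paste, collapse = ","), collapse = ";"),
      character(1))
  }
  g
}
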