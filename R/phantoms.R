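#' Phantom primitives
#'
#' Geometric primitives for synthetic vasculature phantoms. Coordinates
#' are continuous voxel positions in `(z, y, x)` order, 0-based (voxel
#' centers sit at integer positions). A voxel belongs to a primitive iff
#' its center lies within `radius` of the primitive's centerline curve,
#' so tubes are capsules whose medial axis is exactly the start-end
#' segment.
#'
#' @param start,end length-3 `(z, y, x)` centerline end positions.
#' @param radius tube radius in voxels.
#' @return a primitive description (list) for [phantom_spec()].
#' @export
tube_primitive <- function(start, end, radius) {
  list(type = "tube", start = as.numeric(start), end = as.numeric(end),
       radius = radius)
}

#' @rdname tube_primitive
#' @param center arc center `(z, y, x)`; the arc lies in the x-y plane at
#'   `center[1]`.
#' @param arc_radius radius of the arc itself in voxels.
#' @param span numeric length-2, start and end angle in degrees
#'   (counter-clockwise in the x-y plane).
#' @export
arc_primitive <- function(center, arc_radius, radius, span = c(0, 180)) {
  list(type = "arc", center = as.numeric(center), arc_radius = arc_radius,
       radius = radius, span = as.numeric(span))
}

#' @rdname tube_primitive
#' @param root trunk start position `(z, y, x)`.
#' @param junction branch position `(z, y, x)`.
#' @param arm_dirs list of two length-3 direction vectors (normalized
#'   internally).
#' @param arm_lengths lengths of the two arms in voxels.
#' @param radii length-3 radii: trunk, arm 1, arm 2.
#' @export
bifurcation_primitive <- function(root, junction, arm_dirs, arm_lengths,
                                  radii) {
  radii <- rep_len(radii, 3L)
  list(type = "bifurcation", root = as.numeric(root),
       junction = as.numeric(junction),
       arm_dirs = lapply(arm_dirs, function(d) {
         d <- as.numeric(d); d / sqrt(sum(d^2))
       }),
       arm_lengths = rep_len(as.numeric(arm_lengths), 2L), radii = radii)
}

#' Specify a synthetic vascular phantom
#'
#' @param primitives list of primitives ([tube_primitive()],
#'   [arc_primitive()], [bifurcation_primitive()]).
#' @param dims volume dimensions `(z, y, x)` in voxels.
#' @param resolution physical units per voxel (scalar or length-3,
#'   `(z, y, x)`).
#' @param noise optional list: `divot_prob` (probability of carving each
#'   surface voxel), `hole_n` and `hole_radius` (number and size of
#'   punched spherical holes). Both default to off.
#' @param seed integer seed making noise deterministic.
#' @return a `phantom_spec` list for [render_phantom()].
#' @export
phantom_spec <- function(primitives, dims, resolution = 1,
                         noise = list(), seed = NULL) {
  structure(list(primitives = primitives, dims = as.integer(dims),
                 resolution = resolution,
                 noise = utils::modifyList(
                   list(divot_prob = 0, hole_n = 0, hole_radius = 1), noise),
                 seed = seed),
            class = "phantom_spec")
}

# polyline of centerline sample points for one primitive, plus analytic
# ground-truth length/tortuosity
.primitive_curves <- function(p) {
  if (p$type == "tube") {
    L <- sqrt(sum((p$end - p$start)^2))
    list(list(a = p$start, b = p$end, radius = p$radius,
              length = L, tortuosity = 1))
  } else if (p$type == "arc") {
    th <- p$span * pi / 180
    n <- max(8L, ceiling(abs(diff(th)) * p$arc_radius / 0.25))
    tt <- seq(th[1], th[2], length.out = n + 1L)
    pts <- cbind(p$center[1], p$center[2] + p$arc_radius * sin(tt),
                 p$center[3] + p$arc_radius * cos(tt))
    L <- abs(diff(th)) * p$arc_radius
    chord <- sqrt(sum((pts[n + 1L, ] - pts[1L, ])^2))
    segs <- lapply(seq_len(n), function(i)
      list(a = pts[i, ], b = pts[i + 1L, ], radius = p$radius))
    segs[[1]]$length <- L
    segs[[1]]$tortuosity <- if (chord > 0) L / chord else NA_real_
    segs
  } else if (p$type == "bifurcation") {
    tips <- lapply(1:2, function(i)
      p$junction + p$arm_dirs[[i]] * p$arm_lengths[i])
    trunk_len <- sqrt(sum((p$junction - p$root)^2))
    c(list(list(a = p$root, b = p$junction, radius = p$radii[1],
                length = trunk_len, tortuosity = 1)),
      lapply(1:2, function(i)
        list(a = p$junction, b = tips[[i]], radius = p$radii[i + 1L],
             length = p$arm_lengths[i], tortuosity = 1)))
  } else stop("unknown primitive type: ", p$type, call. = FALSE)
}

# stamp one capsule (segment a-b dilated by radius) into the mask
.stamp_capsule <- function(mask, a, b, radius, dims) {
  lo <- floor(pmin(a, b) - radius); hi <- ceiling(pmax(a, b) + radius)
  if (any(lo < 0) || any(hi > dims - 1)) {
    stop("primitive exceeds the volume bounds (need >= 2 voxel margin)",
         call. = FALSE)
  }
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- as.matrix(expand.grid(z = zz, y = yy, x = xx, KEEP.OUT.ATTRS = FALSE))
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) {
    d2 <- rowSums(sweep(g, 2, a)^2)
  } else {
    ap <- sweep(g, 2, a)
    t <- pmin(1, pmax(0, (ap %*% ab) / len2))
    d2 <- rowSums((ap - outer(as.vector(t), ab))^2)
  }
  inside <- g[d2 <= radius^2, , drop = FALSE]
  if (nrow(inside)) mask[inside + 1L] <- 1L
  mask
}

#' Render a phantom volume with ground truth
#'
#' Rasterizes the primitives (voxel center within `radius` of the
#' centerline curve), optionally applies surface divots and hole
#' punching, and returns the binary volume together with the analytic
#' ground truth. Rendering is deterministic given the seed.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (a [vasc_volume()]) and `truth`: a list
#'   with `branchpoint_count`, `endpoint_count` and a `primitives`
#'   data.frame (type, analytic length, tortuosity, radius).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  mask <- array(0L, dim = dims)
  prim_rows <- list()
  bp <- 0L; ep <- 0L
  for (p in spec$primitives) {
    curves <- .primitive_curves(p)
    for (s in curves) {
      mask <- .stamp_capsule(mask, s$a, s$b, s$radius, dims)
      if (!is.null(s$length)) {
        prim_rows[[length(prim_rows) + 1L]] <- data.frame(
          type = p$type, length = s$length, tortuosity = s$tortuosity,
          radius = s$radius)
      }
    }
    if (p$type == "bifurcation") { bp <- bp + 1L; ep <- ep + 3L }
    else ep <- ep + 2L
  }
  if (spec$noise$divot_prob > 0 || spec$noise$hole_n > 0) {
    mask <- .apply_noise(mask, spec$noise, spec$seed)
  }
  truth <- list(
    branchpoint_count = bp, endpoint_count = ep,
    primitives = do.call(rbind, prim_rows)
  )
  list(volume = suppressWarnings(vasc_volume(mask, spec$resolution)),
       truth = truth)
}

.apply_noise <- function(mask, noise, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  if (!is.null(seed)) set.seed(seed)
  dims <- dim(mask)
  if (noise$divot_prob > 0) {
    # surface voxels: foreground with at least one background face neighbor
    fg <- which(mask == 1L)
    idx <- arrayInd(fg, dims)
    surf <- logical(length(fg))
    for (d in 1:3) for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, d] <- nb[, d] + s
      ok <- nb[, d] >= 1L & nb[, d] <= dims[d]
      val <- rep(0L, length(fg))
      val[ok] <- mask[nb[ok, , drop = FALSE]]
      surf <- surf | (val == 0L)
    }
    hit <- surf & stats::runif(length(fg)) < noise$divot_prob
    mask[fg[hit]] <- 0L
  }
  if (noise$hole_n > 0) {
    fg <- which(mask == 1L)
    if (length(fg)) {
      centers <- arrayInd(sample(fg, min(noise$hole_n, length(fg))), dims)
      r <- noise$hole_radius
      for (i in seq_len(nrow(centers))) {
        c0 <- centers[i, ]
        lo <- pmax(c0 - ceiling(r), 1L); hi <- pmin(c0 + ceiling(r), dims)
        g <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
        d2 <- rowSums(sweep(g, 2, c0)^2)
        mask[g[d2 <= r^2, , drop = FALSE]] <- 0L
      }
    }
  }
  mask
}

#' Randomized benchmark phantoms
#'
#' Convenience generators for the branchpoint-labeling benchmark: a
#' randomly oriented Y-bifurcation (ground truth: 1 branchpoint, 3
#' endpoints) or an X-crossing of two tubes through a common point
#' (ground truth: 1 junction branchpoint, 4 endpoints).
#'
#' @param dims volume dimensions `(z, y, x)`.
#' @param seed integer seed for the randomized geometry.
#' @return as [render_phantom()].
#' @export
phantom_bifurcation <- function(dims = c(64, 64, 64), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctr <- dims / 2
  trunk_dir <- .rand_unit()
  root <- ctr - trunk_dir * stats::runif(1, 12, 16)
  # arms tilt to opposite sides within one plane, so the opening angle
  # between them is the sum of the two tilts (60-120 degrees)
  perp <- .rand_unit()
  perp <- perp - sum(perp * trunk_dir) * trunk_dir
  perp <- perp / sqrt(sum(perp^2))
  a1 <- stats::runif(1, 30, 60) * pi / 180
  a2 <- stats::runif(1, 30, 60) * pi / 180
  arm1 <- cos(a1) * trunk_dir + sin(a1) * perp
  arm2 <- cos(a2) * trunk_dir - sin(a2) * perp
  r <- stats::runif(1, 2, 3)
  spec <- phantom_spec(list(bifurcation_primitive(
    root, ctr, list(arm1, arm2),
    arm_lengths = stats::runif(2, 14, 18), radii = c(r, r * 0.9, r * 0.8))),
    dims = dims, seed = seed)
  render_phantom(spec)
}

#' @rdname phantom_bifurcation
#' @export
phantom_crossing <- function(dims = c(64, 64, 64), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ctr <- dims / 2
  d1 <- .rand_unit()
  d2 <- .tilt(d1, stats::runif(1, 50, 90))
  L <- stats::runif(1, 14, 18)
  r <- stats::runif(1, 2, 3)
  spec <- phantom_spec(list(
    tube_primitive(ctr - d1 * L, ctr + d1 * L, r),
    tube_primitive(ctr - d2 * L, ctr + d2 * L, r * 0.9)),
    dims = dims, seed = seed)
  out <- render_phantom(spec)
  out$truth$branchpoint_count <- 1L
  out$truth$endpoint_count <- 4L
  out
}

.rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# rotate `v` by `deg` degrees within the plane spanned by v and a random
# perpendicular direction
.tilt <- function(v, deg) {
  p <- .rand_unit()
  p <- p - sum(p * v) * v
  p <- p / sqrt(sum(p^2))
  th <- deg * pi / 180
  cos(th) * v + sin(th) * p
}

#' Write / read phantom specs as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `path` (write) or a `phantom_spec` (read).
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  prims <- lapply(raw$primitives, function(p) {
    out <- list(type = as.character(unlist(p$type)))
    for (nm in setdiff(names(p), c("type", "arm_dirs"))) {
      out[[nm]] <- num(p[[nm]])
    }
    if (!is.null(p$arm_dirs)) out$arm_dirs <- lapply(p$arm_dirs, num)
    out
  })
  phantom_spec(prims, dims = num(raw$dims), resolution = num(raw$resolution),
               noise = lapply(raw$noise, num),
               seed = if (!is.null(raw$seed)) as.integer(num(raw$seed)))
}
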