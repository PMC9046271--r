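#' Extract vessel centerlines by parallel medial-axis thinning
#'
#' Reduces the binary volume to a single-voxel-wide, topology-preserving
#' centerline using six-subiteration directional parallel thinning in the
#' (26, 6) digital topology: in each subiteration, border voxels of one of
#' the six face directions are collected in parallel if they are
#' topologically simple and not endpoints, then deleted sequentially with a
#' simplicity re-check so every removal provably preserves connected
#' components, tunnels and cavities. Endpoints (voxels with exactly one
#' foreground neighbor) are never removed, so vessel termini are kept.
#' Single-slice (2D) volumes thin to the N8 2D skeleton automatically.
#'
#' The volume is zero-padded by one voxel before thinning and cropped
#' afterwards so boundary voxels have full neighborhoods.
#'
#' @param volume a [vasc_volume()].
#' @return an object of class `vasc_skeleton`: list with `coords`, an
#'   `(n, 3)` integer matrix of 0-based `(z, y, x)` voxel indices in
#'   lexicographic `(z, y, x)` order, and `mask`, a 0/1 array of the same
#'   shape as the input marking skeleton voxels.
#' @export
skeletonize <- function(volume) {
  stopifnot(inherits(volume, "vasc_volume"))
  d <- dim(volume$data)
  pad <- array(0L, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- volume$data
  thin <- thin_volume_cpp(pad, dim(pad))
  dim(thin) <- dim(pad)
  mask <- thin[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  dim(mask) <- d
  skeleton_from_mask(mask)
}

# Build a vasc_skeleton from a 0/1 mask; coords emitted 0-based in
# lexicographic (z, y, x) order for deterministic vertex indexing.
skeleton_from_mask <- function(mask) {
  w <- which(mask != 0)
  d <- dim(mask)
  if (length(w) == 0L) {
    coords <- matrix(integer(0), ncol = 3,
                     dimnames = list(NULL, c("z", "y", "x")))
  } else {
    idx <- arrayInd(w, d) - 1L
    coords <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
    colnames(coords) <- c("z", "y", "x")
  }
  structure(list(coords = coords, mask = mask), class = "vasc_skeleton")
}

#' @export
print.vasc_skeleton <- function(x, ...) {
  cat(sprintf("<vasc_skeleton> %d centerline points\n", nrow(x$coords)))
  invisible(x)
}

#' Count connected components of a binary mask
#'
#' @param mask a 0/1 3D array (or a [vasc_volume()] / `vasc_skeleton`).
#' @param connectivity 26 (default) or 6.
#' @return integer component count.
#' @export
count_components <- function(mask, connectivity = 26) {
  if (inherits(mask, "vasc_volume")) mask <- mask$data
  if (inherits(mask, "vasc_skeleton")) mask <- mask$mask
  lab <- label_components_cpp(as.integer(mask), dim(mask), as.integer(connectivity))
  attr(lab, "n_components")
}

#' Label connected components of a binary mask
#'
#' @inheritParams count_components
#' @return integer array of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (inherits(mask, "vasc_volume")) mask <- mask$data
  if (inherits(mask, "vasc_skeleton")) mask <- mask$mask
  label_components_cpp(as.integer(mask), dim(mask), as.integer(connectivity))
}
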