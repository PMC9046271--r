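#' Binary vasculature volumes
#'
#' A `vasc_volume` wraps a contiguous 3D array of 0/1 voxels (background = 0,
#' vessel = 1) together with the physical voxel resolution. Internal arrays
#' are indexed `(z, y, x)`, 0-based in all coordinate output, and the
#' resolution vector is stored in the same `(z, y, x)` order. 2D images are
#' padded to a single-slice 3D array with a z-resolution of 1 unit, so that
#' neighborhood logic degrades to the 2D N4/N8 case automatically.
#'
#' @param data a 2D or 3D numeric/logical array; any nonzero value is
#'   foreground. Volumes are expected to be pre-segmented: there is no
#'   threshold parameter.
#' @param resolution physical units per voxel. Either a single value
#'   (isotropic) or a length-3 vector in `(z, y, x)` order matching the
#'   array axes. For 2D inputs a single value or length-2 `(y, x)` vector;
#'   the padded z axis gets resolution 1.
#' @return an object of class `vasc_volume` with elements `data` (3D 0/1
#'   integer array), `resolution` (length-3, `(z, y, x)` order) and
#'   `ndim_original` (2 or 3).
#' @export
vasc_volume <- function(data, resolution = 1) {
  if (!is.array(data) && !is.matrix(data)) {
    stop("`data` must be a 2D or 3D array", call. = FALSE)
  }
  nd <- length(dim(data))
  if (nd == 2L) {
    if (length(resolution) == 1L) resolution <- rep(resolution, 2L)
    if (length(resolution) != 2L) {
      stop("2D input needs a scalar or length-2 (y, x) resolution", call. = FALSE)
    }
    resolution <- c(1, resolution)
    data <- array(data, dim = c(1L, dim(data)))
    ndim_original <- 2L
  } else if (nd == 3L) {
    if (length(resolution) == 1L) resolution <- rep(resolution, 3L)
    if (length(resolution) != 3L) {
      stop("3D input needs a scalar or length-3 (z, y, x) resolution", call. = FALSE)
    }
    ndim_original <- 3L
  } else {
    stop("`data` must have 2 or 3 dimensions, got ", nd, call. = FALSE)
  }
  resolution <- as.numeric(resolution)
  if (any(!is.finite(resolution)) || any(resolution <= 0)) {
    stop("all resolution components must be strictly positive and finite",
         call. = FALSE)
  }
  bin <- array(as.integer(data != 0), dim = dim(data))
  if (sum(bin) == 0L) {
    warning("volume contains no foreground voxels", call. = FALSE)
  }
  structure(
    list(data = bin, resolution = resolution, ndim_original = ndim_original),
    class = "vasc_volume"
  )
}

#' @export
print.vasc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<vasc_volume> %d x %d x %d (z, y, x), resolution (%s), %s foreground voxels\n",
    d[1], d[2], d[3], paste(signif(x$resolution, 4), collapse = ", "),
    format(sum(x$data), big.mark = ",")
  ))
  invisible(x)
}

#' Load a pre-segmented vasculature volume
#'
#' Reads a binary (pre-segmented) vasculature image from NIfTI
#' (`.nii`/`.nii.gz`), TIFF (single or multi-page) or PNG, binarizes it
#' (any nonzero value becomes foreground) and attaches the physical voxel
#' resolution. NIfTI affine/orientation metadata is ignored: the
#' user-supplied resolution is authoritative. Multi-channel 2D images are
#' collapsed by maximum over channels before binarization.
#'
#' @param path path to the image file.
#' @param resolution physical units per voxel, see [vasc_volume()].
#' @return a [vasc_volume()].
#' @export
load_volume <- function(path, resolution = 1) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  gz <- grepl("\\.gz$", tolower(path))
  arr <- switch(
    ext,
    nii = {
      img <- RNifti::readNifti(path)
      a <- as.array(img)
      if (length(dim(a)) > 3L) a <- array(a, dim = dim(a)[1:3])
      # NIfTI stores (x, y, z); convert to internal (z, y, x)
      if (length(dim(a)) == 3L) aperm(a, c(3L, 2L, 1L)) else t(a)
    },
    tif = ,
    tiff = {
      pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
      if (!is.list(pages)) pages <- list(pages)
      pages <- lapply(pages, .collapse_channels)
      a <- array(0, dim = c(length(pages), dim(pages[[1]])))
      for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
      if (length(pages) == 1L) a <- a[1, , , drop = TRUE]
      a
    },
    png = .collapse_channels(png::readPNG(path)),
    jpg = ,
    jpeg = ,
    bmp = stop("no reader available for '.", ext,
               "' images; convert to PNG or TIFF", call. = FALSE),
    stop("unsupported image format: '", ext,
         if (gz) ".gz", "' (expected .nii, .nii.gz, .tif(f) or .png)",
         call. = FALSE)
  )
  vasc_volume(arr, resolution = resolution)
}

.collapse_channels <- function(a) {
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), max)
  a
}

#' Write a volume as NIfTI
#'
#' Writes the 0/1 array of a [vasc_volume()] (or the skeleton mask of a
#' [skeletonize()] result) to a NIfTI file, converting from the internal
#' `(z, y, x)` layout back to NIfTI `(x, y, z)` order and recording the
#' voxel resolution in the header pixdim.
#'
#' @param volume a [vasc_volume()] or a plain 0/1 3D array in `(z, y, x)`
#'   order.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param resolution used when `volume` is a plain array.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, resolution = 1) {
  if (inherits(volume, "vasc_volume")) {
    arr <- volume$data
    resolution <- volume$resolution
  } else {
    arr <- volume
    if (length(resolution) == 1L) resolution <- rep(resolution, 3L)
  }
  out <- aperm(arr, c(3L, 2L, 1L))
  img <- RNifti::asNifti(out)
  img <- RNifti::`pixdim<-`(img, rev(resolution)) # (x, y, z)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Foreground (vascular area/volume) fraction
#'
#' Fraction of voxels labeled as vessel, the percent-area/volume network
#' feature expressed as a proportion in `[0, 1]`.
#'
#' @param volume a [vasc_volume()].
#' @return a single number in `[0, 1]`.
#' @export
foreground_fraction <- function(volume) {
  stopifnot(inherits(volume, "vasc_volume"))
  sum(volume$data) / length(volume$data)
}
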