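#' Annotation (ROI) specifications
#'
#' An annotation spec maps ROI names to atlas identifiers: either integer
#' atlas IDs (NIfTI-style annotation volumes) or RGB triples (0-255,
#' image-series annotations). Specs can be written by hand, built from an
#' Allen-style structure-graph JSON, or loaded from a JSON file of the
#' form `{"name": [ids...]}` / `{"name": [[r,g,b], ...]}`.
#'
#' @param rois named list: each element a vector of integer IDs or a
#'   list/matrix of RGB triples.
#' @param type `"id"` or `"rgb"`.
#' @return an `annotation_spec` object.
#' @export
annotation_spec <- function(rois, type = c("id", "rgb")) {
  type <- match.arg(type)
  if (length(rois) == 0L || is.null(names(rois)) || any(names(rois) == "")) {
    stop("`rois` must be a non-empty named list", call. = FALSE)
  }
  rois <- lapply(rois, function(r) {
    if (type == "rgb") {
      m <- if (is.matrix(r)) r else do.call(rbind, lapply(r, as.integer))
      if (ncol(m) != 3L) stop("RGB entries need 3 components", call. = FALSE)
      m
    } else as.numeric(unlist(r))
  })
  if (any(vapply(rois, function(r) if (is.matrix(r)) nrow(r) else length(r),
                 integer(1)) == 0L)) {
    stop("every ROI needs at least one identifier", call. = FALSE)
  }
  keys <- unlist(lapply(rois, function(r)
    if (is.matrix(r)) apply(r, 1, paste, collapse = ",") else as.character(r)))
  if (anyDuplicated(keys)) {
    stop("ROI identifier sets must be pairwise disjoint", call. = FALSE)
  }
  structure(list(rois = rois, type = type), class = "annotation_spec")
}

#' @rdname annotation_spec
#' @param path JSON file of ROI name -> identifier list.
#' @export
read_annotation_spec <- function(path, type = c("id", "rgb")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  annotation_spec(as.list(raw), type = match.arg(type))
}

#' Partition ROIs into labeling bins
#'
#' ROIs are processed in bins of at most 254 regions: within each bin the
#' selected ROIs get labels 1..255 (consecutive from 1) and 0 is reserved
#' for background, so one unsigned-byte labeling pass over the volume
#' covers a bin.
#'
#' @param spec an [annotation_spec()].
#' @param bin_size maximum ROIs per bin (254).
#' @return list of bins; each bin is a data.frame-like list with `name`
#'   and `label` (1-based within the bin) plus the spec entries.
#' @export
bin_rois <- function(spec, bin_size = 254L) {
  stopifnot(inherits(spec, "annotation_spec"))
  nm <- names(spec$rois)
  n <- length(nm)
  bin_of <- ceiling(seq_len(n) / bin_size)
  lapply(split(seq_len(n), bin_of), function(ix) {
    list(names = nm[ix], labels = seq_along(ix),
         rois = spec$rois[ix], type = spec$type)
  })
}

#' Label vasculature voxels by ROI
#'
#' Casts the ROI labels of one bin onto the vasculature: every foreground
#' voxel whose annotation belongs to a selected ROI receives that ROI's
#' bin label (1-255); other foreground voxels get 0. Also returns each
#' ROI's total annotated volume (annotation voxel count x voxel physical
#' volume). The labeled array is cached to disk as a flat binary file for
#' memory-mapped style access.
#'
#' @param volume a [vasc_volume()].
#' @param annotation integer 3D array (same `(z, y, x)` shape) of atlas
#'   IDs, or a 4D `(z, y, x, 3)` RGB array with 0-255 channels.
#' @param bin one bin from [bin_rois()].
#' @param cache_path optional path for the disk cache; a tempfile by
#'   default.
#' @param keep_cache keep the cache file after the call.
#' @return list with `labels` (integer array), `roi_volumes` (named,
#'   physical units^3), `unknown_ids` (count of annotated voxels whose ID
#'   matched no selected ROI) and `cache_path`.
#' @export
label_vasculature <- function(volume, annotation, bin, cache_path = NULL,
                              keep_cache = FALSE) {
  stopifnot(inherits(volume, "vasc_volume"))
  d <- dim(volume$data)
  if (bin$type == "rgb") {
    if (length(dim(annotation)) != 4L || !all(dim(annotation)[1:3] == d)) {
      stop("RGB annotation shape must be (z, y, x, 3) matching the volume",
           call. = FALSE)
    }
    ann_key <- annotation[, , , 1] * 65536 + annotation[, , , 2] * 256 +
      annotation[, , , 3]
    roi_keys <- lapply(bin$rois, function(m)
      m[, 1] * 65536 + m[, 2] * 256 + m[, 3])
  } else {
    if (!all(dim(annotation) == d)) {
      stop("annotation shape must match the volume", call. = FALSE)
    }
    ann_key <- annotation
    roi_keys <- bin$rois
  }
  key_tab <- unlist(roi_keys, use.names = FALSE)
  lab_tab <- rep.int(bin$labels, vapply(roi_keys, length, integer(1)))
  m <- match(as.vector(ann_key), key_tab)
  roi_lab <- ifelse(is.na(m), 0L, lab_tab[m])
  vox_vol <- prod(volume$resolution)
  roi_volumes <- vapply(seq_along(bin$labels), function(l)
    sum(roi_lab == l) * vox_vol, numeric(1))
  names(roi_volumes) <- bin$names
  labels <- array(as.integer(roi_lab * as.vector(volume$data)), dim = d)
  unknown <- sum(ann_key != 0 & is.na(array(m, dim = dim(ann_key))))
  if (unknown > 0) {
    message(unknown, " annotated voxels matched no selected ROI")
  }
  if (sum(labels) == 0L) {
    warning("no vasculature voxel falls inside a selected ROI", call. = FALSE)
  }
  if (is.null(cache_path)) cache_path <- tempfile(fileext = ".bin")
  con <- file(cache_path, "wb")
  writeBin(dim(labels), con, size = 4L)
  writeBin(as.integer(labels), con, size = 4L)
  close(con)
  if (!keep_cache) on.exit(unlink(cache_path), add = TRUE)
  list(labels = labels, roi_volumes = roi_volumes, unknown_ids = unknown,
       cache_path = if (keep_cache) cache_path else NA_character_)
}

#' Read a labeled-volume disk cache
#'
#' @param path cache file from [label_vasculature()].
#' @return the integer label array.
#' @export
read_label_cache <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", 3L, size = 4L)
  array(readBin(con, "integer", prod(d), size = 4L), dim = d)
}

#' ROI-wise vasculature analysis
#'
#' Runs the full analysis pipeline separately on the vasculature of each
#' selected ROI (processed in bins of 254), and merges the per-ROI
#' centerline graphs as a disjoint union with global voxel coordinates
#' preserved. Vessels crossing an ROI boundary are split at the boundary,
#' creating endpoints in both ROI reports (a documented consequence of
#' segmenting before skeletonization).
#'
#' @param volume a [vasc_volume()].
#' @param annotation annotation array, see [label_vasculature()].
#' @param spec an [annotation_spec()].
#' @param ... analysis parameters passed to [run_analysis()]
#'   (`filter_length`, `prune_length`, ...).
#' @return list with `reports` (named per-ROI [network_report()]s),
#'   `roi_volumes` (named physical volumes) and `merged_graph` (disjoint
#'   union of per-ROI final graphs, vertex attribute `roi`).
#' @export
analyze_rois <- function(volume, annotation, spec, ...) {
  stopifnot(inherits(volume, "vasc_volume"), inherits(spec, "annotation_spec"))
  bins <- bin_rois(spec)
  reports <- list()
  roi_volumes <- numeric(0)
  graphs <- list()
  for (bin in bins) {
    lab <- label_vasculature(volume, annotation, bin)
    roi_volumes <- c(roi_volumes, lab$roi_volumes)
    for (i in seq_along(bin$labels)) {
      nm <- bin$names[i]
      sub <- volume
      sub$data <- array(as.integer(lab$labels == bin$labels[i]), dim(lab$labels))
      if (sum(sub$data) == 0L) {
        empty <- network_report(
          igraph::make_empty_graph(0, directed = FALSE),
          segment_features(igraph::make_empty_graph(0, directed = FALSE)),
          suppressWarnings(vasc_volume(sub$data, volume$resolution)))
        reports[[nm]] <- empty
        next
      }
      ana <- suppressWarnings(run_analysis(sub, ...))
      reports[[nm]] <- ana$report
      g <- ana$graph
      if (igraph::vcount(g) > 0L) {
        igraph::V(g)$roi <- nm
        graphs[[length(graphs) + 1L]] <- g
      }
    }
  }
  merged <- if (length(graphs)) do.call(igraph::disjoint_union, graphs)
  else igraph::make_empty_graph(0, directed = FALSE)
  list(reports = reports, roi_volumes = roi_volumes, merged_graph = merged)
}
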