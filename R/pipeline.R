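#' Run the full vasculature analysis pipeline
#'
#' Executes load -> skeletonize -> radii -> graph -> clique filter ->
#' prune -> feature extraction on one pre-segmented volume and returns
#' all intermediate products plus the network report.
#'
#' @param volume a [vasc_volume()] or a path readable by [load_volume()].
#' @param resolution physical units per voxel (used when `volume` is a
#'   path), see [vasc_volume()].
#' @param filter_length isolated-segment filter length, physical units.
#' @param prune_length endpoint-segment prune length, physical units.
#' @param bin_edges radius bin boundaries for [network_report()].
#' @param clique_window class-3 sliding-window length, voxels.
#' @param verbose log per-stage counts to stderr.
#' @return an object of class `vasc_analysis`: list with `volume`
#'   (post-pruning), `skeleton`, `radii`, `graph` (final centerline
#'   graph), `reduced` (segment-level graph), `segments`
#'   ([segment_features()] table) and `report` ([network_report()]).
#' @export
run_analysis <- function(volume, resolution = 1, filter_length = 10,
                         prune_length = 5, bin_edges = NULL,
                         clique_window = 10, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.character(volume)) volume <- load_volume(volume, resolution)
  stopifnot(inherits(volume, "vasc_volume"))
  res <- volume$resolution

  skel <- skeletonize(volume)
  say("skeletonization: %d centerline points", nrow(skel$coords))

  lut <- build_medt_lut(res)
  radii <- estimate_radii(volume, skel, lut)
  say("radius estimation: mean radius %.3g", mean(radii, na.rm = TRUE))

  g <- build_graph(skel, radii)
  say("graph construction: %d vertices, %d edges",
      igraph::vcount(g), igraph::ecount(g))

  g <- filter_cliques(g, window = clique_window)
  say("clique filtering: %d vertices, %d branchpoints",
      igraph::vcount(g), sum(igraph::degree(g) > 2L))

  pr <- prune_graph(g, volume, isolated_filter_length = filter_length,
                    endpoint_prune_length = prune_length)
  g <- pr$graph
  volume <- pr$volume
  say("pruning: %d vertices retained", igraph::vcount(g))

  segs <- extract_segments(g)
  feats <- segment_features(g, res, segs)
  report <- network_report(g, feats, volume, bin_edges = bin_edges)
  reduced <- reduce_graph(g, segs, feats, res)
  say("features: %d segments, total length %.4g",
      nrow(feats), report$network$total_length)

  structure(list(volume = volume, skeleton = skel, radii = radii,
                 graph = g, reduced = reduced, segments = feats,
                 report = report),
            class = "vasc_analysis")
}

#' @export
print.vasc_analysis <- function(x, ...) {
  cat("<vasc_analysis>\n")
  print(x$report)
  invisible(x)
}

#' Write analysis reports to CSV
#'
#' Writes the one-row network summary, the per-segment table and the
#' per-radius-bin table as CSV files `<stem>_network.csv`,
#' `<stem>_segments.csv`, `<stem>_bins.csv`.
#'
#' @param analysis a [run_analysis()] result (or a `vasc_report`).
#' @param stem output path stem.
#' @return the written paths, invisibly.
#' @export
write_reports <- function(analysis, stem) {
  report <- if (inherits(analysis, "vasc_analysis")) analysis$report else analysis
  stopifnot(inherits(report, "vasc_report"))
  paths <- paste0(stem, c("_network.csv", "_segments.csv", "_bins.csv"))
  utils::write.csv(report$network, paths[1], row.names = FALSE)
  utils::write.csv(report$segments, paths[2], row.names = FALSE)
  utils::write.csv(report$bins, paths[3], row.names = FALSE)
  invisible(paths)
}
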