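test_that("spline lengths reproduce chords, lines and arcs", {
  # two points: the spline degenerates to the chord
  expect_equal(segment_length(rbind(c(0, 0, 0), c(0, 0, 5))), 5)
  # collinear points: exact line length
  expect_equal(segment_length(cbind(0, 0, 0:10)), 10, tolerance = 1e-6)
  # anisotropic scaling enters the physical length
  expect_equal(segment_length(rbind(c(0, 0, 0), c(1, 0, 0)), c(2.5, 1, 1)),
               2.5)
  # single point has zero length
  expect_equal(segment_length(matrix(c(1, 2, 3), 1)), 0)

  # semicircular arc phantom: length within 2% of 20*pi
  spec <- phantom_spec(list(
    arc_primitive(c(6, 30, 30), 20, 1.5, span = c(-90, 90))),
    dims = c(12, 60, 60))
  ph <- render_phantom(spec)
  ana <- run_analysis(ph$volume, filter_length = 0, prune_length = 0)
  expect_equal(ana$segments$length, 20 * pi, tolerance = 0.02)
  expect_equal(ana$segments$tortuosity, pi / 2, tolerance = 0.02)
})

test_that("tortuosity is the arc-chord ratio with loops excluded", {
  expect_equal(segment_tortuosity(10, c(0, 0, 0), c(0, 0, 10)), 1)
  expect_equal(segment_tortuosity(20 * pi, c(0, 0, -20), c(0, 0, 20)),
               pi / 2)
  expect_true(is.na(segment_tortuosity(5, c(1, 1, 1), c(1, 1, 1))))
})

test_that("segments are isolated between branchpoints", {
  # pure path graph: one segment spanning all vertices
  path <- make_vgraph(cbind(0, 0, 0:5), rep(1, 6), cbind(1:5, 2:6))
  segs <- extract_segments(path)
  expect_length(segs, 1L)
  expect_length(segs[[1]]$vertex_path, 6L)
  expect_length(segs[[1]]$boundary, 0L)

  # Y: three arms bounded by the central branchpoint
  co <- cbind(z = rep(0, 7), y = c(0, 1, 2, -1, -2, 0, 0),
              x = c(0, 1, 2, 1, 2, -1, -2))
  edges <- rbind(c(1, 2), c(2, 3), c(1, 4), c(4, 5), c(1, 6), c(6, 7))
  y <- make_vgraph(co, rep(1, 7), edges)
  segs <- extract_segments(y)
  expect_length(segs, 3L)
  expect_true(all(vapply(segs, function(s) identical(s$boundary, 1L),
                         logical(1))))
  # boundary coordinates are appended to the paths for length fitting
  expect_true(all(vapply(segs, function(s)
    nrow(s$path_coords) == length(s$vertex_path) + 1L, logical(1))))

  expect_length(extract_segments(igraph::make_empty_graph(0, FALSE)), 0L)
})

test_that("surface area and volume follow the cylinder identities", {
  ph <- random_tube_phantom(9, dims = c(28, 28, 28))
  ana <- run_analysis(ph$volume, filter_length = 0, prune_length = 0)
  s <- ana$segments
  expect_equal(s$surface_area, 2 * pi * s$radius_mean * s$length)
  expect_equal(s$volume, pi * s$radius_mean^2 * s$length)
  expect_true(all(s$radius_min <= s$radius_mean + 1e-12))
  expect_true(all(s$radius_mean <= s$radius_max + 1e-12))
  expect_true(all(s$tortuosity >= 1 - 1e-6, na.rm = TRUE))
})

test_that("network reports satisfy the aggregation identities", {
  ph <- phantom_bifurcation(seed = 3)
  ana <- run_analysis(ph$volume)
  rep_ <- ana$report
  expect_equal(rep_$network$branchpoint_count, 1)
  expect_equal(rep_$network$endpoint_count, 3)
  expect_equal(rep_$network$segment_count, 3)
  expect_equal(rep_$network$segment_partitioning,
               rep_$network$segment_count / rep_$network$total_length)
  expect_equal(sum(rep_$bins$segment_count), rep_$network$segment_count)
  expect_equal(rep_$network$total_volume, sum(rep_$segments$volume))
  expect_equal(rep_$network$total_surface_area, sum(rep_$segments$surface_area))
  expect_equal(rep_$network$area_fraction, foreground_fraction(ana$volume))

  # explicit bin edges: counts still sum, assignment by mean radius
  rep2 <- network_report(ana$graph, ana$segments, ana$volume,
                         bin_edges = c(0, 1, 2, 3, 10))
  expect_equal(sum(rep2$bins$segment_count), nrow(ana$segments))

  # empty graph: all zero, partitioning 0 by convention
  g0 <- igraph::make_empty_graph(0, FALSE)
  v0 <- suppressWarnings(vasc_volume(array(0L, c(3, 3, 3))))
  r0 <- network_report(g0, segment_features(g0), v0)
  expect_equal(r0$network$segment_count, 0)
  expect_equal(r0$network$segment_partitioning, 0)
})

test_that("tortuosity over random phantoms never drops below 1", {
  for (seed in 1:10) {
    ph <- random_tube_phantom(seed, dims = c(26, 26, 26), n_tubes = 2)
    ana <- run_analysis(ph$volume, filter_length = 0, prune_length = 0)
    tt <- ana$segments$tortuosity
    expect_true(all(tt >= 1 - 1e-6, na.rm = TRUE),
                info = paste("seed", seed))
  }
})

test_that("closed loops have undefined tortuosity and are excluded", {
  # diamond cycle, no branchpoints
  co <- cbind(z = rep(0, 4), y = c(0, 1, 0, -1), x = c(0, 1, 2, 1))
  ring <- make_vgraph(co, rep(1, 4),
                      rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)))
  segs <- extract_segments(ring)
  expect_length(segs, 1L)
  feats <- segment_features(ring)
  expect_true(is.na(feats$tortuosity))
  v <- vasc_volume(array(1L, c(1, 3, 3)))
  rep_ <- network_report(ring, feats, v)
  expect_equal(rep_$network$undefined_tortuosity, 1)
  expect_true(is.na(rep_$network$mean_tortuosity))
})

test_that("the reduced graph carries one edge per segment with coordinates", {
  ph <- phantom_bifurcation(seed = 7)
  ana <- run_analysis(ph$volume)
  red <- ana$reduced
  expect_equal(igraph::ecount(red), nrow(ana$segments))
  expect_setequal(unique(igraph::V(red)$kind), c("branchpoint", "endpoint"))
  expect_equal(igraph::E(red)$length, ana$segments$length)
  # coords attribute parses back into (z, y, x) triples
  c1 <- strsplit(igraph::E(red)$coords[1], ";")[[1]]
  expect_true(all(lengths(strsplit(c1, ",")) == 3))

  td <- withr::local_tempdir()
  gml <- file.path(td, "g.graphml")
  export_graph(red, gml)
  expect_true(file.exists(gml))
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(red))
  csvs <- export_graph(red, file.path(td, "g.csv"), format = "csv")
  expect_true(all(file.exists(csvs)))
})
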