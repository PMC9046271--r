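test_that("an already-thin line is its own skeleton", {
  v <- line_volume(20)
  sk <- skeletonize(v)
  expect_identical(sk$mask, v$data)
  expect_equal(nrow(sk$coords), 20L)
  # lexicographic (z, y, x) emission order
  expect_false(is.unsorted(sk$coords[, 3]))
})

test_that("a solid cylinder thins to a single width-1 axial path", {
  spec <- phantom_spec(list(tube_primitive(c(8, 8, 5), c(8, 8, 44), 3)),
                       dims = c(17, 17, 50))
  ph <- render_phantom(spec)
  sk <- skeletonize(ph$volume)
  expect_equal(count_components(sk$mask), 1L)
  # all skeleton points within 1 voxel of the cylinder axis (z=8, y=8)
  expect_true(all(abs(sk$coords[, 1] - 8) <= 1))
  expect_true(all(abs(sk$coords[, 2] - 8) <= 1))
  # width 1: no skeleton voxel has more than 2 neighbors
  g <- build_graph(sk, rep(1, nrow(sk$coords)))
  expect_true(all(igraph::degree(g) <= 2))
  # skeleton is a subset of the foreground
  expect_true(all(ph$volume$data[sk$coords + 1L] == 1L))
})

test_that("topology is preserved: components, idempotence, subsets", {
  # two disjoint blobs keep 2 components
  spec <- phantom_spec(list(
    tube_primitive(c(8, 8, 8), c(8, 8, 9), 3),
    tube_primitive(c(22, 22, 22), c(22, 22, 23), 3)), dims = c(31, 31, 33))
  ph <- render_phantom(spec)
  sk <- skeletonize(ph$volume)
  expect_equal(count_components(sk$mask), 2L)

  for (seed in 1:10) {
    ph <- random_tube_phantom(seed)
    sk <- skeletonize(ph$volume)
    expect_equal(count_components(sk$mask), count_components(ph$volume),
                 info = paste("component conservation, seed", seed))
    expect_true(all(ph$volume$data[sk$coords + 1L] == 1L),
                info = paste("subset, seed", seed))
    # idempotence: thinning the skeleton changes nothing
    sk2 <- skeletonize(vasc_volume(sk$mask, ph$volume$resolution))
    expect_identical(sk2$coords, sk$coords,
                     info = paste("idempotence, seed", seed))
  }
})

test_that("empty and 2D inputs are handled", {
  v <- suppressWarnings(vasc_volume(array(0L, c(4, 4, 4))))
  sk <- skeletonize(v)
  expect_equal(nrow(sk$coords), 0L)

  # 2D disk thins to a near-point blob, preserved as one component
  m <- matrix(0L, 21, 21)
  for (i in 1:21) for (j in 1:21) if ((i - 11)^2 + (j - 11)^2 <= 36) m[i, j] <- 1L
  v2 <- vasc_volume(m, 1)
  sk2 <- skeletonize(v2)
  expect_gt(nrow(sk2$coords), 0L)
  expect_equal(count_components(sk2$mask), 1L)
  expect_lt(nrow(sk2$coords), sum(m)) # strictly thinner than the disk
})

test_that("thinning agrees with an independent reference implementation", {
  # scikit-image implements the same published medial-axis thinning; the
  # two skeletons need not match voxel-for-voxel, but must agree on
  # topology and lie within a small Hausdorff distance on clean tubes
  py <- Sys.which("python")
  expect_true(nzchar(py)) # present in the analysis environment
  td <- withr::local_tempdir()
  # L-shaped vessel: two joined tubes give a long, unambiguous centerline
  ph <- render_phantom(phantom_spec(list(
    tube_primitive(c(8, 8, 8), c(8, 30, 8), 2.5),
    tube_primitive(c(8, 30, 8), c(8, 30, 32), 2.5)), dims = c(17, 39, 41)))
  fin <- file.path(td, "vol.txt"); fout <- file.path(td, "skel.txt")
  writeLines(c(paste(dim(ph$volume$data), collapse = " "),
               paste(as.integer(ph$volume$data), collapse = " ")), fin)
  script <- file.path(td, "ref.py")
  writeLines(c(
    "import sys, numpy as np",
    "from skimage.morphology import skeletonize",
    "dims, data = open(sys.argv[1]).read().splitlines()",
    "d = tuple(int(x) for x in dims.split())",
    "a = np.array(data.split(), dtype=np.uint8).reshape(d, order='F')",
    "s = skeletonize(a).astype(np.uint8)",
    "np.savetxt(sys.argv[2], np.argwhere(s), fmt='%d')"), script)
  st <- system2(py, c(script, fin, fout))
  expect_equal(st, 0L)
  ref <- as.matrix(read.table(fout))
  sk <- skeletonize(ph$volume)
  expect_equal(count_components(sk$mask), count_components(ph$volume))
  # symmetric Hausdorff distance between the two point sets
  dmat <- function(a, b) {
    outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
      sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2 +
             (a[i, 3] - b[j, 3])^2))
  }
  dd <- dmat(sk$coords, ref)
  haus <- max(max(apply(dd, 1, min)), max(apply(dd, 2, min)))
  expect_lte(haus, 3)
  # comparable point counts (same curve, different tie-breaking)
  expect_lt(abs(nrow(sk$coords) - nrow(ref)) / nrow(ref), 0.25)
})
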