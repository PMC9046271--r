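# triangle of branchpoint candidates with pendant outside neighbors:
# v1..v3 form the clique, v4..v7 hang off them
triangle_graph <- function(radii_clique = c(3, 1, 1),
                           radii_out = c(3, 3, 1, 1)) {
  co <- cbind(z = c(0, 0, 1, 0, 0, 0, 2), y = c(0, 1, 0, -1, 0, 2, 0),
              x = c(0, 0, 0, 0, -1, 0, 0))
  make_vgraph(co, c(radii_clique, radii_out),
              edges = rbind(c(1, 2), c(1, 3), c(2, 3), # clique
                            c(1, 4), c(1, 5), c(2, 6), c(3, 7)))
}

test_that("clique weights combine own and outside-neighbor radii", {
  g <- triangle_graph()
  w <- weight_clique_candidates(g, 1:3)
  expect_equal(w, c(6, 2, 2)) # radius + mean(outside radii)
  # all-equal radii tie
  g2 <- triangle_graph(radii_clique = c(2, 2, 2), radii_out = rep(2, 4))
  expect_equal(unique(weight_clique_candidates(g2, 1:3)), 4)
  # vertex with no outside neighbors keeps its own radius
  g3 <- make_vgraph(cbind(c(0, 0, 1), c(0, 1, 0), c(0, 0, 0)), c(2, 1, 1),
                    rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(weight_clique_candidates(g3, 1:3), c(2, 1, 1))
})

test_that("class-1 filtering removes the lowest-weighted connection", {
  g <- triangle_graph()
  f <- filter_class1(g)
  # the edge between the two low-weight candidates (2,3) is gone
  expect_equal(igraph::ecount(f), igraph::ecount(g) - 1L)
  expect_false(igraph::are_adjacent(f, 2, 3))
  expect_true(igraph::are_adjacent(f, 1, 2))
  expect_equal(igraph::count_components(f), igraph::count_components(g))
  # no degree > 2 clique left: only the true junction remains a branchpoint
  expect_equal(sum(igraph::degree(f) > 2), 1L)

  # a graph without branchpoint candidates is untouched
  path <- make_vgraph(cbind(0:3, 0, 0), rep(1, 4), cbind(1:3, 2:4))
  expect_equal(igraph::ecount(filter_class1(path)), 3)
})

test_that("a Y-junction phantom resolves to one branchpoint", {
  ph <- phantom_bifurcation(seed = 5)
  sk <- skeletonize(ph$volume)
  g <- build_graph(sk, estimate_radii(ph$volume, sk))
  before <- sum(igraph::degree(g) > 2)
  f <- filter_cliques(g)
  after <- sum(igraph::degree(f) > 2)
  expect_gte(before, after)
  expect_equal(after, 1L)
  expect_equal(igraph::count_components(f), igraph::count_components(g))
})

test_that("class-2 clusters merge to a centroid vertex with mean radius", {
  # 5-vertex blob, radii 1,1,2,2,4, three external targets 6,7,8
  co <- cbind(z = c(0, 0, 1, 1, 0, 3, -3, 0),
              y = c(0, 1, 0, 1, 2, 0, 0, 5),
              x = c(0, 0, 0, 0, 0, 0, 0, 0))
  edges <- rbind(t(combn(1:5, 2)), c(1, 6), c(2, 7), c(5, 8))
  g <- make_vgraph(co, c(1, 1, 2, 2, 4, 1, 1, 1), edges)
  cl <- list(vertex_ids = 1:5, cluster_class = 2L,
             external_targets = 6:8)
  f <- filter_class2(g, cl)
  expect_equal(igraph::vcount(f), 4L) # 3 targets + 1 merged
  merged <- igraph::vcount(f) # new vertex is appended last before deletion
  expect_equal(sort(igraph::V(f)$radius), c(1, 1, 1, 2))
  mid <- which(igraph::V(f)$radius == 2)
  expect_equal(igraph::degree(f)[mid], 3L)
  expect_equal(igraph::count_components(f), 1L)
  # merged radius lies within the cluster's radius range
  expect_gte(2, 1); expect_lte(2, 4)

  # degenerate 2-vertex cluster
  g2 <- make_vgraph(cbind(c(0, 1, 2), 0, 0), c(1, 3, 1),
                    rbind(c(1, 2), c(2, 3)))
  f2 <- filter_class2(g2, list(vertex_ids = 1:2, cluster_class = 2L,
                               external_targets = 3L))
  expect_equal(igraph::vcount(f2), 2L)
  expect_equal(igraph::count_components(f2), 1L)
  expect_equal(sort(igraph::V(f2)$radius), c(1, 2))

  # cluster with no external projections becomes an isolated vertex
  g3 <- make_vgraph(cbind(c(0, 0, 1), c(0, 1, 0), 0), rep(1, 3),
                    rbind(c(1, 2), c(1, 3), c(2, 3)))
  f3 <- filter_class2(g3, list(vertex_ids = 1:3, cluster_class = 2L,
                               external_targets = integer(0)))
  expect_equal(igraph::vcount(f3), 1L)
  expect_equal(igraph::degree(f3), 0L)
})

test_that("class-3 sliding window collapses a bar cluster into a path", {
  # 60-vertex dense bar along x (x = 0..59), plus two external targets
  n <- 60L
  co <- cbind(z = rep(0, n + 2), y = rep(0, n + 2),
              x = c(0:(n - 1), -3, n + 2))
  edges <- rbind(cbind(1:(n - 1), 2:n), c(1, n + 1), c(n, n + 2))
  g <- make_vgraph(co, rep(1, n + 2), edges)
  cl <- list(vertex_ids = 1:n, cluster_class = 3L,
             external_targets = c(n + 1L, n + 2L))
  f <- filter_class3(g, cl, window = 10)
  expect_equal(igraph::vcount(f), 2L + 6L) # 6 window vertices
  expect_equal(igraph::count_components(f), 1L)
  # windows form a path; external targets stay attached at the ends
  deg <- igraph::degree(f)
  expect_equal(sum(deg == 1), 2L)
  expect_true(all(deg <= 2))
})

test_that("the two-pass filter preserves structure on random phantoms", {
  for (seed in 1:12) {
    ph <- random_tube_phantom(seed, dims = c(28, 28, 28), n_tubes = 3)
    sk <- skeletonize(ph$volume)
    g <- build_graph(sk, estimate_radii(ph$volume, sk))
    f <- filter_cliques(g)
    expect_equal(igraph::count_components(f), igraph::count_components(g),
                 info = paste("components, seed", seed))
    expect_lte(sum(igraph::degree(f) > 2), sum(igraph::degree(g) > 2))
    # no maximal clique of size >= 3 among branchpoint candidates
    cand <- which(igraph::degree(f) > 2)
    if (length(cand) >= 3) {
      sub <- igraph::induced_subgraph(f, cand)
      expect_equal(igraph::clique_num(sub) < 3 ||
                     length(igraph::max_cliques(sub, min = 3)) == 0, TRUE,
                   info = paste("clique-free, seed", seed))
    }
    # merged radii stay within the original radius range
    expect_true(all(igraph::V(f)$radius >=
                      min(igraph::V(g)$radius) - 1e-12))
    expect_true(all(igraph::V(f)$radius <=
                      max(igraph::V(g)$radius) + 1e-12))
  }
})

test_that("crossing phantoms stay connected with at most two junctions", {
  ph <- phantom_crossing(seed = 2)
  ana <- run_analysis(ph$volume)
  expect_lte(ana$report$network$branchpoint_count, 2L)
  expect_equal(igraph::count_components(ana$graph), 1L)
})
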