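#' Weight branchpoint candidates of a clique
#'
#' Spurious branchpoints arise because 26-connectivity lets several
#' vertices at one junction all reach degree > 2; these vertices form
#' small all-to-all connected cliques. To decide which connections are
#' spurious, each clique vertex is weighted by its own radius plus the
#' mean radius of its neighbors *outside* the clique; vertices with no
#' outside neighbors keep their own radius as weight. Higher weight marks
#' vertices closer to the true (parent, larger-vessel) junction.
#'
#' @param graph a vessel graph ([build_graph()]).
#' @param clique integer vertex ids forming the clique/cluster.
#' @return numeric weight per clique vertex (same order as `clique`).
#' @export
weight_clique_candidates <- function(graph, clique) {
  rad <- igraph::V(graph)$radius
  vapply(clique, function(v) {
    nb <- as.integer(igraph::neighbors(graph, v))
    out <- setdiff(nb, clique)
    if (length(out) == 0L) rad[v] else rad[v] + mean(rad[out])
  }, numeric(1))
}

# maximal cliques among branchpoint-candidate (degree > 2) vertices,
# translated back to ids of the full graph
.candidate_cliques <- function(graph, min = 3L, max = NULL) {
  cand <- which(igraph::degree(graph) > 2L)
  if (length(cand) < min) return(list())
  sub <- igraph::induced_subgraph(graph, cand)
  cl <- igraph::max_cliques(sub, min = min, max = max)
  lapply(cl, function(x) cand[as.integer(x)])
}

#' First-pass filter: 3- and 4-vertex cliques
#'
#' Finds maximal cliques of three or four vertices among
#' branchpoint-candidate (degree > 2) vertices, weights the members with
#' [weight_clique_candidates()], and removes the edge between the two
#' lowest-weighted members of each clique — eliminating 3-cliques and
#' simplifying 4-cliques. The pass repeats (edge removal can expose new
#' cliques) up to `max_iter` times. Removing one edge of a clique never
#' splits a connected component. Equal weights are broken towards the
#' lowest vertex-id pair for determinism.
#'
#' @param graph a vessel graph.
#' @param max_iter maximum number of sweeps.
#' @return the filtered graph.
#' @export
filter_class1 <- function(graph, max_iter = 5L) {
  for (it in seq_len(max_iter)) {
    cliques <- .candidate_cliques(graph, min = 3L, max = 4L)
    if (length(cliques) == 0L) break
    drop <- matrix(integer(0), ncol = 2)
    for (cl in cliques) {
      w <- weight_clique_candidates(graph, cl)
      ord <- order(w, cl) # ties -> lowest vertex ids
      pair <- sort(cl[ord[1:2]])
      drop <- rbind(drop, pair)
    }
    drop <- unique(drop)
    eids <- igraph::get_edge_ids(graph, as.vector(t(drop)), error = FALSE)
    eids <- eids[eids > 0]
    if (length(eids) == 0L) break
    graph <- igraph::delete_edges(graph, eids)
  }
  graph
}

#' Detect clique clusters
#'
#' Groups the vertices of all remaining maximal cliques (size >= 3) among
#' branchpoint candidates into connected clusters and classifies them by
#' size: class 2 clusters have fewer than 50 vertices, class 3 clusters
#' 50 or more (class 1 cliques are handled by [filter_class1()] first).
#'
#' @param graph a vessel graph.
#' @param class3_min vertex count at which a cluster becomes class 3.
#' @return list of clusters, each a list with `vertex_ids`,
#'   `cluster_class` (2 or 3) and `external_targets`.
#' @export
detect_clique_clusters <- function(graph, class3_min = 50L) {
  cliques <- .candidate_cliques(graph, min = 3L)
  if (length(cliques) == 0L) return(list())
  members <- sort(unique(unlist(cliques)))
  sub <- igraph::induced_subgraph(graph, members)
  comp <- igraph::components(sub)$membership
  lapply(split(members, comp), function(vids) {
    nb <- unique(unlist(lapply(vids, function(v)
      as.integer(igraph::neighbors(graph, v)))))
    list(vertex_ids = as.integer(vids),
         cluster_class = if (length(vids) >= class3_min) 3L else 2L,
         external_targets = setdiff(nb, vids))
  })
}

# Shared merge machinery: each group of vertices is replaced by one new
# vertex with the mean radius and (rounded) centroid coordinate of the
# group, wired to the supplied targets; `chains` lists pairs of group
# indices to connect (class 3 sliding-window order).
.merge_groups <- function(graph, groups, targets, chains = NULL) {
  n0 <- igraph::vcount(graph)
  rad <- igraph::V(graph)$radius
  co <- vertex_coords(graph)
  k <- length(groups)
  newz <- newy <- newx <- newr <- numeric(k)
  for (i in seq_len(k)) {
    vids <- groups[[i]]
    newr[i] <- mean(rad[vids])
    cen <- round(colMeans(co[vids, , drop = FALSE]))
    newz[i] <- cen[1]; newy[i] <- cen[2]; newx[i] <- cen[3]
  }
  graph <- igraph::add_vertices(graph, k, z = newz, y = newy, x = newx,
                                radius = newr)
  edges <- integer(0)
  for (i in seq_len(k)) {
    tg <- targets[[i]]
    if (length(tg)) edges <- c(edges, rbind(n0 + i, tg))
  }
  if (!is.null(chains) && nrow(chains)) {
    edges <- c(edges, rbind(n0 + chains[, 1], n0 + chains[, 2]))
  }
  if (length(edges)) graph <- igraph::add_edges(graph, edges)
  igraph::delete_vertices(graph, unlist(groups))
}

#' Second-pass filter for class 2 clusters
#'
#' Replaces a connected clique cluster of fewer than 50 vertices by a
#' single new vertex carrying the mean radius and the (voxel-rounded)
#' centroid coordinate of the cluster, connected to every external
#' projection target. A cluster without external targets becomes an
#' isolated vertex, removable by the downstream length filters.
#'
#' @param graph a vessel graph.
#' @param cluster one cluster from [detect_clique_clusters()].
#' @return the filtered graph.
#' @export
filter_class2 <- function(graph, cluster) {
  .merge_groups(graph, list(cluster$vertex_ids),
                list(cluster$external_targets))
}

#' Second-pass filter for class 3 clusters
#'
#' Large clusters (>= 50 vertices) are collapsed with a sliding window
#' scanned along the cluster's longest bounding-box axis: each window of
#' `window` voxels is merged per the class-2 rule (mean radius, preserved
#' external projections of that window), and consecutive window vertices
#' are connected in axis order.
#'
#' @param graph a vessel graph.
#' @param cluster one cluster from [detect_clique_clusters()].
#' @param window window length along the longest axis, in voxels.
#' @return the filtered graph.
#' @export
filter_class3 <- function(graph, cluster, window = 10) {
  vids <- cluster$vertex_ids
  co <- vertex_coords(graph)[vids, , drop = FALSE]
  span <- apply(co, 2, function(v) diff(range(v)))
  ax <- which.max(span)
  pos <- co[, ax]
  bin <- floor((pos - min(pos)) / window)
  ord <- sort(unique(bin))
  groups <- lapply(ord, function(b) vids[bin == b])
  targets <- lapply(groups, function(g) {
    nb <- unique(unlist(lapply(g, function(v)
      as.integer(igraph::neighbors(graph, v)))))
    setdiff(nb, vids)
  })
  k <- length(groups)
  chains <- if (k > 1L) cbind(seq_len(k - 1L), 2:k) else NULL
  .merge_groups(graph, groups, targets, chains)
}

#' Two-pass spurious-branchpoint filter
#'
#' Pass 1 removes 3-/4-vertex cliques by radius weighting
#' ([filter_class1()]); pass 2 detects remaining clique clusters and
#' collapses them by size class ([filter_class2()], [filter_class3()]).
#' The passes alternate until no maximal clique of size >= 3 remains among
#' branchpoint-candidate vertices (or `max_outer` rounds).
#'
#' @param graph a vessel graph.
#' @param window class-3 sliding-window length in voxels.
#' @param class3_min cluster size at which class 3 applies.
#' @param max_outer maximum pass-1/pass-2 rounds.
#' @return the filtered graph.
#' @export
filter_cliques <- function(graph, window = 10, class3_min = 50L,
                           max_outer = 3L) {
  for (i in seq_len(max_outer)) {
    graph <- filter_class1(graph)
    clusters <- detect_clique_clusters(graph, class3_min = class3_min)
    if (length(clusters) == 0L) break
    # merge all clusters in one batch: vertex ids stay valid because
    # clusters are vertex-disjoint and deletion happens last
    groups <- list(); targets <- list(); chains <- NULL
    base <- 0L
    for (cl in clusters) {
      if (cl$cluster_class == 2L) {
        groups <- c(groups, list(cl$vertex_ids))
        targets <- c(targets, list(cl$external_targets))
        base <- base + 1L
      } else {
        co <- vertex_coords(graph)[cl$vertex_ids, , drop = FALSE]
        span <- apply(co, 2, function(v) diff(range(v)))
        pos <- co[, which.max(span)]
        bin <- floor((pos - min(pos)) / window)
        gs <- lapply(sort(unique(bin)), function(b) cl$vertex_ids[bin == b])
        tg <- lapply(gs, function(g) {
          nb <- unique(unlist(lapply(g, function(v)
            as.integer(igraph::neighbors(graph, v)))))
          setdiff(nb, cl$vertex_ids)
        })
        k <- length(gs)
        if (k > 1L) {
          chains <- rbind(chains, cbind(base + seq_len(k - 1L), base + 2:k))
        }
        groups <- c(groups, gs)
        targets <- c(targets, tg)
        base <- base + k
      }
    }
    graph <- .merge_groups(graph, groups, targets, chains)
  }
  graph
}

#' Branchpoint labeling benchmark
#'
#' Compares pipeline branchpoint counts against a ground-truth label
#' volume in which each true branchpoint is marked by a sphere: the label
#' volume is skeletonized, its connected components are labeled and
#' counted to give the true branchpoint number, and the analysis pipeline
#' is run on the vasculature volume to count detected branchpoints.
#'
#' @param volume a [vasc_volume()] of the vasculature.
#' @param label_volume a [vasc_volume()] with spheres at true
#'   branchpoints.
#' @param ... parameters forwarded to [run_analysis()] (e.g.
#'   `filter_length`, `prune_length`).
#' @return list with `predicted`, `truth`, `accuracy` (1 - |error|) and
#'   `error` (signed relative error), both rates as proportions.
#' @export
benchmark_branchpoints <- function(volume, label_volume, ...) {
  stopifnot(inherits(volume, "vasc_volume"),
            inherits(label_volume, "vasc_volume"))
  truth_sk <- skeletonize(label_volume)
  truth <- count_components(truth_sk$mask)
  res <- run_analysis(volume, ...)
  predicted <- res$report$network$branchpoint_count
  err <- if (truth > 0) (predicted - truth) / truth else NA_real_
  list(predicted = predicted, truth = truth,
       accuracy = 1 - abs(err), error = err)
}
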