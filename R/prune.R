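# physical Euclidean length of every edge of the graph
.edge_lengths <- function(graph, resolution) {
  if (igraph::ecount(graph) == 0L) return(numeric(0))
  co <- vertex_coords(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  d <- (co[el[, 1], , drop = FALSE] - co[el[, 2], , drop = FALSE])
  d <- sweep(d, 2, resolution, `*`)
  sqrt(rowSums(d^2))
}

# components of the branchpoint-removed graph, with bookkeeping back to
# full-graph vertex ids; shared by pruning and feature extraction
.segment_components <- function(graph) {
  deg <- igraph::degree(graph)
  keep <- which(deg <= 2L)
  if (length(keep) == 0L) return(list())
  sub <- igraph::induced_subgraph(graph, keep)
  comp <- igraph::components(sub)$membership
  lapply(split(seq_along(keep), comp), function(si) {
    list(vids = keep[si], sub_ids = si)
  })
}

# order a path/cycle component end-to-end; returns full-graph vertex ids
.order_component <- function(graph, vids) {
  if (length(vids) == 1L) return(vids)
  sub <- igraph::induced_subgraph(graph, vids)
  sdeg <- igraph::degree(sub)
  term <- which(sdeg <= 1L)
  start <- if (length(term)) {
    # deterministic: terminus with the smallest coordinate
    co <- vertex_coords(graph)[vids[term], , drop = FALSE]
    term[order(co[, 1], co[, 2], co[, 3])[1]]
  } else 1L # cycle: arbitrary but fixed start
  ord <- as.integer(igraph::dfs(sub, root = start)$order)
  vids[ord]
}

#' Prune isolated and short endpoint segments
#'
#' Removes (1) isolated segments -- connected components containing no
#' branchpoint -- whose total chained-edge Euclidean length is below
#' `isolated_filter_length`, and (2) endpoint segments -- segments bounded
#' by one endpoint and one branchpoint -- shorter than
#' `endpoint_prune_length` (the branchpoint is retained and its degree
#' re-evaluated downstream). Pruned vertices' voxels are also removed from
#' a copy of the volume. Lengths are physical units of the volume
#' resolution; pruning lengths of 0 are a no-op. Endpoint pruning is a
#' single (non-recursive) pass; the decision length of an endpoint
#' segment includes its connecting edge to the branchpoint.
#'
#' @param graph a vessel graph (post clique filtering).
#' @param volume the [vasc_volume()] the graph came from.
#' @param isolated_filter_length,endpoint_prune_length thresholds in
#'   physical units; segments strictly shorter are removed.
#' @return list with the pruned `graph` and mirrored `volume`.
#' @export
prune_graph <- function(graph, volume, isolated_filter_length = 0,
                        endpoint_prune_length = 0) {
  stopifnot(inherits(volume, "vasc_volume"))
  if (isolated_filter_length < 0 || endpoint_prune_length < 0) {
    stop("pruning lengths must be >= 0", call. = FALSE)
  }
  res <- volume$resolution
  drop <- integer(0)
  deg <- igraph::degree(graph)

  # isolated segments: whole components without a branchpoint
  if (isolated_filter_length > 0 && igraph::vcount(graph) > 0L) {
    comp <- igraph::components(graph)$membership
    elen <- .edge_lengths(graph, res)
    el <- igraph::as_edgelist(graph, names = FALSE)
    ecomp <- comp[el[, 1]]
    clen <- tapply(elen, factor(ecomp, levels = seq_len(max(comp))), sum,
                   default = 0)
    has_bp <- tapply(deg > 2L, comp, any)
    bad <- which(!has_bp & clen < isolated_filter_length)
    if (length(bad)) drop <- which(comp %in% bad)
  }

  # endpoint segments: one endpoint terminus, one boundary branchpoint
  if (endpoint_prune_length > 0 && igraph::vcount(graph) > 0L) {
    co <- vertex_coords(graph)
    for (seg in .segment_components(graph)) {
      vids <- seg$vids
      if (any(vids %in% drop)) next
      bps <- unique(unlist(lapply(vids, function(v) {
        nb <- as.integer(igraph::neighbors(graph, v))
        nb[deg[nb] > 2L]
      })))
      has_end <- any(deg[vids] == 1L)
      if (length(bps) != 1L || !has_end) next
      path <- .order_component(graph, vids)
      # append the branchpoint coordinate at the attached end
      att <- which(vapply(path, function(v)
        bps %in% as.integer(igraph::neighbors(graph, v)), logical(1)))
      pc <- co[path, , drop = FALSE]
      if (length(att) && att[1] == 1L) pc <- rbind(co[bps, ], pc)
      else pc <- rbind(pc, co[bps, ])
      step <- sweep(diff(pc), 2, res, `*`)
      len <- sum(sqrt(rowSums(step^2)))
      if (len < endpoint_prune_length) drop <- c(drop, vids)
    }
  }

  drop <- unique(drop)
  vol2 <- volume
  if (length(drop)) {
    co <- vertex_coords(graph)[drop, , drop = FALSE]
    vol2$data[co + 1L] <- 0L
    graph <- igraph::delete_vertices(graph, drop)
  }
  list(graph = graph, volume = vol2)
}
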