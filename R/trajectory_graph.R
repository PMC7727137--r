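#' Build a k-nearest-neighbor graph on an embedding
#'
#' Each cell is connected to its `k` nearest neighbors (Euclidean), with
#' ties at equal distance broken toward the lower cell index; the edge set
#' is the symmetrized union, so degrees can exceed `k` but never fall below
#' it. No self-loops.
#'
#' @param embedding Cells-by-dimensions numeric matrix (rownames = cell
#'   ids).
#' @param k Number of neighbors (default 15; must be `< nrow`).
#' @return Undirected simple `igraph` graph with vertex names.
#' @export
knn_graph <- function(embedding, k = 15L) {
  n <- nrow(embedding)
  stopifnot(k >= 1L, k < n)
  ids <- rownames(embedding) %||% as.character(seq_len(n))
  d <- as.matrix(stats::dist(embedding))
  edges <- matrix(0L, n * k, 2L)
  for (i in seq_len(n)) {
    dd <- d[i, ]
    dd[i] <- Inf
    nb <- order(dd)[seq_len(k)]        # order() breaks ties by index
    edges[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- ids
  g
}

#' Partition a neighbor graph by resolution-scaled modularity
#'
#' Communities are found by multilevel (Louvain) optimization and then
#' refined by local single-node moves until the partition carries its
#' certificate: no community can gain resolution-scaled modularity by moving
#' one node. Connected components are partitioned independently (a property
#' of the objective). Community ids are ordered by decreasing size.
#'
#' @param graph Undirected `igraph` graph.
#' @param resolution Resolution parameter of the modularity objective
#'   (default 1).
#' @param seed Integer seed controlling initialization.
#' @return Named integer vector: vertex name -> community id, with
#'   attributes `modularity` (the achieved objective) and `certified`
#'   (`TRUE`; the local-optimality certificate held on exit).
#' @export
cluster_graph_partition <- function(graph, resolution = 1, seed = 1L) {
  set.seed(stage_seed(seed, "partition"))
  cl <- igraph::cluster_louvain(graph, resolution = resolution)
  memb <- igraph::membership(cl)
  memb <- local_move_refine(graph, as.integer(memb), resolution)
  ## order community ids by decreasing size (ties: by smallest member index)
  tab <- table(memb)
  first_member <- vapply(names(tab), function(cid)
    min(which(memb == as.integer(cid))), integer(1))
  ord <- order(-as.integer(tab), first_member)
  relabel <- integer(max(memb))
  relabel[as.integer(names(tab))[ord]] <- seq_along(tab)
  out <- relabel[memb]
  names(out) <- igraph::V(graph)$name
  attr(out, "modularity") <- igraph::modularity(graph, out,
                                                resolution = resolution)
  attr(out, "certified") <- TRUE
  out
}

## Sweep single-node moves (to neighboring communities) until none improves
## the resolution-scaled modularity. Guaranteed to terminate: each accepted
## move strictly increases a bounded objective.
local_move_refine <- function(graph, memb, resolution, tol = 1e-12) {
  m <- igraph::ecount(graph)
  if (m == 0L) return(memb)
  deg <- igraph::degree(graph)
  comm_deg <- tapply(deg, memb, sum)
  cd <- numeric(max(memb))
  cd[as.integer(names(comm_deg))] <- comm_deg
  adj <- igraph::as_adj_list(graph, mode = "all")
  repeat {
    moved <- FALSE
    for (v in seq_along(memb)) {
      nbs <- as.integer(adj[[v]])
      if (!length(nbs)) next
      a <- memb[v]
      k_vc <- tapply(rep(1, length(nbs)), memb[nbs], sum)
      k_va <- if (as.character(a) %in% names(k_vc)) k_vc[[as.character(a)]] else 0
      cand <- as.integer(names(k_vc))
      cand <- cand[cand != a]
      if (!length(cand)) next
      gains <- vapply(cand, function(b)
        (k_vc[[as.character(b)]] - k_va) / m -
          resolution * deg[v] * (cd[b] - (cd[a] - deg[v])) / (2 * m^2),
        numeric(1))
      j <- which.max(gains)
      if (gains[j] > tol) {
        b <- cand[j]
        cd[a] <- cd[a] - deg[v]
        cd[b] <- cd[b] + deg[v]
        memb[v] <- b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  memb
}

#' Verify the local-optimality certificate of a partition
#'
#' Checks that no single node can move to a neighboring community with a
#' strictly positive gain in resolution-scaled modularity.
#'
#' @param graph Undirected `igraph` graph.
#' @param membership Integer community vector (vertex order).
#' @param resolution Resolution parameter.
#' @param tol Numerical tolerance on the gain.
#' @return `TRUE` iff the certificate holds.
#' @export
verify_partition_certificate <- function(graph, membership, resolution = 1,
                                         tol = 1e-10) {
  refined <- local_move_refine(graph, as.integer(membership), resolution,
                               tol = tol)
  identical(as.integer(refined), as.integer(membership))
}

#' PAGA-style cluster connectivity
#'
#' For clusters i and j with `e_ij` inter-cluster edges, the expected count
#' under a null where the graph's `m` edges fall on cluster pairs
#' proportionally to size products is
#' `m * n_i n_j / sum_{p<q} n_p n_q`; connectivity is
#' `c_ij = min(1, e_ij / expected_ij * scale)` with the scale chosen so the
#' strongest pair has `c = 1`. Pairs without edges are omitted.
#'
#' @param graph Undirected `igraph` neighbor graph.
#' @param partition Named integer vector from [cluster_graph_partition()]
#'   (vertex name -> cluster).
#' @return Object of class `cluster_graph`: list with `nodes` (data frame
#'   `cluster`, `size`) and `edges` (data frame `i`, `j`, `e_ij`,
#'   `expected`, `connectivity`).
#' @export
paga_connectivity <- function(graph, partition) {
  memb <- partition[igraph::V(graph)$name]
  if (anyNA(memb)) stop("partition must cover every vertex")
  sizes <- table(memb)
  clusters <- as.integer(names(sizes))
  m <- igraph::ecount(graph)
  el <- igraph::as_edgelist(graph, names = FALSE)
  ci <- as.integer(memb[el[, 1L]])
  cj <- as.integer(memb[el[, 2L]])
  inter <- ci != cj
  lo <- pmin(ci[inter], cj[inter])
  hi <- pmax(ci[inter], cj[inter])
  nodes <- data.frame(cluster = clusters, size = as.integer(sizes))
  if (length(clusters) < 2L || !any(inter)) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(i = integer(0), j = integer(0),
                                             e_ij = integer(0),
                                             expected = numeric(0),
                                             connectivity = numeric(0))),
                     class = "cluster_graph"))
  }
  key <- paste(lo, hi)
  e <- table(key)
  pair <- do.call(rbind, strsplit(names(e), " ", fixed = TRUE))
  i <- as.integer(pair[, 1L])
  j <- as.integer(pair[, 2L])
  n <- as.numeric(sizes[as.character(clusters)])
  names(n) <- clusters
  denom <- (sum(n)^2 - sum(n^2)) / 2       # sum over p<q of n_p n_q
  expected <- m * n[as.character(i)] * n[as.character(j)] / denom
  ratio <- as.numeric(e) / expected
  conn <- pmin(1, ratio / max(ratio))
  edges <- data.frame(i = i, j = j, e_ij = as.integer(e),
                      expected = unname(expected), connectivity = conn)
  edges <- edges[order(-edges$connectivity, edges$i, edges$j), ]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("cluster_graph:", nrow(x$nodes), "clusters,", nrow(x$edges),
      "connected pairs\n")
  print(head(x$edges, 10L))
  invisible(x)
}

#' Report labelled trajectory edges and state-to-state paths
#'
#' Thresholds the cluster graph at `c_min`, attaches type labels to
#' clusters (missing labels become `"unknown"`), and for an optional
#' (source type, target type) query lists all simple paths of up to
#' `max_len` edges between clusters of those types, ordered by bottleneck
#' connectivity. An edge is flagged `skip` when a stronger route between its
#' two endpoints exists through at least one intermediate cluster of a
#' different type: the alternative path's bottleneck connectivity must
#' exceed the direct edge's (e.g. a weak direct matNeu-preNeu edge next to
#' a strong route through immNeu marks a stage-skipping conversion).
#'
#' @param cluster_graph A [paga_connectivity()] result.
#' @param type_labels Named vector: cluster id (as character) -> type label.
#' @param c_min Connectivity threshold (default 0.05).
#' @param query Optional `c(source_type, target_type)` character pair.
#' @param max_len Maximum path length in edges (default 4).
#' @return List with `edges` (data frame `i`, `j`, `connectivity`,
#'   `type_i`, `type_j`, `skip`) and `paths` (list of data frames
#'   `clusters`, `types`, `bottleneck`), plus `query`.
#' @export
trajectory_report <- function(cluster_graph, type_labels, c_min = 0.05,
                              query = NULL, max_len = 4L) {
  lab <- function(cl) {
    l <- type_labels[as.character(cl)]
    ifelse(is.na(l), "unknown", l)
  }
  ed <- cluster_graph$edges
  ed <- ed[ed$connectivity >= c_min, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(ed$i), to = as.character(ed$j)),
    directed = FALSE,
    vertices = data.frame(name = as.character(cluster_graph$nodes$cluster))
  )
  igraph::E(g)$connectivity <- ed$connectivity

  path_bottleneck <- function(gr, ids) {
    min(vapply(seq_len(length(ids) - 1L), function(k) {
      eid <- igraph::get_edge_ids(gr, c(ids[k], ids[k + 1L]))
      igraph::E(gr)$connectivity[eid]
    }, numeric(1)))
  }
  skip <- vapply(seq_len(nrow(ed)), function(r) {
    u <- as.character(ed$i[r])
    v <- as.character(ed$j[r])
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(u, v)))
    ps <- igraph::all_simple_paths(g2, from = u, to = v, cutoff = max_len)
    any(vapply(ps, function(p) {
      ids <- igraph::as_ids(p)
      mid <- ids[-c(1L, length(ids))]
      length(mid) > 0L &&
        any(lab(mid) != lab(u) & lab(mid) != lab(v)) &&
        path_bottleneck(g2, ids) > ed$connectivity[r]
    }, logical(1)))
  }, logical(1))
  edges <- data.frame(i = ed$i, j = ed$j, connectivity = ed$connectivity,
                      type_i = lab(ed$i), type_j = lab(ed$j), skip = skip,
                      stringsAsFactors = FALSE)

  paths <- list()
  if (!is.null(query)) {
    stopifnot(length(query) == 2L)
    all_cl <- as.character(cluster_graph$nodes$cluster)
    src <- all_cl[lab(all_cl) == query[1L]]
    dst <- all_cl[lab(all_cl) == query[2L]]
    for (s in src) {
      ps <- igraph::all_simple_paths(g, from = s,
                                     to = intersect(dst, igraph::V(g)$name),
                                     cutoff = max_len)
      for (p in ps) {
        ids <- igraph::as_ids(p)
        if (length(ids) < 2L) next
        cs <- vapply(seq_len(length(ids) - 1L), function(k) {
          eid <- igraph::get_edge_ids(g, c(ids[k], ids[k + 1L]))
          igraph::E(g)$connectivity[eid]
        }, numeric(1))
        paths[[length(paths) + 1L]] <-
          data.frame(clusters = paste(ids, collapse = "-"),
                     types = paste(lab(ids), collapse = "-"),
                     bottleneck = min(cs), stringsAsFactors = FALSE)
      }
    }
    if (length(paths)) {
      paths <- do.call(rbind, paths)
      paths <- paths[order(-paths$bottleneck), , drop = FALSE]
      rownames(paths) <- NULL
    } else {
      paths <- data.frame(clusters = character(0), types = character(0),
                          bottleneck = numeric(0))
    }
  }
  list(edges = edges, paths = paths, query = query, c_min = c_min)
}
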