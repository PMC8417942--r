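#' Overlapping rectangular cover of a 2-D lens
#'
#' Per axis the range is split into `resolution` base intervals of width
#' `w = range / resolution`; interval `i` (0-based) is widened symmetrically
#' to `[min + i w - o w / 2, min + (i + 1) w + o w / 2]` with `o = overlap`.
#' The 2-D cover is the product grid, so there are `resolution^2` closed
#' rectangles and every sample lies in at least one. A degenerate axis
#' (zero range) contributes a single interval.
#'
#' @param lens An `mds_lens` (or any list with an n x 2 `coords` matrix with
#'   row names).
#' @param resolution Number of base intervals per axis (>= 1).
#' @param overlap Fractional widening of each interval, in `[0, 1)`.
#' @return A list of cover bins; each bin is a list with `index` = c(i, j)
#'   (1-based grid position), `x_interval`, `y_interval`, and `members`
#'   (character vector of sample IDs). Empty bins are retained.
#' @export
build_cover <- function(lens, resolution = 85L, overlap = 0.85) {
  stopifnot(resolution >= 1, overlap >= 0, overlap < 1)
  coords <- lens$coords
  ids <- rownames(coords)
  axis_intervals <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi - lo <= 0) return(matrix(c(lo, hi), nrow = 1L))
    w <- (hi - lo) / resolution
    i <- seq_len(resolution) - 1L
    cbind(lo + i * w - overlap * w / 2, lo + (i + 1L) * w + overlap * w / 2)
  }
  xi <- axis_intervals(coords[, 1L])
  yi <- axis_intervals(coords[, 2L])
  bins <- vector("list", nrow(xi) * nrow(yi))
  k <- 0L
  for (i in seq_len(nrow(xi))) {
    in_x <- coords[, 1L] >= xi[i, 1L] & coords[, 1L] <= xi[i, 2L]
    for (j in seq_len(nrow(yi))) {
      in_y <- coords[, 2L] >= yi[j, 1L] & coords[, 2L] <= yi[j, 2L]
      k <- k + 1L
      bins[[k]] <- list(index = c(i, j),
                        x_interval = xi[i, ], y_interval = yi[j, ],
                        members = ids[in_x & in_y])
    }
  }
  bins
}

#' Optimize the DBSCAN eps from nearest-neighbour distances
#'
#' Returns the `coverage_threshold` quantile (nearest-rank, no
#' interpolation) of the per-sample nearest-neighbour distance
#' distribution: with threshold q on n samples, the `ceiling(q * n)`-th
#' order statistic of the n distances to each sample's closest other
#' sample.
#'
#' @param D Square symmetric distance matrix, n >= 2.
#' @param coverage_threshold Quantile in (0, 1] (default 0.95).
#' @return A positive scalar eps.
#' @export
optimize_eps <- function(D, coverage_threshold = 0.95) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(n >= 2, coverage_threshold > 0, coverage_threshold <= 1)
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  unname(sort(nn)[ceiling(coverage_threshold * n)])
}

#' Density-cluster the samples of one cover bin
#'
#' DBSCAN on the original-space distance submatrix of the bin's members:
#' a point is core when at least `min_samples` points (itself included) lie
#' within `eps`; clusters are the connected components of core points under
#' eps-reachability, plus border points, each attached to the cluster of its
#' nearest core point (ties broken by sample identifier, so the result does
#' not depend on member order). Noise points belong to no cluster.
#'
#' @param members Character vector of sample IDs in the bin.
#' @param D Full distance matrix (subset internally).
#' @param eps Neighbourhood radius.
#' @param min_samples Core-point threshold, self included (default 5).
#' @return A list of character vectors (clusters, each sorted); possibly
#'   empty.
#' @export
cluster_bin <- function(members, D, eps, min_samples = 5L) {
  members <- sort(members)
  m <- length(members)
  if (!m) return(list())
  d <- D[members, members, drop = FALSE]
  nbr <- d <= eps # self included (diagonal 0)
  core <- rowSums(nbr) >= min_samples
  if (!any(core)) return(list())
  # connected components of the core-core eps graph
  core_idx <- which(core)
  adj <- nbr[core_idx, core_idx, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  cluster_of <- rep(NA_integer_, m)
  cluster_of[core_idx] <- comp
  # border points join the cluster of their nearest core point
  for (i in which(!core)) {
    reach <- core_idx[nbr[i, core_idx]]
    if (length(reach)) {
      nearest <- reach[order(d[i, reach], members[reach])][1L]
      cluster_of[i] <- cluster_of[nearest]
    }
  }
  out <- split(members[!is.na(cluster_of)], cluster_of[!is.na(cluster_of)])
  unname(lapply(out, sort))
}

#' Assemble the Mapper network (nerve of the clustered cover)
#'
#' One node per within-bin cluster; an undirected edge joins two nodes
#' exactly when they share at least one sample. Node positions are the mean
#' lens coordinates of their members.
#'
#' @param cover Output of [build_cover()].
#' @param clusters List parallel to `cover`: per-bin output of
#'   [cluster_bin()].
#' @param lens The lens the cover was built from.
#' @param params Optional named list of parameters recorded on the network.
#' @return An object of class `tda_network`: `nodes` (named list of member
#'   ID vectors), `node_meta` (data.frame: node, bin_i, bin_j, size, x, y),
#'   `edges` (data.frame: from, to), `graph` (igraph), `params`.
#' @export
build_network <- function(cover, clusters, lens, params = list()) {
  stopifnot(length(cover) == length(clusters))
  nodes <- list()
  meta <- list()
  for (b in seq_along(cover)) {
    cl <- clusters[[b]]
    if (!length(cl)) next
    for (k in seq_along(cl)) {
      id <- sprintf("n%d_%d_%d", cover[[b]]$index[1L], cover[[b]]$index[2L], k)
      nodes[[id]] <- cl[[k]]
      xy <- lens$coords[cl[[k]], , drop = FALSE]
      meta[[id]] <- data.frame(node = id,
                               bin_i = cover[[b]]$index[1L],
                               bin_j = cover[[b]]$index[2L],
                               size = length(cl[[k]]),
                               x = mean(xy[, 1L]), y = mean(xy[, 2L]),
                               stringsAsFactors = FALSE)
    }
  }
  node_ids <- names(nodes)
  n_nodes <- length(node_ids)
  edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  if (n_nodes > 1L) {
    all_samples <- sort(unique(unlist(nodes)))
    M <- matrix(0L, nrow = length(all_samples), ncol = n_nodes,
                dimnames = list(all_samples, node_ids))
    for (v in node_ids) M[nodes[[v]], v] <- 1L
    shared <- crossprod(M)
    diag(shared) <- 0L
    idx <- which(shared > 0 & upper.tri(shared), arr.ind = TRUE)
    if (nrow(idx)) edges <- data.frame(from = node_ids[idx[, 1L]],
                                       to = node_ids[idx[, 2L]],
                                       stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = as.character(node_ids),
                                                           stringsAsFactors = FALSE))
  node_meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(node = character(), bin_i = integer(), bin_j = integer(),
               size = integer(), x = numeric(), y = numeric())
  rownames(node_meta) <- NULL
  structure(list(nodes = nodes, node_meta = node_meta, edges = edges,
                 graph = g, params = params),
            class = "tda_network")
}

#' @export
print.tda_network <- function(x, ...) {
  cat("Mapper network:", length(x$nodes), "nodes,", nrow(x$edges), "edges,",
      length(unique(unlist(x$nodes))), "retained samples\n")
  invisible(x)
}

#' Fraction of samples retained in the network
#'
#' The cover ratio: size of the union of all node member sets over the
#' number of input samples. Samples lost to DBSCAN noise (or to bins
#' smaller than the core-point requirement) lower it.
#'
#' @param network A `tda_network`.
#' @param n_total Number of input samples.
#' @return A real in `[0, 1]`.
#' @export
cover_ratio <- function(network, n_total) {
  retained <- length(unique(unlist(network$nodes)))
  stopifnot(n_total >= retained)
  if (n_total == 0) return(0)
  retained / n_total
}

#' Build a Mapper network from distances and a lens
#'
#' Convenience wrapper chaining [build_cover()], [optimize_eps()],
#' [cluster_bin()] over all bins, and [build_network()]. Defaults are the
#' pipeline's final settings: resolution 85, overlap 0.85, eps at the 0.95
#' nearest-neighbour quantile, DBSCAN minimum neighbourhood 5.
#'
#' @param D Distance matrix over all samples.
#' @param lens An `mds_lens` over the same samples.
#' @param resolution,overlap Cover parameters (see [build_cover()]).
#' @param eps_threshold Quantile for [optimize_eps()].
#' @param min_samples DBSCAN core threshold.
#' @return A `tda_network`; `params` records all settings plus the chosen
#'   eps and the dropped-sample count.
#' @export
build_mapper <- function(D, lens, resolution = 85L, overlap = 0.85,
                         eps_threshold = 0.95, min_samples = 5L) {
  cover <- build_cover(lens, resolution = resolution, overlap = overlap)
  eps <- optimize_eps(D, eps_threshold)
  clusters <- lapply(cover, function(b) {
    if (length(b$members) < min_samples) list()
    else cluster_bin(b$members, D, eps, min_samples)
  })
  net <- build_network(cover, clusters, lens,
                       params = list(resolution = resolution, overlap = overlap,
                                     eps = eps, eps_threshold = eps_threshold,
                                     min_samples = min_samples))
  net$params$n_input <- nrow(lens$coords)
  net$params$n_retained <- length(unique(unlist(net$nodes)))
  net$params$n_dropped <- net$params$n_input - net$params$n_retained
  net
}

#' Export a Mapper network as GraphML plus a membership sidecar
#'
#' Writes the network graph (node attributes: size, centroid x/y) in
#' GraphML and a JSON file mapping node ID to member sample IDs.
#'
#' @param network A `tda_network`.
#' @param graphml_path,membership_path Output paths.
#' @return `graphml_path`, invisibly.
#' @export
write_network <- function(network, graphml_path, membership_path = NULL) {
  g <- network$graph
  meta <- network$node_meta[match(igraph::V(g)$name, network$node_meta$node), ]
  igraph::V(g)$size <- meta$size
  igraph::V(g)$x <- meta$x
  igraph::V(g)$y <- meta$y
  igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(membership_path))
    jsonlite::write_json(network$nodes, membership_path, auto_unbox = FALSE)
  invisible(graphml_path)
}

#' Read a Mapper network from GraphML plus membership sidecar
#'
#' @param graphml_path,membership_path Paths written by [write_network()].
#' @return A `tda_network` (without cover bin provenance).
#' @export
read_network <- function(graphml_path, membership_path) {
  g <- igraph::read_graph(graphml_path, format = "graphml")
  nodes <- lapply(jsonlite::read_json(membership_path), function(v)
    vapply(v, as.character, character(1L)))
  names(nodes) <- names(jsonlite::read_json(membership_path))
  vn <- igraph::V(g)$name
  node_meta <- data.frame(node = vn, bin_i = NA_integer_, bin_j = NA_integer_,
                          size = igraph::V(g)$size,
                          x = igraph::V(g)$x, y = igraph::V(g)$y,
                          stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1L], to = el[, 2L], stringsAsFactors = FALSE)
  structure(list(nodes = nodes[vn], node_meta = node_meta, edges = edges,
                 graph = g, params = list()),
            class = "tda_network")
}
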