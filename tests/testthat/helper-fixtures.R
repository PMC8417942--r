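# Shared fixtures and independent oracles, all built in code.

# hand-constructed network for SAFE/co-enrichment unit tests; edges given
# explicitly so graph topologies can be designed directly
toy_network <- function(members, edges = NULL) {
  ids <- names(members)
  if (is.null(edges)) {
    pairs <- list()
    if (length(ids) > 1L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq(i + 1L, length(ids))) {
          if (length(intersect(members[[i]], members[[j]])))
            pairs[[length(pairs) + 1L]] <- c(ids[i], ids[j])
        }
      }
    }
    edges <- if (length(pairs))
      data.frame(from = vapply(pairs, `[`, "", 1L),
                 to = vapply(pairs, `[`, "", 2L), stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids,
                                                           stringsAsFactors = FALSE))
  structure(list(nodes = members,
                 node_meta = data.frame(node = ids, stringsAsFactors = FALSE),
                 edges = edges, graph = g, params = list()),
            class = "tda_network")
}

# lattice network with one sample per node, for permutation-test unit tests
lattice_network <- function(nrow_l, ncol_l) {
  n <- nrow_l * ncol_l
  ids <- sprintf("v%03d", seq_len(n))
  idx <- function(i, j) (i - 1L) * ncol_l + j
  from <- character(0); to <- character(0)
  for (i in seq_len(nrow_l)) for (j in seq_len(ncol_l)) {
    if (j < ncol_l) { from <- c(from, ids[idx(i, j)]); to <- c(to, ids[idx(i, j + 1L)]) }
    if (i < nrow_l) { from <- c(from, ids[idx(i, j)]); to <- c(to, ids[idx(i + 1L, j)]) }
  }
  members <- as.list(paste0("s_", ids))
  names(members) <- ids
  toy_network(members, data.frame(from = from, to = to, stringsAsFactors = FALSE))
}

# breadth-first search oracle for hop distances
bfs_distances <- function(edges, ids) {
  adj <- lapply(ids, function(v) character(0))
  names(adj) <- ids
  for (k in seq_len(nrow(edges))) {
    adj[[edges$from[k]]] <- c(adj[[edges$from[k]]], edges$to[k])
    adj[[edges$to[k]]] <- c(adj[[edges$to[k]]], edges$from[k])
  }
  out <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  for (src in ids) {
    dist <- stats::setNames(rep(Inf, length(ids)), ids)
    dist[src] <- 0
    queue <- src
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (u in adj[[v]]) {
        if (!is.finite(dist[u])) {
          dist[u] <- dist[v] + 1
          queue <- c(queue, u)
        }
      }
    }
    out[src, ] <- dist
  }
  out
}

# exact hypergeometric upper tail by direct enumeration of overlap counts
hyper_tail_enum <- function(n, a, b, k) {
  js <- seq(k, min(a, b))
  if (!length(js)) return(0)
  sum(vapply(js, function(j) choose(a, j) * choose(n - a, b - j), numeric(1L))) /
    choose(n, b)
}

# brute-force DBSCAN oracle: transitive closure of the eps graph over cores
dbscan_oracle <- function(members, D, eps, min_samples) {
  members <- sort(members)
  d <- D[members, members, drop = FALSE]
  nbr <- d <= eps
  core <- rowSums(nbr) >= min_samples
  if (!any(core)) return(list())
  m <- length(members)
  reach <- matrix(FALSE, m, m)
  for (i in 1:m) for (j in 1:m) reach[i, j] <- core[i] && core[j] && nbr[i, j]
  # transitive closure
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  labels <- rep(NA_integer_, m)
  lab <- 0L
  for (i in which(core)) {
    if (is.na(labels[i])) {
      lab <- lab + 1L
      labels[reach[i, ] & core] <- lab
      labels[i] <- lab
    }
  }
  for (i in which(!core)) {
    cand <- which(core & nbr[i, ])
    if (length(cand)) {
      best <- cand[order(d[i, cand], members[cand])][1L]
      labels[i] <- labels[best]
    }
  }
  out <- split(members[!is.na(labels)], labels[!is.na(labels)])
  unname(lapply(out, sort))
}

# minimal safe_result with a designed enriched set
mk_res <- function(variable, enriched, nodes) {
  structure(list(variable = variable,
                 table = data.frame(node = nodes,
                                    observed = 0,
                                    p = ifelse(nodes %in% enriched, 0.001, 1),
                                    score = as.numeric(nodes %in% enriched),
                                    enriched = nodes %in% enriched,
                                    stringsAsFactors = FALSE),
                 enriched = enriched,
                 safe_enriched_score = length(enriched),
                 n_enriched = length(enriched),
                 n_permutations = 999L, threshold = 1, alpha = 0.05),
            class = "safe_result")
}

# small per-sample metadata table for io tests
toy_metadata <- function() {
  data.frame(
    sample_id = paste0("s", 1:8),
    country = c("A", "A", "A", "B", "B", "B", "B", "C"),
    study_id = c("st1", "st1", "st1", "st2", "st2", "st2", "st2", "st3"),
    age = c(30, 40, NA, 25, 35, 45, 55, 60),
    sex = c("Female", "Male", "Female", "Missing", "Male", "Female", "Male", "Female"),
    bmi_value = c(17, 22, 27, 31, NA, 24.9, 18.5, 29.9),
    stringsAsFactors = FALSE
  ) |> transform(bmi_category = bin_bmi(bmi_value))
}

small_cohort_params <- function(n_countries = 2L, n = 50L) {
  cp <- default_country_params()[seq_len(n_countries), ]
  cp$n <- rep(as.integer(n), n_countries)
  cp
}
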