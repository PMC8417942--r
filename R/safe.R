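#' Map per-sample values onto network nodes
#'
#' The node attribute is the arithmetic mean of the variable over the node's
#' member samples: mean abundance for a taxon, mean age, or the proportion
#' of a dummy-coded level. Missing sample values are excluded from the mean;
#' a node whose members are all missing gets value 0 and is flagged.
#'
#' @param network A `tda_network`.
#' @param values Named numeric vector (names = sample IDs); `NA` = missing.
#' @return Named numeric vector over nodes, with attribute `all_missing`
#'   (character vector of flagged nodes).
#' @export
node_values <- function(network, values) {
  members <- unique(unlist(network$nodes))
  have <- intersect(members, names(values))
  if (!length(have) || all(is.na(values[have])))
    stop("variable has no observed value for any network sample")
  out <- numeric(length(network$nodes))
  names(out) <- names(network$nodes)
  flagged <- character(0)
  for (v in names(network$nodes)) {
    x <- values[network$nodes[[v]]]
    x <- x[!is.na(x)]
    if (!length(x)) {
      out[v] <- 0
      flagged <- c(flagged, v)
    } else out[v] <- mean(x)
  }
  attr(out, "all_missing") <- flagged
  out
}

#' Pairwise node distances (hop counts)
#'
#' Unweighted shortest-path distances between all node pairs of the network
#' graph; disconnected pairs are `Inf`.
#'
#' @param network A `tda_network` with at least one node.
#' @return Square numeric matrix with node dimnames.
#' @export
node_distances <- function(network) {
  if (!length(network$nodes)) stop("network has no nodes")
  d <- igraph::distances(network$graph)
  ids <- names(network$nodes)
  d[ids, ids, drop = FALSE]
}

#' Local neighbourhoods under a node-distance percentile threshold
#'
#' The threshold t is the nearest-rank `percentile`-th percentile of all
#' finite off-diagonal pairwise node distances (unordered pairs); the
#' neighbourhood of node v is v itself plus every node within distance t.
#' The default 0.5th percentile keeps neighbourhoods tight, which localizes
#' the enrichment statistic.
#'
#' @param network A `tda_network`.
#' @param percentile Percentile in (0, 100] (default 0.5).
#' @return A list of class `safe_neighborhoods`: `sets` (named list of node
#'   ID vectors) and `threshold` (the distance cutoff).
#' @export
neighborhoods <- function(network, percentile = 0.5) {
  stopifnot(percentile > 0, percentile <= 100)
  ids <- names(network$nodes)
  d <- node_distances(network)
  ut <- d[upper.tri(d)]
  ut <- ut[is.finite(ut)]
  threshold <- if (!length(ut)) 0 else sort(ut)[max(1L, ceiling(percentile / 100 * length(ut)))]
  sets <- lapply(ids, function(v) ids[d[v, ] <= threshold | ids == v])
  names(sets) <- ids
  structure(list(sets = sets, threshold = threshold), class = "safe_neighborhoods")
}

#' SAFE permutation enrichment scores for one variable
#'
#' For each node v the observed statistic is the sum of the node attribute
#' over v's neighbourhood. The null distribution shuffles the attribute
#' values uniformly across nodes (`n_permutations` times) and recomputes all
#' neighbourhood sums. The one-sided (enrichment) p-value uses the add-one
#' estimator \eqn{p_v = (1 + \#\{perm \ge obs\}) / (1 + P)}, so the smallest
#' attainable p is exactly 1/(P+1). The SAFE score is the log-transformed,
#' normalized p-value \eqn{S_v = \log_{10} p_v / \log_{10}(1/(P+1))},
#' clipped to `[0, 1]`; the minimum p maps to score 1 and p = 1 to score 0.
#'
#' @param network A `tda_network`.
#' @param attr Node attribute vector from [node_values()].
#' @param nbhd A `safe_neighborhoods` (default: computed at the 0.5th
#'   percentile).
#' @param n_permutations Number of permutations P (default 5000).
#' @param seed Integer seed; scores are deterministic given it.
#' @param alpha Node-significance cutoff used for the enriched set and the
#'   network-level score (default 0.05, strict inequality).
#' @param variable Variable name recorded on the result.
#' @return An object of class `safe_result`: `variable`, `table`
#'   (data.frame: node, observed, p, score, enriched), `enriched` (node
#'   IDs), `safe_enriched_score` (sum of scores over enriched nodes),
#'   `n_enriched`, `n_permutations`, `threshold` (neighbourhood distance),
#'   `alpha`.
#' @export
safe_scores <- function(network, attr, nbhd = NULL, n_permutations = 5000L,
                        seed = 1L, alpha = 0.05, variable = "variable") {
  stopifnot(n_permutations >= 1)
  if (is.null(nbhd)) nbhd <- neighborhoods(network)
  ids <- names(network$nodes)
  n <- length(ids)
  vals <- as.numeric(attr[ids])
  # neighbourhood incidence: A[v, u] = 1 iff u in nbhd(v)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (v in ids) A[v, nbhd$sets[[v]]] <- 1
  observed <- as.numeric(A %*% vals)
  P <- as.integer(n_permutations)
  exceed <- integer(n)
  withr::with_seed(seed, {
    # permutations in blocks to bound memory at larger P
    block <- 500L
    done <- 0L
    while (done < P) {
      b <- min(block, P - done)
      V <- vapply(seq_len(b), function(i) vals[sample.int(n)], numeric(n))
      sums <- A %*% V
      exceed <- exceed + rowSums(sums >= observed - 1e-12)
      done <- done + b
    }
  })
  p <- (1 + exceed) / (1 + P)
  score <- pmin(1, pmax(0, log10(p) / log10(1 / (1 + P))))
  enriched <- ids[p < alpha]
  tab <- data.frame(node = ids, observed = observed, p = p, score = score,
                    enriched = p < alpha, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(variable = variable, table = tab, enriched = enriched,
                 safe_enriched_score = sum(score[p < alpha]),
                 n_enriched = length(enriched),
                 n_permutations = P, threshold = nbhd$threshold, alpha = alpha),
            class = "safe_result")
}

#' @export
print.safe_result <- function(x, ...) {
  cat(sprintf("SAFE result '%s': %d/%d nodes enriched (alpha %g), enriched score %.2f\n",
              x$variable, x$n_enriched, nrow(x$table), x$alpha,
              x$safe_enriched_score))
  invisible(x)
}

#' Significantly enriched nodes of a SAFE result
#'
#' Nodes with permutation p-value strictly below `alpha`.
#'
#' @param result A `safe_result`.
#' @param alpha Significance cutoff (default 0.05).
#' @return Character vector of node IDs.
#' @export
enriched_nodes <- function(result, alpha = 0.05) {
  result$table$node[result$table$p < alpha]
}

#' Network-level SAFE enriched score
#'
#' Sum of SAFE scores over the significantly enriched nodes — the
#' network-level association strength of a variable, comparable across
#' variables.
#'
#' @param result A `safe_result`.
#' @param alpha Significance cutoff (default the result's own alpha).
#' @return Non-negative scalar.
#' @export
safe_enriched_score <- function(result, alpha = result$alpha) {
  keep <- result$table$p < alpha
  sum(result$table$score[keep])
}

#' SAFE enrichment over many variables
#'
#' Runs [node_values()] and [safe_scores()] for every column of a
#' per-sample variable matrix (dummy-coded metadata levels, continuous
#' metadata, taxon abundances). Each variable draws its permutations from a
#' distinct stream derived from `seed`.
#'
#' @param network A `tda_network`.
#' @param sample_values Numeric matrix, rows = samples (named), columns =
#'   variables (named); `NA` = missing.
#' @param n_permutations,alpha,percentile See [safe_scores()] and
#'   [neighborhoods()].
#' @param seed Integer base seed.
#' @return Named list of `safe_result`, one per variable.
#' @export
safe_analysis <- function(network, sample_values, n_permutations = 5000L,
                          alpha = 0.05, percentile = 0.5, seed = 1L) {
  nbhd <- neighborhoods(network, percentile)
  vars <- colnames(sample_values)
  out <- vector("list", length(vars))
  names(out) <- vars
  for (k in seq_along(vars)) {
    vals <- sample_values[, k]
    names(vals) <- rownames(sample_values)
    attr_k <- node_values(network, vals)
    out[[k]] <- safe_scores(network, attr_k, nbhd,
                            n_permutations = n_permutations,
                            seed = (seed + 7919L * k) %% .Machine$integer.max,
                            alpha = alpha, variable = vars[k])
  }
  out
}

#' Rank variables by SAFE enriched score
#'
#' Descending by network-level enriched score, ties broken alphabetically by
#' variable name.
#'
#' @param results List of `safe_result`.
#' @return data.frame: variable, safe_enriched_score, n_enriched, in rank
#'   order.
#' @export
rank_variables <- function(results) {
  stopifnot(length(results) >= 1)
  df <- data.frame(
    variable = vapply(results, function(r) r$variable, character(1L)),
    safe_enriched_score = vapply(results, function(r) r$safe_enriched_score, numeric(1L)),
    n_enriched = vapply(results, function(r) r$n_enriched, integer(1L)),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$safe_enriched_score, df$variable), ]
  rownames(df) <- NULL
  df
}

#' Write SAFE results as a long tab-separated table
#'
#' One row per (variable, node): observed neighbourhood sum, p-value, SAFE
#' score and enriched flag; plus an optional per-variable summary.
#'
#' @param results List of `safe_result`.
#' @param path Long-table output path.
#' @param summary_path Optional per-variable summary output path.
#' @return `path`, invisibly.
#' @export
write_safe_results <- function(results, path, summary_path = NULL) {
  long <- do.call(rbind, lapply(results, function(r)
    cbind(variable = r$variable, r$table, stringsAsFactors = FALSE)))
  rownames(long) <- NULL
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.table(rank_variables(results), summary_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
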