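#' Co-enrichment p-value for a pair of variables
#'
#' Tests whether two variables enrich in overlapping regions of the network
#' by a one-sided Fisher exact (hypergeometric tail) test on the overlap of
#' their significantly enriched node sets: given enriched sets of sizes a
#' and b among n nodes with overlap k, the p-value is
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(n, a, b)}. Either
#' set empty returns 1 (no evidence of co-enrichment).
#'
#' @param a,b `safe_result` objects from the same network.
#' @param n_nodes Total number of network nodes.
#' @return A p-value in (0, 1]; symmetric in `a` and `b`.
#' @export
coenrichment_p <- function(a, b, n_nodes) {
  ea <- a$enriched
  eb <- b$enriched
  if (!length(ea) || !length(eb)) return(1)
  stopifnot(length(ea) <= n_nodes, length(eb) <= n_nodes)
  k <- length(intersect(ea, eb))
  stats::phyper(k - 1L, length(ea), n_nodes - length(ea), length(eb),
                lower.tail = FALSE)
}

#' Pairwise co-enrichment p-value matrix
#'
#' @param results Named list of `safe_result` from the same network.
#' @param n_nodes Total number of network nodes.
#' @return Symmetric matrix of p-values with unit diagonal set to 1.
#' @export
coenrichment_matrix <- function(results, n_nodes) {
  vars <- vapply(results, function(r) r$variable, character(1L))
  m <- length(vars)
  p <- matrix(1, m, m, dimnames = list(vars, vars))
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq(i + 1L, m)) {
        p[i, j] <- p[j, i] <- coenrichment_p(results[[i]], results[[j]], n_nodes)
      }
    }
  }
  p
}

#' Percentile-threshold and binarize a co-enrichment matrix
#'
#' The cutoff is the nearest-rank `percentile`-th percentile of the
#' upper-triangle p-values; a pair is called significantly co-enriched when
#' its p-value is at or below the cutoff. The strict default (0.5th
#' percentile) compensates for the large number of pairwise tests.
#'
#' @param p_matrix Symmetric p-value matrix.
#' @param percentile Percentile in (0, 100] (default 0.5).
#' @return An object of class `coenrichment_result`: `variables`,
#'   `p_matrix`, `threshold` (the cutoff p-value) and `binary_matrix`
#'   (symmetric 0/1, zero diagonal).
#' @export
threshold_binarize <- function(p_matrix, percentile = 0.5) {
  stopifnot(percentile > 0, percentile <= 100)
  vars <- rownames(p_matrix)
  m <- nrow(p_matrix)
  if (!m) {
    return(structure(list(variables = character(), p_matrix = p_matrix,
                          threshold = NA_real_,
                          binary_matrix = p_matrix), class = "coenrichment_result"))
  }
  if (max(abs(p_matrix - t(p_matrix))) > 1e-12) stop("p_matrix must be symmetric")
  ut <- p_matrix[upper.tri(p_matrix)]
  threshold <- if (!length(ut)) NA_real_ else
    sort(ut)[max(1L, ceiling(percentile / 100 * length(ut)))]
  binary <- matrix(0L, m, m, dimnames = dimnames(p_matrix))
  if (!is.na(threshold)) binary[p_matrix <= threshold] <- 1L
  diag(binary) <- 0L
  structure(list(variables = vars, p_matrix = p_matrix, threshold = threshold,
                 binary_matrix = binary),
            class = "coenrichment_result")
}

#' @export
print.coenrichment_result <- function(x, ...) {
  n_sig <- sum(x$binary_matrix[upper.tri(x$binary_matrix)])
  cat("co-enrichment over", length(x$variables), "variables:",
      n_sig, "significant pair(s) at threshold", signif(x$threshold, 4), "\n")
  invisible(x)
}

#' Most-enriched variable per node (network stratification)
#'
#' For each node, among the variables whose significantly enriched set
#' contains it, the one with the maximal SAFE score wins (ties broken
#' alphabetically). Nodes enriched for no variable get `NA` — the "grey"
#' nodes of a stratified network plot.
#'
#' @param results List of `safe_result` sharing a network.
#' @return data.frame: node, winner (variable name or `NA`), score.
#' @export
stratify_nodes <- function(results) {
  stopifnot(length(results) >= 1)
  nodes <- results[[1L]]$table$node
  winner <- rep(NA_character_, length(nodes))
  score <- rep(NA_real_, length(nodes))
  ord <- order(vapply(results, function(r) r$variable, character(1L)))
  for (r in results[ord]) {
    s <- r$table$score
    enr <- r$table$enriched
    better <- enr & (is.na(score) | s > score + 1e-15)
    winner[better] <- r$variable
    score[better] <- s[better]
  }
  data.frame(node = nodes, winner = winner, score = score,
             stringsAsFactors = FALSE)
}

#' Write co-enrichment matrices and a stratification table
#'
#' @param coe A `coenrichment_result`.
#' @param p_path,binary_path Output paths for the two square tables.
#' @param stratification Optional output of [stratify_nodes()].
#' @param strat_path Output path for the stratification table.
#' @return `p_path`, invisibly.
#' @export
write_coenrichment <- function(coe, p_path, binary_path,
                               stratification = NULL, strat_path = NULL) {
  wr <- function(mat, path) {
    df <- data.frame(variable = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(coe$p_matrix, p_path)
  wr(coe$binary_matrix, binary_path)
  if (!is.null(stratification) && !is.null(strat_path))
    utils::write.table(stratification, strat_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(p_path)
}
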