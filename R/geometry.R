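#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \deqn{BC(x, y) = 1 - \frac{2 \sum_i \min(x_i, y_i)}{\sum_i x_i + \sum_i y_i}}
#'
#' @param x,y Non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return A dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 && sy == 0) stop("Bray-Curtis is undefined for two all-zero vectors")
  1 - 2 * sum(pmin(x, y)) / (sx + sy)
}

#' Square-form Bray-Curtis distance matrix
#'
#' Pairwise Bray-Curtis dissimilarities over all samples of an abundance
#' table, as a symmetric square matrix with zero diagonal.
#'
#' @param x Row-normalized abundance matrix (samples x taxa), at least two
#'   samples, no all-zero rows.
#' @return A symmetric numeric matrix with `dimnames` = sample identifiers.
#' @export
pairwise_distances <- function(x) {
  validate_abundance(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  zero <- rowSums(x) == 0
  if (any(zero))
    stop("Bray-Curtis is undefined for all-zero sample(s): ",
         paste(rownames(x)[zero], collapse = ", "))
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Two-dimensional metric MDS lens
#'
#' Embeds a precomputed distance matrix in the plane by metric
#' multidimensional scaling: classical scaling (Torgerson) initialization
#' followed by stress majorization (SMACOF / Guttman transform) of the raw
#' stress \eqn{\sum_{i<j} (d_{ij} - \hat d_{ij})^2}. Iteration stops when the
#' relative stress decrease falls below `tol` or after `max_iter`
#' iterations. The reported `stress` is normalized,
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} (Kruskal stress-1 with metric
#' targets). Deterministic given `seed` (the seed only matters when
#' coincident points require a jitter to separate).
#'
#' @param D Square symmetric distance matrix.
#' @param seed Integer seed.
#' @param max_iter Maximum majorization iterations (default 300).
#' @param tol Relative stress-change tolerance (default 1e-6).
#' @return A list of class `mds_lens` with `coords` (n x 2 matrix, rows
#'   named by sample), `stress` (final normalized stress) and `n_iter`.
#' @export
mds_lens <- function(D, seed = 1L, max_iter = 300L, tol = 1e-6) {
  D <- as.matrix(D)
  n <- nrow(D)
  ids <- rownames(D)
  if (n == 1L) {
    coords <- matrix(0, 1L, 2L, dimnames = list(ids, c("x", "y")))
    return(structure(list(coords = coords, stress = 0, n_iter = 0L),
                     class = "mds_lens"))
  }
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  X <- withr::with_seed(seed, {
    X0 <- suppressWarnings(stats::cmdscale(D, k = 2L))
    if (ncol(X0) < 2L) X0 <- cbind(X0, 0)[, 1:2, drop = FALSE]
    # separate coincident points so the Guttman transform is defined
    dup <- duplicated(round(X0, 12L))
    if (any(dup)) X0[dup, ] <- X0[dup, ] + matrix(stats::rnorm(2 * sum(dup), 0, 1e-8),
                                                  ncol = 2L)
    X0
  })
  denom <- sum(D^2) / 2 # sum over unordered pairs
  stress_of <- function(E) sum((D - E)^2) / 2
  edist <- function(X) {
    E <- as.matrix(stats::dist(X))
    diag(E) <- 0
    E
  }
  E <- edist(X)
  s_old <- stress_of(E)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    ratio <- ifelse(E > 0, D / E, 0)
    B <- -ratio
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    E <- edist(X)
    s_new <- stress_of(E)
    n_iter <- it
    if (s_old <= 0 || (s_old - s_new) / s_old < tol) {
      s_old <- s_new
      break
    }
    s_old <- s_new
  }
  colnames(X) <- c("x", "y")
  rownames(X) <- ids
  structure(list(coords = X, stress = sqrt(s_old / denom), n_iter = n_iter),
            class = "mds_lens")
}

#' @export
print.mds_lens <- function(x, ...) {
  cat("2-D metric MDS lens:", nrow(x$coords), "points, stress",
      signif(x$stress, 4), "after", x$n_iter, "iterations\n")
  invisible(x)
}

#' Zero-dimensional persistence diagram
#'
#' Tracks connected components of the distance graph as the scale grows:
#' every point is born at 0; components die at the single-linkage merge
#' heights (equivalently, the minimum-spanning-tree edge weights); one bar
#' per final connected component persists to infinity. For a connected
#' distance matrix on n points this gives n - 1 finite deaths plus one
#' infinite bar.
#'
#' @param D Square symmetric distance matrix.
#' @return A list of class `h0_diagram` with `deaths` (sorted, `Inf` last)
#'   and `n_points`.
#' @export
h0_persistence <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n == 1L) {
    return(structure(list(deaths = Inf, n_points = 1L), class = "h0_diagram"))
  }
  heights <- stats::hclust(stats::as.dist(D), method = "single")$height
  structure(list(deaths = c(sort(heights), Inf), n_points = n),
            class = "h0_diagram")
}

#' @export
print.h0_diagram <- function(x, ...) {
  cat("H0 persistence diagram:", x$n_points, "bars,",
      sum(is.finite(x$deaths)), "finite deaths\n")
  invisible(x)
}

#' Count high-persistence H0 bars
#'
#' Estimates the number of robust clusters from an H0 diagram by the
#' largest-gap rule: the finite deaths are sorted and the largest gap
#' between consecutive deaths separates low-persistence "noise" merges from
#' the high-persistence merges between genuine clusters; the bars dying
#' above that gap, plus the one infinite bar, are the clusters. A diagram
#' whose finite deaths are all (nearly) equal distinguishes no scale and
#' counts as a single cluster.
#'
#' @param diagram An `h0_diagram`.
#' @param tol Gap width below which deaths are considered indistinguishable
#'   (default 1e-8).
#' @return Integer cluster count (>= 1).
#' @export
count_high_persistence <- function(diagram, tol = 1e-8) {
  finite <- sort(diagram$deaths[is.finite(diagram$deaths)])
  m <- length(finite)
  if (m == 0L) return(1L)
  if (m == 1L) return(2L)
  gaps <- diff(finite)
  if (max(gaps) <= tol) return(1L)
  j <- which.max(gaps) # deaths 1..j are below the gap
  (m - j) + 1L
}

#' Write an H0 diagram as two-column text
#'
#' @param diagram An `h0_diagram`.
#' @param path Output path; infinite deaths are written as `inf`.
#' @return `path`, invisibly.
#' @export
write_h0_diagram <- function(diagram, path) {
  death <- ifelse(is.finite(diagram$deaths), format(diagram$deaths, digits = 12), "inf")
  utils::write.table(data.frame(birth = 0, death = death), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix as a square tab-separated table
#' @param D Distance matrix with sample dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(sample_id = rownames(D), D, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
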