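test_that("cover intervals follow the widened-grid convention", {
  coords <- cbind(x = c(0, 0.4, 1), y = c(0, 0, 0))
  rownames(coords) <- paste0("s", 1:3)
  lens <- structure(list(coords = coords), class = "mds_lens")
  bins <- build_cover(lens, resolution = 2L, overlap = 0.5)
  # x range [0,1], w = 0.5, widened by 0.5*w/2 = 0.125 per side
  xi <- unique(t(vapply(bins, function(b) b$x_interval, numeric(2L))))
  expect_equal(xi[1, ], c(-0.125, 0.625))
  expect_equal(xi[2, ], c(0.375, 1.125))
  # shared region [0.375, 0.625] has width w * overlap / ... = 0.25
  expect_equal(xi[2, 1] - xi[1, 1], 0.5)
  expect_equal(xi[1, 2] - xi[2, 1], 0.25)
  # degenerate y axis collapses to a single interval; every sample covered
  expect_true(all(vapply(bins, function(b) all(b$y_interval == 0), logical(1L))))
  covered <- unique(unlist(lapply(bins, function(b) b$members)))
  expect_setequal(covered, paste0("s", 1:3))
  # sample 0.4 sits in the overlap of no bins; 0.4 < 0.375? no: in both? only bin 1
  expect_true("s2" %in% bins[[1]]$members)
})

test_that("cover degenerate settings: resolution 1 and zero overlap", {
  withr::with_seed(3, coords <- matrix(runif(40), ncol = 2))
  rownames(coords) <- paste0("s", 1:20)
  lens <- structure(list(coords = coords), class = "mds_lens")
  one <- build_cover(lens, resolution = 1L, overlap = 0.3)
  expect_length(one, 1L)
  expect_setequal(one[[1]]$members, paste0("s", 1:20))
  # overlap 0: bins partition samples up to boundary points
  part <- build_cover(lens, resolution = 3L, overlap = 0)
  counts <- table(unlist(lapply(part, function(b) b$members)))
  expect_true(all(counts >= 1))
  on_boundary <- sum(counts > 1)
  expect_equal(sum(vapply(part, function(b) length(b$members), integer(1L))),
               20 + on_boundary)
})

test_that("eps optimization takes the nearest-rank quantile of NN distances", {
  # 1-D points 0, 1, 3, 7: NN distances 1, 1, 2, 4
  D <- as.matrix(dist(c(0, 1, 3, 7)))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_equal(optimize_eps(D, 0.95), 4)   # ceil(0.95*4) = 4th order statistic
  expect_equal(optimize_eps(D, 0.5), 1)
  expect_equal(optimize_eps(D, 1.0), 4)    # maximum NN distance
  # all pairwise distances equal d
  De <- matrix(0.7, 5, 5); diag(De) <- 0
  dimnames(De) <- list(paste0("s", 1:5), paste0("s", 1:5))
  expect_equal(optimize_eps(De, 0.95), 0.7)
})

test_that("bin clustering has DBSCAN semantics and matches the brute-force oracle", {
  # 6 mutually close points form one cluster at min_samples 5
  ids <- paste0("s", 1:6)
  D <- matrix(0.1, 6, 6, dimnames = list(ids, ids)); diag(D) <- 0
  expect_equal(cluster_bin(ids, D, eps = 0.2, min_samples = 5L), list(ids))
  # 4 points cannot satisfy a core requirement of 5: all noise
  expect_equal(cluster_bin(ids[1:4], D, eps = 0.2, min_samples = 5L), list())
  # two separated groups of 6
  ids2 <- paste0("t", 1:12)
  D2 <- matrix(0.9, 12, 12, dimnames = list(ids2, ids2))
  D2[1:6, 1:6] <- 0.1; D2[7:12, 7:12] <- 0.1; diag(D2) <- 0
  got <- cluster_bin(ids2, D2, eps = 0.2, min_samples = 5L)
  expect_setequal(lapply(got, sort), list(sort(ids2[1:6]), sort(ids2[7:12])))
  # random instances against the transitive-closure oracle
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(6:15, 1)
      x <- matrix(rnorm(n * 2, sd = 0.5), ncol = 2)
      ids_r <- paste0("r", seq_len(n))
      Dr <- as.matrix(dist(x)); dimnames(Dr) <- list(ids_r, ids_r)
      eps <- quantile(Dr[upper.tri(Dr)], 0.3)
      got_r <- cluster_bin(ids_r, Dr, eps, min_samples = 3L)
      oracle <- dbscan_oracle(ids_r, Dr, eps, 3L)
      expect_setequal(got_r, oracle)
      # invariance to member ordering
      got_shuf <- cluster_bin(sample(ids_r), Dr, eps, min_samples = 3L)
      expect_setequal(got_shuf, got_r)
    }
  })
})

test_that("nerve edges equal the brute-force shared-sample relation", {
  coords <- cbind(c(0, 0.5, 1), c(0, 0, 0))
  rownames(coords) <- paste0("s", 1:3)
  lens <- structure(list(coords = rbind(coords, s4 = c(0.2, 0))), class = "mds_lens")
  cover <- list(list(index = c(1L, 1L), x_interval = c(0, 1), y_interval = c(0, 0),
                     members = rownames(lens$coords)))
  clusters <- list(list(c("s1", "s2"), c("s2", "s3"), "s4"))
  net <- build_network(cover, clusters, lens)
  expect_length(net$nodes, 3L)
  expect_equal(nrow(net$edges), 1L)  # only the s2-sharing pair
  # random small instances vs pairwise intersection oracle
  withr::with_seed(23, {
    for (rep in 1:8) {
      n_samp <- sample(10:40, 1)
      ids <- paste0("s", seq_len(n_samp))
      xy <- matrix(runif(2 * n_samp), ncol = 2, dimnames = list(ids, NULL))
      lens_r <- structure(list(coords = xy), class = "mds_lens")
      n_cl <- sample(3:8, 1)
      cl <- lapply(seq_len(n_cl), function(i) sample(ids, sample(2:6, 1)))
      cover_r <- list(list(index = c(1L, 1L), x_interval = 0:1, y_interval = 0:1,
                           members = ids))
      net_r <- build_network(cover_r, list(cl), lens_r)
      got_edges <- with(net_r$edges, paste(pmin(from, to), pmax(from, to)))
      exp_edges <- character(0)
      node_ids <- names(net_r$nodes)
      for (i in seq_len(n_cl - 1L)) for (j in seq(i + 1L, n_cl)) {
        if (length(intersect(cl[[i]], cl[[j]])))
          exp_edges <- c(exp_edges, paste(pmin(node_ids[i], node_ids[j]),
                                          pmax(node_ids[i], node_ids[j])))
      }
      expect_setequal(got_edges, exp_edges)
      # node membership and centroid integrity
      for (k in seq_len(n_cl)) {
        nid <- node_ids[k]
        expect_setequal(net_r$nodes[[nid]], cl[[k]])
        meta <- net_r$node_meta[net_r$node_meta$node == nid, ]
        expect_equal(meta$x, mean(xy[cl[[k]], 1]))
      }
    }
  })
})

test_that("cover ratio counts the union of node members", {
  members <- list(A = c("s1", "s2"), B = c("s2", "s3"))
  net <- toy_network(members)
  expect_equal(cover_ratio(net, 3), 1.0)
  expect_equal(cover_ratio(net, 6), 0.5)
  empty <- toy_network(stats::setNames(list(), character(0)))
  expect_equal(cover_ratio(empty, 10), 0)
})

test_that("a Mapper network over well-separated blobs has one component per blob", {
  withr::with_seed(31, {
    centers <- rbind(c(0, 0), c(5, 0), c(2.5, 5))
    xy <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(2 * 25, sd = 0.3), ncol = 2), 2, centers[k, ], `+`)))
  })
  rownames(xy) <- paste0("s", 1:75)
  lens <- structure(list(coords = xy), class = "mds_lens")
  D <- as.matrix(dist(xy))
  net <- build_mapper(D, lens, resolution = 6L, overlap = 0.5, min_samples = 3L)
  expect_equal(igraph::components(net$graph)$no, 3L)
  # the H0 diagram of the same distances counts the same number of clusters
  expect_equal(count_high_persistence(h0_persistence(D)), 3L)
  # every node's members sit inside its originating bin
  cover <- build_cover(lens, resolution = 6L, overlap = 0.5)
  for (nid in names(net$nodes)) {
    meta <- net$node_meta[net$node_meta$node == nid, ]
    bin <- Filter(function(b) identical(b$index, c(meta$bin_i, meta$bin_j)), cover)[[1]]
    expect_true(all(net$nodes[[nid]] %in% bin$members))
  }
})

test_that("network round-trips through GraphML plus membership JSON", {
  members <- list(A = c("s1", "s2"), B = c("s2", "s3"), C = "s4")
  net <- toy_network(members)
  net$node_meta$size <- lengths(members)
  net$node_meta$x <- c(0, 1, 2); net$node_meta$y <- c(0, 0, 1)
  g_path <- withr::local_tempfile(fileext = ".graphml")
  m_path <- withr::local_tempfile(fileext = ".json")
  write_network(net, g_path, m_path)
  got <- read_network(g_path, m_path)
  expect_setequal(names(got$nodes), names(members))
  expect_equal(got$nodes[order(names(got$nodes))], members[order(names(members))])
  expect_equal(igraph::ecount(got$graph), 1)
})
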