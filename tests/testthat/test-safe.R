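test_that("node attributes are member means with missing values excluded", {
  net <- toy_network(list(A = c("s1", "s2"), B = c("s2", "s3", "s4"), C = "s5"))
  vals <- c(s1 = 1, s2 = 0, s3 = NA, s4 = 4, s5 = 7)
  attr_v <- node_values(net, vals)
  expect_equal(unname(attr_v["A"]), 0.5)
  expect_equal(unname(attr_v["B"]), 2)     # mean of 0 and 4; NA excluded
  expect_equal(unname(attr_v["C"]), 7)
  # all-missing node maps to 0 and is flagged
  vals2 <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 3, s5 = NA)
  attr2 <- node_values(net, vals2)
  expect_equal(unname(attr2["C"]), 0)
  expect_equal(attr(attr2, "all_missing"), "C")
  expect_error(node_values(net, c(s1 = NA_real_, s2 = NA_real_, s3 = NA_real_,
                                  s4 = NA_real_, s5 = NA_real_)), "no observed value")
})

test_that("node hop distances match breadth-first search on random graphs", {
  # path A-B-C: d(A, C) = 2
  path_net <- toy_network(list(A = c("s1", "s2"), B = c("s2", "s3"),
                               C = c("s3", "s4")))
  d <- node_distances(path_net)
  expect_equal(d["A", "C"], 2)
  # disconnected components are infinitely far apart
  disc <- toy_network(list(A = "s1", B = "s2"))
  expect_equal(node_distances(disc)["A", "B"], Inf)
  withr::with_seed(5, {
    for (rep in 1:6) {
      n <- sample(5:30, 1)
      ids <- sprintf("n%02d", seq_len(n))
      pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
      keep <- runif(nrow(pairs)) < 0.12
      edges <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                          stringsAsFactors = FALSE)
      members <- as.list(paste0("s_", ids)); names(members) <- ids
      net <- toy_network(members, edges)
      expect_equal(node_distances(net), bfs_distances(edges, ids))
    }
  })
})

test_that("neighbourhoods use the nearest-rank percentile of finite distances", {
  # path A-B-C: pairwise distances {1, 1, 2}; 0.5th percentile -> 1st order stat
  net <- toy_network(list(A = c("s1", "s2"), B = c("s2", "s3"), C = c("s3", "s4")))
  nb <- neighborhoods(net, 0.5)
  expect_equal(nb$threshold, 1)
  expect_setequal(nb$sets$A, c("A", "B"))
  expect_setequal(nb$sets$B, c("A", "B", "C"))
  # complete graph: everything within one hop
  nodes <- list(A = "s1", B = "s2", C = "s3")
  cmpl <- toy_network(nodes, data.frame(from = c("A", "A", "B"),
                                        to = c("B", "C", "C")))
  nbc <- neighborhoods(cmpl, 50)
  expect_setequal(nbc$sets$A, c("A", "B", "C"))
  # disconnected pairs never enter the percentile; singletons stay themselves
  lone <- toy_network(list(A = "s1", B = "s2"))
  nbl <- neighborhoods(lone, 0.5)
  expect_equal(nbl$sets$A, "A")
})

test_that("SAFE scores: constant attributes score zero, concentrated ones score high", {
  net <- lattice_network(10, 10)
  const_attr <- stats::setNames(rep(2, 100), names(net$nodes))
  res <- safe_scores(net, const_attr, n_permutations = 99L, seed = 1L)
  expect_true(all(res$table$p == 1))
  expect_true(all(res$table$score == 0))
  expect_equal(res$safe_enriched_score, 0)
  # all attribute mass inside one tight neighbourhood
  nb <- neighborhoods(net, 0.5)
  expect_equal(nb$threshold, 1)
  center <- "v045"
  attr_v <- stats::setNames(rep(0, 100), names(net$nodes))
  attr_v[nb$sets[[center]]] <- 1
  res2 <- safe_scores(net, attr_v, nb, n_permutations = 999L, seed = 2L)
  expect_gte(res2$table$score[res2$table$node == center], 0.9)
})

test_that("SAFE p-values are bounded, map monotonically to scores, and are seeded", {
  net <- lattice_network(5, 6)
  withr::with_seed(8, attr_v <- stats::setNames(runif(30), names(net$nodes)))
  res <- safe_scores(net, attr_v, n_permutations = 199L, seed = 3L)
  expect_true(all(res$table$p >= 1 / 200) && all(res$table$p <= 1))
  expect_true(all(res$table$score >= 0 & res$table$score <= 1))
  ord <- order(res$table$p)
  expect_true(all(diff(res$table$score[ord]) <= 1e-12))
  res_b <- safe_scores(net, attr_v, n_permutations = 199L, seed = 3L)
  expect_identical(res$table, res_b$table)
})

test_that("permutation test is calibrated for node attributes drawn iid", {
  net <- lattice_network(6, 6)
  nb <- neighborhoods(net, 0.5)
  rates <- vapply(1:50, function(s) {
    attr_v <- withr::with_seed(3000 + s,
                               stats::setNames(rnorm(36), names(net$nodes)))
    res <- safe_scores(net, attr_v, nb, n_permutations = 999L, seed = s)
    mean(res$table$p < 0.05)
  }, numeric(1L))
  expect_gte(mean(rates), 0.03)
  expect_lte(mean(rates), 0.07)
})

test_that("relabelling nodes permutes SAFE scores conformably", {
  net <- lattice_network(4, 5)
  withr::with_seed(12, attr_v <- stats::setNames(runif(20), names(net$nodes)))
  res <- safe_scores(net, attr_v, n_permutations = 199L, seed = 6L)
  # rename every node (order and topology preserved): scores must follow
  ids <- names(net$nodes)
  relabel <- stats::setNames(paste0("X_", ids), ids)
  members2 <- net$nodes; names(members2) <- relabel[ids]
  edges2 <- data.frame(from = relabel[net$edges$from], to = relabel[net$edges$to],
                       stringsAsFactors = FALSE)
  net2 <- toy_network(members2, edges2)
  attr_v2 <- stats::setNames(as.numeric(attr_v), relabel[names(attr_v)])
  res2 <- safe_scores(net2, attr_v2, n_permutations = 199L, seed = 6L)
  expect_equal(res2$table$node, unname(relabel[res$table$node]))
  expect_equal(res2$table$score, res$table$score)
  expect_equal(res2$table$p, res$table$p)
})

test_that("a rare label spread uniformly over the network yields no enrichment", {
  net <- lattice_network(8, 8)
  # 6 positive nodes scattered maximally far apart
  attr_v <- stats::setNames(rep(0, 64), names(net$nodes))
  attr_v[c("v001", "v008", "v029", "v036", "v057", "v064")] <- 1
  res <- safe_scores(net, attr_v, n_permutations = 999L, seed = 4L)
  expect_equal(res$n_enriched, 0L)
  expect_equal(res$safe_enriched_score, 0)
})

test_that("enriched-node filtering is strict and the network score sums over it", {
  net <- lattice_network(3, 4)
  tab <- data.frame(node = names(net$nodes),
                    observed = 1,
                    p = c(0.0005, 0.05, 0.02, rep(1, 9)),
                    score = c(1, 0.4, 0.6, rep(0, 9)),
                    enriched = c(TRUE, FALSE, TRUE, rep(FALSE, 9)),
                    stringsAsFactors = FALSE)
  res <- structure(list(variable = "x", table = tab,
                        enriched = tab$node[tab$p < 0.05],
                        safe_enriched_score = sum(tab$score[tab$p < 0.05]),
                        n_enriched = 2L, n_permutations = 1999L,
                        threshold = 1, alpha = 0.05),
                   class = "safe_result")
  expect_setequal(enriched_nodes(res), tab$node[c(1, 3)])  # p = alpha excluded
  expect_equal(safe_enriched_score(res), 1.6)
  # the p floor 1/(P+1) with P = 5000 is comfortably inside alpha = 0.05
  expect_lt(1 / 5001, 0.05)
})

test_that("variables rank by enriched score with lexicographic ties", {
  mk <- function(v, s) structure(list(variable = v, safe_enriched_score = s,
                                      n_enriched = 1L),
                                 class = "safe_result")
  got <- rank_variables(list(mk("C", 84), mk("A", 400), mk("B", 190)))
  expect_equal(got$variable, c("A", "B", "C"))
  tie <- rank_variables(list(mk("zeta", 10), mk("alpha", 10)))
  expect_equal(tie$variable, c("alpha", "zeta"))
  single <- rank_variables(list(mk("only", 3)))
  expect_equal(single$variable, "only")
})
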