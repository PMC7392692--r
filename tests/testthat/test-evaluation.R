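named_graph <- function(edges, isolated = character()) {
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  if (length(isolated)) g <- g + igraph::vertices(isolated)
  g
}

path4 <- function() named_graph(c("a","b", "b","c", "c","d"))

test_that("common-node restriction keeps exactly the induced subgraphs", {
  gan <- named_graph(c("A","B", "B","C", "A","C"))
  ref <- named_graph(c("B","C", "C","D"))
  out <- suppressMessages(restrict_common(gan, ref))
  expect_setequal(igraph::V(out$gan)$name, c("B", "C"))
  expect_setequal(igraph::V(out$ref)$name, c("B", "C"))
  expect_equal(out$n_common_nodes, 2)
  # brute-force oracle: kept edges are those with both endpoints retained
  for (i in 1:10) {
    g1 <- random_named_graph(15, 0.25, seed = i)
    g2 <- random_named_graph(15, 0.25, seed = i + 50)
    igraph::V(g2)$name <- sprintf("N%03d", 6:20)
    res <- suppressMessages(restrict_common(g1, g2))
    common <- intersect(igraph::V(g1)$name, igraph::V(g2)$name)
    el <- igraph::as_edgelist(g1)
    keep <- el[el[, 1] %in% common & el[, 2] %in% common, , drop = FALSE]
    expect_setequal(canonical_keys_test(res$gan),
                    paste(pmin(keep[, 1], keep[, 2]), pmax(keep[, 1], keep[, 2])))
  }
  same <- suppressMessages(restrict_common(gan, gan))
  expect_equal(igraph::ecount(same$gan), igraph::ecount(gan))
  expect_error(restrict_common(gan, named_graph(c("X","Y"))), "no common nodes")
})

test_that("graph power adds exactly the k-hop pairs", {
  p <- path4()
  k2 <- graph_power(p, 2)
  expect_setequal(canonical_keys_test(k2),
                  c("a b", "b c", "c d", "a c", "b d"))
  k3 <- graph_power(p, 3)
  expect_setequal(canonical_keys_test(k3),
                  c("a b", "b c", "c d", "a c", "b d", "a d"))
  expect_equal(igraph::graph_attr(k3, "order_k"), 3L)
  # identity at k = 1, monotone in k, BFS oracle on random graphs
  for (i in 1:30) {
    g <- random_named_graph(sample(8:40, 1), 0.12, seed = i)
    expect_setequal(canonical_keys_test(graph_power(g, 1)),
                    canonical_keys_test(g))
    d <- bfs_distances(adj_of(g))
    for (k in 2:3) {
      gk <- graph_power(g, k)
      hit <- which(d >= 1 & d <= k & upper.tri(d), arr.ind = TRUE)
      ids <- rownames(d)
      expect_setequal(canonical_keys_test(gk),
                      paste(pmin(ids[hit[, 1]], ids[hit[, 2]]),
                            pmax(ids[hit[, 1]], ids[hit[, 2]])))
    }
    expect_true(all(canonical_keys_test(graph_power(g, 2)) %in%
                      canonical_keys_test(graph_power(g, 3))))
  }
})

test_that("common-edge statistics count shared unordered pairs", {
  gan <- named_graph(c("a","b", "c","d"))
  ref <- named_graph(c("a","b", "b","c"), isolated = "d")
  cs <- common_edge_stats(gan, ref)
  expect_equal(cs$n_common, 1)
  expect_equal(cs$pct_common, 50)
  expect_equal(common_edge_stats(gan, gan)$pct_common, 100)
  disj <- named_graph(c("a","c", "b","d"))
  expect_equal(common_edge_stats(disj, ref)$n_common, 0)
  empty <- igraph::make_empty_graph(0, directed = FALSE) +
    igraph::vertices(c("a", "b"))
  expect_message(cs0 <- common_edge_stats(empty, ref), "no edges")
  expect_true(is.na(cs0$pct_common))
})

test_that("label permutation preserves topology and is uniform", {
  g <- random_named_graph(20, 0.2, seed = 1)
  pg <- permute_node_labels(g, seed = 3)
  expect_setequal(igraph::V(pg)$name, igraph::V(g)$name)
  expect_equal(sort(unname(igraph::degree(pg))),
               sort(unname(igraph::degree(g))))
  expect_equal(igraph::ecount(pg), igraph::ecount(g))
  expect_identical(canonical_keys_test(permute_node_labels(g, seed = 3)),
                   canonical_keys_test(pg))
  # uniformity over the 24 labelings of a labeled path
  p <- path4()
  draws <- vapply(1:10000, function(i)
    paste(sort(canonical_keys_test(permute_node_labels(p, seed = i))),
          collapse = "|"), "")
  tab <- table(draws)
  # 4 nodes: 24 permutations but pairs of them give the same edge set
  # (path reversal), so 12 distinct labelings, each expected 1/12
  expect_length(tab, 12)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("edge permutation test matches exhaustive enumeration on a path", {
  p <- path4()
  res <- permutation_test_edges(p, p, k = 1, exact = TRUE)
  # independent enumeration over all 24 label permutations
  ids <- igraph::V(p)$name
  a <- adj_of(p)
  el <- igraph::as_edgelist(p)
  eu <- match(el[, 1], ids); ev <- match(el[, 2], ids)
  cnt <- vapply(perms_of(4), function(pm) sum(a[cbind(pm[eu], pm[ev])]),
                numeric(1))
  expect_equal(res$n_common, 3)
  expect_equal(res$n_perm, 24)
  expect_equal(res$p_perm_edges, mean(cnt >= 3))
  expect_equal(res$p_perm_edges, 2 / 24)   # only the 2 path automorphisms
})

test_that("edge permutation test is deterministic with sensible defaults", {
  expect_equal(eval(formals(permutation_test_edges)$n_perm), 1000L)
  expect_equal(eval(formals(permutation_test_msp)$n_perm), 1000L)
  gan <- random_named_graph(25, 0.15, seed = 2)
  ref <- random_named_graph(25, 0.2, seed = 3)
  r1 <- permutation_test_edges(gan, ref, k = 2, n_perm = 200, seed = 11)
  r2 <- permutation_test_edges(gan, ref, k = 2, n_perm = 200, seed = 11)
  expect_identical(r1, r2)
  add1 <- permutation_test_edges(gan, ref, n_perm = 200, seed = 11,
                                 estimator = "add_one")
  expect_gt(add1$p_perm_edges, 0)
})

test_that("mean shortest path averages reference distances of proposed edges", {
  ref <- path4()
  gan <- named_graph(c("a","c"), isolated = c("b", "d"))
  ms <- mean_shortest_path(gan, ref)
  expect_equal(ms$msp, 2)
  expect_equal(ms$n_unreachable, 0)
  sub <- named_graph(c("a","b", "b","c"), isolated = "d")
  expect_equal(mean_shortest_path(sub, ref)$msp, 1)
  # unreachable pairs are excluded and counted
  ref2 <- named_graph(c("a","b", "c","d"))
  gan2 <- named_graph(c("a","b", "a","c"), isolated = "d")
  ms2 <- mean_shortest_path(gan2, ref2)
  expect_equal(ms2$msp, 1)
  expect_equal(ms2$n_unreachable, 1)
  # BFS oracle on random graphs
  for (i in 1:20) {
    gan <- random_named_graph(20, 0.15, seed = i)
    ref <- random_named_graph(20, 0.2, seed = i + 100)
    d <- bfs_distances(adj_of(ref))
    el <- igraph::as_edgelist(gan)
    dv <- d[el]
    ms <- mean_shortest_path(gan, ref)
    expect_equal(ms$msp, mean(dv[is.finite(dv)]))
    expect_equal(ms$n_unreachable, sum(!is.finite(dv)))
  }
})

test_that("mean-shortest-path permutation p matches the exact automorphism rate", {
  p <- path4()
  res <- permutation_test_msp(p, p, n_perm = 2400, seed = 5)
  expect_equal(res$msp, 1)
  # msp <= 1 requires mapping the path onto itself: 2 of 24 labelings
  expect_lt(abs(res$p_perm_msp - 2 / 24), 0.02)
  r2 <- permutation_test_msp(p, p, n_perm = 2400, seed = 5)
  expect_identical(res, r2)
})

test_that("permutation tests are calibrated under label-randomized networks", {
  ref <- random_named_graph(40, 0.15, seed = 99)
  ps <- vapply(1:120, function(i) {
    gan <- permute_node_labels(ref, seed = 5000 + i)
    permutation_test_edges(gan, ref, n_perm = 400, seed = i)$p_perm_edges
  }, numeric(1))
  expect_gt(mean(ps < 0.1), 0.04)
  expect_lt(mean(ps < 0.1), 0.18)
})

test_that("evaluation grid enumerates every cell with bookkeeping", {
  st <- tiny_study()
  sc <- st$truth$model$scaffold
  nets <- list(
    good = list("0.3" = degrade_network(sc, 0.3, 0.01, seed = 1),
                "0.5" = degrade_network(sc, 0.5, 0.005, seed = 2),
                "0.7" = degrade_network(sc, 0.7, 0.002, seed = 3)),
    rand = list("0.3" = random_named_graph(30, 0.1, seed = 4),
                "0.5" = random_named_graph(30, 0.08, seed = 5),
                "0.7" = random_named_graph(30, 0.05, seed = 6)))
  set.seed(7)
  igraph::V(nets$rand[["0.3"]])$name <- sample(igraph::V(sc)$name, 30)
  igraph::V(nets$rand[["0.5"]])$name <- sample(igraph::V(sc)$name, 30)
  igraph::V(nets$rand[["0.7"]])$name <- sample(igraph::V(sc)$name, 30)
  grid <- suppressMessages(
    evaluate_grid(nets, list(truth = sc), orders = 1:3, n_perm = 50, seed = 1))
  expect_equal(nrow(grid), 2 * 3 * 1 * 3)
  expect_true(all(grid$n_perm == 50))
  expect_named(attr(grid, "summary"))
  # the degraded copies of the truth out-reject the random networks
  summ <- attr(grid, "summary")
  expect_gt(summ[["good"]], summ[["rand"]])
})
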