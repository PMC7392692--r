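test_that("preferential-attachment scaffold has the expected size and is deterministic", {
  g <- generate_scaffold(5, 1, seed = 1)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)        # m = 1 yields a tree
  expect_true(igraph::is_connected(g))

  g2 <- generate_scaffold(200, 2, seed = 7)
  expect_equal(igraph::ecount(g2), 2 * (200 - 2) + 1)  # attachment closed form
  expect_true(igraph::is_connected(g2))
  expect_true(igraph::is_simple(g2))

  g3 <- generate_scaffold(200, 2, seed = 7)
  expect_identical(igraph::as_edgelist(g2), igraph::as_edgelist(g3))

  expect_error(generate_scaffold(3, 3, seed = 1), "n_genes > attach_m")
})

test_that("precision model is PD with zeros exactly off the scaffold", {
  # edgeless scaffold -> identity
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- letters[1:4]
  m0 <- build_precision(g0, seed = 1)
  expect_equal(unname(m0$precision), diag(4))
  expect_equal(unname(m0$pcor - diag(4)), matrix(0, 4, 4))

  # path a-b-c: zero only at the non-edge (a, c)
  gp <- igraph::graph_from_edgelist(cbind(c("a", "b"), c("b", "c")),
                                    directed = FALSE)
  mp <- build_precision(gp, seed = 2)
  expect_equal(mp$precision["a", "c"], 0)
  expect_equal(mp$pcor["a", "c"], 0)       # conditional independence given b
  expect_true(all(abs(mp$pcor[cbind(c("a", "b"), c("b", "c"))]) > 0))

  m <- build_precision(generate_scaffold(50, 2, seed = 3), seed = 3)
  ev <- eigen(m$precision, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)

  expect_error(build_precision(igraph::make_graph(c("a","b","a","a")),
                               seed = 1), "simple")
})

test_that("positive definiteness and non-edge conditional independence hold over seeds", {
  for (s in 1:5) {
    sc <- generate_scaffold(40, 2, seed = s)
    m <- build_precision(sc, seed = s + 100)
    expect_gt(min(eigen(m$precision, symmetric = TRUE,
                        only.values = TRUE)$values), 0)
    # partial correlations recomputed from the inverse covariance vanish on
    # non-edges
    sigma <- solve(m$precision)
    w <- solve(sigma)
    pc <- -w / sqrt(outer(diag(w), diag(w)))
    adj <- adj_of(sc)
    expect_lt(max(abs(pc[!adj & upper.tri(adj)])), 1e-10)
  }
})

test_that("knockdown ramp is monotone and reaches full depth at the last harvest", {
  r <- kd_ramp(c(20, 28, 44, 48, 52, 68, 72, 76))
  expect_equal(unname(r[length(r)]), 1)
  expect_true(all(diff(r) > 0))
  expect_equal(unname(kd_ramp(48)), 1)
})

test_that("expression sampling is deterministic and matches the model covariance", {
  des <- study_design()
  sc <- generate_scaffold(10, 2, seed = 4)
  m <- build_precision(sc, seed = 4)
  e1 <- sample_expression(m, des, seed = 9)
  e2 <- sample_expression(m, des, seed = 9)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  expect_identical(colnames(e1), des$sample_id)

  # independence: identity precision -> correlations within +/- 4 / sqrt(n)
  g0 <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(g0)$name <- letters[1:5]
  m0 <- build_precision(g0, seed = 1)
  big <- data.frame(sample_id = paste0("s", 1:2000), condition = "untreated",
                    timepoint_h = 0, clone_id = "", replicate_kind = "biological",
                    bio_rep = 1:2000)
  e0 <- sample_expression(m0, big, seed = 2)
  r0 <- cor(t(e0))
  expect_lt(max(abs(r0[upper.tri(r0)])), 4 / sqrt(2000))

  # Monte-Carlo consistency: sample covariance ~ inverse precision
  gp <- igraph::graph_from_edgelist(
    cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")), directed = FALSE)
  mm <- build_precision(gp, pcor_lo = 0.3, pcor_hi = 0.5, seed = 5)
  huge <- data.frame(sample_id = paste0("s", 1:10000), condition = "untreated",
                     timepoint_h = 0, clone_id = "", replicate_kind = "biological",
                     bio_rep = 1:10000)
  eh <- sample_expression(mm, huge, seed = 6)
  expect_lt(max(abs(cov(t(eh)) - solve(mm$precision))), 0.05)
})

test_that("perturbation shifts are exactly as constructed when deterministic", {
  sc <- generate_scaffold(30, 2, seed = 7)
  m <- build_precision(sc, seed = 7)
  des <- study_design()
  expr <- sample_expression(m, des, seed = 8)
  target <- names(which.max(igraph::degree(sc)))
  nbrs <- igraph::neighbors(sc, target)$name
  art <- setdiff(m$gene_ids, c(target, nbrs))[1:3]
  st <- apply_perturbation(expr, des, m, target, artifact_genes = art,
                           response_sd = 0, seed = 1)
  shift <- st$expression - expr
  ramp <- kd_ramp(des$timepoint_h[des$condition == "sirna_kd"])

  kd76 <- des$condition == "sirna_kd" & des$timepoint_h == 76
  expect_equal(unname(shift[target, kd76]),
               rep(-5.32, sum(kd76)))          # ~2.5% mRNA at full depth
  kd20 <- des$condition == "sirna_kd" & des$timepoint_h == 20
  expect_equal(unname(shift[target, kd20]),
               rep(-5.32 * ramp[["20"]], sum(kd20)))
  ox <- des$condition == "ox_clone" & des$clone_id == "OX2"
  expect_equal(unname(shift[target, ox]), rep(5.83 * 1.0, sum(ox)))

  # artifact genes shift in all transfected samples, nowhere else
  transf <- des$condition %in% c("sirna_kd", "nonsense")
  expect_equal(unname(shift[art, transf]),
               matrix(2, length(art), sum(transf)))
  expect_true(all(shift[art, !transf] == 0))

  # untreated and negative clone columns untouched
  clean <- des$condition %in% c("untreated", "negative_clone")
  expect_true(all(shift[, clean][setdiff(rownames(shift), art), ] == 0))

  # neighbor shift carries the propagation fraction and the edge sign
  nb <- nbrs[1]
  expect_equal(unname(shift[nb, kd76]),
               rep(0.35 * sign(m$pcor[target, nb]) * -5.32, sum(kd76)))

  # no propagation -> only the target responds to the perturbation conditions
  st0 <- apply_perturbation(expr, des, m, target, propagation = 0,
                            artifact_genes = character(), response_sd = 0)
  diff0 <- st0$expression - expr
  expect_true(all(diff0[setdiff(rownames(expr), target), ] == 0))
  expect_error(apply_perturbation(expr, des, m, "NOPE"), "unknown target")
})

test_that("response heterogeneity preserves the expected shift", {
  sc <- generate_scaffold(20, 1, seed = 3)
  m <- build_precision(sc, seed = 3)
  des <- study_design()
  expr <- sample_expression(m, des, seed = 4)
  target <- names(which.max(igraph::degree(sc)))
  nb <- igraph::neighbors(sc, target)$name[1]
  shifts <- sapply(1:40, function(s) {
    st <- apply_perturbation(expr, des, m, target, response_sd = 0.25, seed = s)
    kd76 <- des$condition == "sirna_kd" & des$timepoint_h == 76
    mean(st$expression[nb, kd76] - expr[nb, kd76])
  })
  expected <- 0.35 * sign(m$pcor[target, nb]) * -5.32
  expect_lt(abs(mean(shifts) - expected), 0.25)
})

test_that("network degradation follows the false-negative/positive rates", {
  sc <- generate_scaffold(51, 2, seed = 5)      # 99 true edges
  same <- degrade_network(sc, 0, 0, seed = 1)
  expect_setequal(canonical_keys_test(same), canonical_keys_test(sc))
  gone <- degrade_network(sc, 1, 0, seed = 1)
  expect_equal(igraph::ecount(gone), 0)
  expect_equal(igraph::graph_attr(gone, "order_k"), 1L)

  kept <- sapply(1:200, function(s)
    igraph::ecount(degrade_network(sc, fn_rate = 0.2, fp_rate = 0, seed = s)))
  expect_lt(abs(mean(kept) - 0.8 * 99), 1.5)   # binomial expectation
})

test_that("fixtures round-trip through the module readers", {
  st <- tiny_study()
  d <- withr::local_tempdir()
  paths <- write_fixture(st, file.path(d, "fix"))
  expect_true(all(file.exists(paths)))
  back <- read_fixture(file.path(d, "fix"))
  expect_equal(back$expression, st$expression, tolerance = 1e-6)
  expect_equal(nrow(back$truth_edges),
               igraph::ecount(st$truth$model$scaffold))
  expect_setequal(back$artifact_genes, st$truth$artifact_genes)
  expect_equal(back$design$sample_id, st$design$sample_id)
  expect_error(write_fixture(st, file.path(d, "missing"), create = FALSE),
               "does not exist")
})

test_that("studies are identical under identical seeds", {
  a <- tiny_study(seed = 7)
  b <- tiny_study(seed = 7)
  expect_identical(a$expression, b$expression)
  expect_identical(igraph::as_edgelist(a$truth$model$scaffold),
                   igraph::as_edgelist(b$truth$model$scaffold))
  expect_identical(a$truth$artifact_genes, b$truth$artifact_genes)
})
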