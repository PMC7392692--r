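# Brute-force oracles, kept deliberately independent of the package
# implementations (plain loops over adjacency matrices, no igraph calls on
# the checked quantity).

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical "min max" edge keys of an igraph
canonical_keys_test <- function(g) {
  el <- igraph::as_edgelist(g)
  if (!nrow(el)) return(character())
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

# adjacency matrix of an igraph, symmetric logical
adj_of <- function(g) {
  ids <- igraph::V(g)$name
  a <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  el <- igraph::as_edgelist(g)
  if (nrow(el)) {
    a[el] <- TRUE
    a[el[, 2:1, drop = FALSE]] <- TRUE
  }
  a
}

# all-pairs shortest-path distances by repeated BFS over an adjacency matrix
bfs_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  diag(d) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    dist <- 0
    while (length(frontier)) {
      dist <- dist + 1
      nxt <- integer()
      for (v in frontier) {
        for (w in which(a[v, ])) {
          if (d[s, w] > dist) {
            d[s, w] <- dist
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# shortest-path counts between all pairs (for the betweenness oracle)
path_counts <- function(a, d) {
  n <- nrow(a)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (t in which(d[s, ] == dist)) {
        pred <- which(a[, t] & d[s, ] == dist - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  sigma
}

brute_betweenness <- function(g) {
  a <- adj_of(g)
  d <- bfs_distances(a)
  sigma <- path_counts(a, d)
  n <- nrow(a)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (sigma[s, t] > 0 && d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  setNames(btw, rownames(a))
}

brute_closeness <- function(g) {
  d <- bfs_distances(adj_of(g))
  apply(d, 1, function(row) {
    row <- row[is.finite(row) & row > 0]
    if (length(row)) 1 / mean(row) else 0
  })
}

# naive partial correlations via plain matrix inversion of the sample
# correlation matrix (no shrinkage)
naive_pcor <- function(expr) {
  w <- solve(cor(t(expr)))
  pc <- -w / sqrt(outer(diag(w), diag(w)))
  diag(pc) <- 1
  pc
}

# exhaustive hypergeometric tail P(X >= k) by enumerating all C(N, n) draws
hyper_tail_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- seq_len(K)
  overlaps <- apply(draws, 2, function(dr) sum(dr %in% in_set))
  mean(overlaps >= k)
}

# recursive enumeration of all permutations of 1..n (independent of the
# package's internal enumeration: builds by inserting n at every position)
perms_of <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (pp in perms_of(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(pp, n, after = pos)
    }
  }
  out
}

# Erdos-Renyi random graph with named vertices, at least one edge
random_named_graph <- function(n, p_edge, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p_edge)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
  if (igraph::ecount(g) == 0L) g <- igraph::add_edges(g, c(1, 2))
  g
}

# small, fast synthetic study shared across tests
tiny_study <- function(seed = 42L, ...) {
  gannet::simulate_study(seed = seed, n_genes = 60L, n_artifact = 6L, ...)
}
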