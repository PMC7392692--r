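# Scoring reconstructed networks against reference interactomes: common-node
# restriction, k-order reference expansion, and topology-preserving node-label
# permutation tests for common edges and mean shortest path.

#' Restrict a reconstructed network and a reference to their common nodes
#'
#' @param gan Reconstructed igraph.
#' @param ref Reference igraph.
#' @return List with induced subgraphs `gan` and `ref` and `n_common_nodes`.
#' @export
restrict_common <- function(gan, ref) {
  common <- intersect(igraph::V(gan)$name, igraph::V(ref)$name)
  if (!length(common)) stop("no common nodes between network and reference")
  message(length(common), " common node(s)")
  list(gan = igraph::induced_subgraph(gan, common),
       ref = igraph::induced_subgraph(ref, common),
       n_common_nodes = length(common))
}

#' k-order expansion of a reference network (graph power)
#'
#' An edge (u, v) is present in the result iff the unweighted shortest-path
#' distance between u and v in the input is between 1 and k, so indirect
#' protein chains of length up to k can match direct associations.
#'
#' @param ref Reference igraph.
#' @param k Expansion order, 1, 2 or 3; `k = 1` is the identity.
#' @return igraph with graph attribute `order_k = k`.
#' @export
graph_power <- function(ref, k) {
  stopifnot(k %in% 1:3)
  if (k == 1L) return(as_reference(ref, source = ref_source(ref), order_k = 1L))
  d <- igraph::distances(ref)
  ids <- igraph::V(ref)$name
  hit <- which(d >= 1 & d <= k & upper.tri(d), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(ids[hit[, 1L]], ids[hit[, 2L]]),
                                   directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  as_reference(g, source = ref_source(ref), order_k = k)
}

ref_source <- function(ref) {
  s <- igraph::graph_attr(ref, "source")
  if (is.null(s)) "reference" else s
}

canonical_edge_keys <- function(net) {
  el <- igraph::as_edgelist(net)
  if (!nrow(el)) return(character())
  paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
}

#' Common edges between a reconstructed network and a reference
#'
#' @param gan Reconstructed igraph (already restricted to common nodes).
#' @param ref_k Reference igraph (possibly k-order expanded).
#' @return List with `n_common` and `pct_common` (percent of the
#'   reconstructed network's edges found in the reference; `NA` when the
#'   reconstructed network has no edges).
#' @export
common_edge_stats <- function(gan, ref_k) {
  n_gan <- igraph::ecount(gan)
  if (n_gan == 0L) {
    message("reconstructed network has no edges; percent undefined")
    return(list(n_common = 0L, pct_common = NA_real_))
  }
  n_common <- sum(canonical_edge_keys(gan) %in% canonical_edge_keys(ref_k))
  list(n_common = n_common, pct_common = 100 * n_common / n_gan)
}

#' Topology-preserving node-label permutation
#'
#' Applies a uniformly random bijection of the node names onto themselves;
#' degree sequence and all topological invariants are preserved.
#'
#' @param net igraph with named vertices.
#' @param seed Integer seed.
#' @return igraph with permuted names.
#' @export
permute_node_labels <- function(net, seed = 1L) {
  ids <- igraph::V(net)$name
  withr_seed(seed, igraph::set_vertex_attr(net, "name", value = sample(ids)))
}

# shared machinery: gan edges as integer index pairs into the common node set,
# plus a lookup matrix on the reference side
perm_setup <- function(gan, ref, lookup) {
  common <- intersect(igraph::V(gan)$name, igraph::V(ref)$name)
  if (!length(common)) stop("no common nodes between network and reference")
  gan_c <- igraph::induced_subgraph(gan, common)
  el <- igraph::as_edgelist(gan_c)
  list(common = common,
       eu = match(el[, 1L], common), ev = match(el[, 2L], common),
       lookup = lookup(igraph::induced_subgraph(ref, common), common))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation test for common edges
#'
#' Compares the observed number of edges shared with the (k-order expanded)
#' reference against the null distribution obtained by permuting the
#' reconstructed network's node labels while preserving its topology. The
#' p-value is the plain fraction of permutations with at least as many common
#' edges (ties count against the observed network); `estimator = "add_one"`
#' uses `(n_exceed + 1) / (n_perm + 1)`.
#'
#' @param gan Reconstructed igraph.
#' @param ref Reference igraph.
#' @param k Reference expansion order (1, 2 or 3).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param exact Enumerate all label permutations instead (common node set of
#'   at most 8 nodes).
#' @param estimator `"plain"` (default) or `"add_one"`.
#' @return List with `n_common`, `pct_common`, `p_perm_edges`, `n_perm`.
#' @export
permutation_test_edges <- function(gan, ref, k = 1L, n_perm = 1000L,
                                   seed = 1L, exact = FALSE,
                                   estimator = c("plain", "add_one")) {
  estimator <- match.arg(estimator)
  st <- perm_setup(gan, ref, function(ref_c, common) {
    refk <- graph_power(ref_c, k)
    a <- matrix(FALSE, length(common), length(common),
                dimnames = list(common, common))
    el <- igraph::as_edgelist(refk)
    if (nrow(el)) {
      iu <- match(el[, 1L], common); iv <- match(el[, 2L], common)
      a[cbind(iu, iv)] <- TRUE
      a[cbind(iv, iu)] <- TRUE
    }
    a
  })
  n_edges <- length(st$eu)
  obs <- if (n_edges) sum(st$lookup[cbind(st$eu, st$ev)]) else 0L
  n <- length(st$common)
  if (exact) {
    if (n > 8L) stop("exact enumeration limited to 8 common nodes")
    perms <- all_permutations(n)
    cnt <- apply(perms, 1L, function(pm) {
      if (n_edges) sum(st$lookup[cbind(pm[st$eu], pm[st$ev])]) else 0L
    })
    n_perm <- nrow(perms)
    p <- mean(cnt >= obs)
  } else {
    cnt <- withr_seed(seed, vapply(seq_len(n_perm), function(i) {
      pm <- sample.int(n)
      if (n_edges) sum(st$lookup[cbind(pm[st$eu], pm[st$ev])]) else 0L
    }, numeric(1L)))
    p <- if (estimator == "plain") mean(cnt >= obs) else
      (sum(cnt >= obs) + 1) / (n_perm + 1)
  }
  list(n_common = as.integer(obs),
       pct_common = if (n_edges) 100 * obs / n_edges else NA_real_,
       p_perm_edges = p, n_perm = as.integer(n_perm))
}

#' Mean shortest path of reconstructed edges within a reference
#'
#' For every edge (u, v) of the reconstructed network, the unweighted
#' shortest-path distance between u and v in the reference; the mean is taken
#' over pairs with finite distance, unreachable pairs are counted separately.
#'
#' @param gan Reconstructed igraph.
#' @param ref Reference igraph.
#' @return List with `msp` (NA when no finite distance exists) and
#'   `n_unreachable`.
#' @export
mean_shortest_path <- function(gan, ref) {
  st <- perm_setup(gan, ref, function(ref_c, common) {
    igraph::distances(ref_c)[common, common]
  })
  if (!length(st$eu)) return(list(msp = NA_real_, n_unreachable = 0L))
  d <- st$lookup[cbind(st$eu, st$ev)]
  finite <- is.finite(d)
  if (!any(finite)) {
    warning("no finite reference distance for any reconstructed edge")
    return(list(msp = NA_real_, n_unreachable = sum(!finite)))
  }
  list(msp = mean(d[finite]), n_unreachable = sum(!finite))
}

#' Permutation test for the mean-shortest-path statistic
#'
#' The reconstructed network's node labels are permuted (topology preserved)
#' and the mean shortest path recomputed; `p` is the fraction of permutations
#' with a mean shortest path at most as large as observed (ties inclusive).
#'
#' @param gan Reconstructed igraph.
#' @param ref Reference igraph.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List with `msp`, `n_unreachable`, `p_perm_msp`, `n_perm`.
#' @export
permutation_test_msp <- function(gan, ref, n_perm = 1000L, seed = 1L) {
  st <- perm_setup(gan, ref, function(ref_c, common) {
    igraph::distances(ref_c)[common, common]
  })
  n <- length(st$common)
  if (!length(st$eu)) {
    return(list(msp = NA_real_, n_unreachable = 0L, p_perm_msp = NA_real_,
                n_perm = as.integer(n_perm)))
  }
  msp_of <- function(pm) {
    d <- st$lookup[cbind(pm[st$eu], pm[st$ev])]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else NA_real_
  }
  obs <- msp_of(seq_len(n))
  if (is.na(obs)) {
    warning("no finite reference distance for any reconstructed edge")
    return(list(msp = NA_real_, n_unreachable = length(st$eu),
                p_perm_msp = NA_real_, n_perm = as.integer(n_perm)))
  }
  perm <- withr_seed(seed, vapply(seq_len(n_perm),
                                  function(i) msp_of(sample.int(n)),
                                  numeric(1L)))
  d_obs <- st$lookup[cbind(st$eu, st$ev)]
  list(msp = obs, n_unreachable = sum(!is.finite(d_obs)),
       p_perm_msp = mean(perm <= obs, na.rm = TRUE),
       n_perm = as.integer(n_perm))
}

#' Evaluate a grid of reconstructed networks against references
#'
#' One row per (gene set, cutoff, reference, expansion order): common-edge
#' count/percent with permutation p, and the mean-shortest-path statistic
#' with its permutation p (computed against the unexpanded reference and
#' repeated across order rows). Cells whose network is empty or shares no
#' node with the reference are reported with NA statistics.
#'
#' @param gene_set_networks Nested named list: gene set -> cutoff -> igraph
#'   (as produced by [scan_cutoffs()] per gene set).
#' @param refs Named list of reference igraphs.
#' @param orders Expansion orders to evaluate (subset of 1:3).
#' @param n_perm Permutations per test (default 1000).
#' @param seed Integer seed; per-cell substreams are derived from it.
#' @return data.frame with columns `gene_set, cutoff, reference, order_k,
#'   n_common, pct_common, p_edges, msp, n_unreachable, p_msp, n_perm`, with
#'   a per-gene-set summary (count of cells with `p_edges < 0.1`) in
#'   attribute `"summary"`.
#' @export
evaluate_grid <- function(gene_set_networks, refs, orders = 1:3,
                          n_perm = 1000L, seed = 1L) {
  stopifnot(length(gene_set_networks) > 0L, length(refs) > 0L,
            all(orders %in% 1:3))
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  rows <- list()
  cell <- 0L
  for (gs in names(gene_set_networks)) {
    for (co in names(gene_set_networks[[gs]])) {
      gan <- gene_set_networks[[gs]][[co]]
      for (rf in names(refs)) {
        cell <- cell + 1L
        cell_seed <- (seed + 7919L * cell) %% .Machine$integer.max
        usable <- igraph::ecount(gan) > 0L &&
          length(intersect(igraph::V(gan)$name, igraph::V(refs[[rf]])$name)) > 0L
        ms <- if (usable) {
          permutation_test_msp(gan, refs[[rf]], n_perm = n_perm,
                               seed = cell_seed)
        } else list(msp = NA_real_, n_unreachable = NA_integer_,
                    p_perm_msp = NA_real_)
        for (k in orders) {
          ed <- if (usable) {
            permutation_test_edges(gan, refs[[rf]], k = k, n_perm = n_perm,
                                   seed = cell_seed + k)
          } else list(n_common = NA_integer_, pct_common = NA_real_,
                      p_perm_edges = NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_set = gs, cutoff = as.numeric(co), reference = rf,
            order_k = k, n_common = ed$n_common, pct_common = ed$pct_common,
            p_edges = ed$p_perm_edges, msp = ms$msp,
            n_unreachable = ms$n_unreachable, p_msp = ms$p_perm_msp,
            n_perm = as.integer(n_perm), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  summ <- vapply(split(out$p_edges, out$gene_set),
                 function(p) sum(!is.na(p) & p < 0.1), integer(1L))
  attr(out, "summary") <- sort(summ, decreasing = TRUE)
  out
}
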