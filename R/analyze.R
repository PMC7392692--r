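# Downstream analysis of the selected network: centralities with rank
# consensus, k-neighborhoods, Fisher over-representation, degree-distribution
# diagnostic, and co-expression validation of proposed direct neighbors.

#' Node centralities
#'
#' Degree, shortest-path betweenness and closeness. Closeness is computed
#' within connected components as the reciprocal of the mean distance to the
#' reachable nodes; isolated nodes get closeness 0.
#'
#' @param net igraph with >= 2 nodes.
#' @return data.frame with columns `node, degree, betweenness, closeness`.
#' @export
centralities <- function(net) {
  if (igraph::vcount(net) < 2L) stop("need >= 2 nodes")
  ids <- igraph::V(net)$name
  d <- igraph::distances(net)
  clo <- apply(d, 1L, function(row) {
    row <- row[is.finite(row) & row > 0]
    if (length(row)) 1 / mean(row) else 0
  })
  data.frame(node = ids,
             degree = as.numeric(igraph::degree(net)),
             betweenness = as.numeric(igraph::betweenness(net,
                                                          directed = FALSE)),
             closeness = as.numeric(clo),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-consensus centrality
#'
#' Each measure is ranked with 1 = most central (ties averaged); the
#' consensus is the mean of the three ranks and the result is sorted by it,
#' most important node first.
#'
#' @param records data.frame from [centralities()].
#' @return The input with `rank_degree, rank_betweenness, rank_closeness,
#'   consensus` appended, sorted ascending by consensus.
#' @export
consensus_centrality <- function(records) {
  if (!nrow(records)) stop("empty centrality table")
  rk <- function(x) rank(-x, ties.method = "average")
  records$rank_degree <- rk(records$degree)
  records$rank_betweenness <- rk(records$betweenness)
  records$rank_closeness <- rk(records$closeness)
  records$consensus <- (records$rank_degree + records$rank_betweenness +
                          records$rank_closeness) / 3
  records[order(records$consensus, records$node), , drop = FALSE]
}

#' k-neighborhood of a gene
#'
#' Nodes at shortest-path distance at most k from the gene, excluding the
#' gene itself.
#'
#' @param net igraph.
#' @param gene Focal gene symbol (must be a node).
#' @param k Neighborhood order (1 or 2).
#' @return Character vector of gene symbols.
#' @export
k_neighborhood <- function(net, gene, k = 1L) {
  stopifnot(k %in% 1:2)
  if (!gene %in% igraph::V(net)$name) stop("gene not in network: ", gene)
  setdiff(igraph::ego(net, order = k, nodes = gene)[[1L]]$name, gene)
}

#' Fisher over-representation of catalog gene sets in a query set
#'
#' One-sided hypergeometric tail per catalog set (catalog sets are first
#' intersected with the universe), Benjamini-Hochberg across the catalog,
#' significance at adjusted p below `alpha`.
#'
#' @param query Character vector, a subset of `universe`.
#' @param catalog Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector of all eligible genes (explicit, never
#'   defaulted).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @return data.frame with one row per catalog set: `set_name, k_overlap,
#'   k_query, k_set, k_universe, odds_ratio, p, q, significant`.
#' @export
fisher_enrichment <- function(query, catalog, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes outside the universe")
  if (is.null(names(catalog))) stop("catalog sets must be named")
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(catalog), function(nm) {
    gs <- intersect(unique(catalog[[nm]]), universe)
    k <- length(intersect(query, gs))
    a <- k
    b <- n_q - k
    cc <- length(gs) - k
    dd <- n_u - n_q - cc
    data.frame(set_name = nm, k_overlap = a, k_query = n_q,
               k_set = length(gs), k_universe = n_u,
               odds_ratio = if (b * cc > 0) (a * dd) / (b * cc) else Inf,
               p = phyper(k - 1, length(gs), n_u - length(gs), n_q,
                          lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}

#' Degree-distribution diagnostic
#'
#' Histogram of node degrees and the least-squares slope of log(count)
#' against log(degree) over the occupied positive-degree bins; a heavy
#' (power-law-like) tail shows as a clearly negative slope. Purely
#' diagnostic, no pass/fail.
#'
#' @param net igraph with >= 10 nodes.
#' @return List with `histogram` (data.frame `degree, count`) and `slope`
#'   (NA when fewer than two occupied bins exist).
#' @export
degree_distribution_diagnostic <- function(net) {
  if (igraph::vcount(net) < 10L) stop("need >= 10 nodes")
  deg <- igraph::degree(net)
  tab <- table(deg)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab), row.names = NULL)
  pos <- hist[hist$degree > 0 & hist$count > 0, , drop = FALSE]
  slope <- if (nrow(pos) < 2L) NA_real_ else {
    unname(coef(lm(log(count) ~ log(degree), data = pos))[2L])
  }
  list(histogram = hist, slope = slope)
}

#' Co-expression validation of proposed direct neighbors
#'
#' Pearson correlation of each neighbor with the target across samples,
#' two-sided p from the exact t transform `t = r sqrt(n-2) / sqrt(1-r^2)`,
#' Benjamini-Hochberg across neighbors, significance at `q < max_fdr`.
#' Zero-variance genes are reported with missing statistics.
#'
#' @param expr Numeric matrix (genes x samples), >= 4 samples.
#' @param target Target gene symbol.
#' @param neighbors Character vector of neighbor genes.
#' @param max_fdr FDR threshold (default 0.1).
#' @return data.frame `gene, r_pearson, p, q, significant`.
#' @export
neighbor_correlation_validation <- function(expr, target, neighbors,
                                            max_fdr = 0.1) {
  validate_expression(expr)
  if (ncol(expr) < 4L) stop("need >= 4 samples")
  missing <- setdiff(c(target, neighbors), rownames(expr))
  if (length(missing)) stop("genes not in expression: ",
                            paste(missing, collapse = ", "))
  x <- expr[target, ]
  n <- length(x)
  res <- lapply(neighbors, function(g) {
    y <- expr[g, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(data.frame(gene = g, r_pearson = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- cor(x, y)
    tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    data.frame(gene = g, r_pearson = r, p = 2 * pt(-abs(tt), df = n - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- bh_adjust(out$p)
  out$significant <- !is.na(out$q) & out$q < max_fdr
  out
}
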