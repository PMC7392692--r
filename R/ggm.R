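# Gaussian graphical model inference: shrinkage correlation estimation,
# partial correlations, an empirical null for edge p-values, and
# local-fdr-based edge probabilities thresholded over a cutoff grid.
#
# The null density of a partial correlation r under no association is
#   f0(r; kappa) = (1 - r^2)^((kappa - 3) / 2) / Beta(1/2, (kappa - 1) / 2),
# i.e. r^2 ~ Beta(1/2, (kappa - 1) / 2), with Var(r) = 1 / kappa. The edge
# probability is one minus the local false discovery rate under the
# two-component mixture f(r) = eta0 f0(r; kappa) + (1 - eta0) fA(r).

#' Shrinkage estimate of the correlation matrix
#'
#' Computes `R* = (1 - lambda) R + lambda I` with the analytic shrinkage
#' intensity `lambda = sum Var(r_ij) / sum r_ij^2` (off-diagonal sums,
#' clipped to \[0, 1\]), where `Var(r_ij)` is the unbiased estimate of the
#' sampling variance of each correlation coefficient. For `lambda > 0` the
#' result is positive definite even when samples are fewer than genes.
#'
#' @param expr Numeric matrix (genes x samples), >= 3 samples, >= 2 genes,
#'   no zero-variance gene.
#' @return List with `R_star` (shrunken correlation matrix) and `lambda`.
#' @export
shrink_correlation <- function(expr) {
  validate_expression(expr)
  n <- ncol(expr)
  p <- nrow(expr)
  if (n < 3L) stop("need >= 3 samples")
  if (p < 2L) stop("need >= 2 genes")
  sds <- apply(expr, 1L, sd)
  if (any(sds == 0)) {
    stop("zero-variance gene(s): ",
         paste(head(rownames(expr)[sds == 0], 10L), collapse = ", "))
  }
  xs <- scale(t(expr))                      # n x p, unit sd (n-1 denominator)
  r <- crossprod(xs) / (n - 1)
  # Var-hat of r_ij from the centered products w_k = x_ki x_kj:
  #   Var(r_ij) = n / (n-1)^3 * sum_k (w_k - w_bar)^2
  m1 <- crossprod(xs)                       # sum_k w_k
  m2 <- crossprod(xs^2)                     # sum_k w_k^2
  var_r <- n / (n - 1)^3 * (m2 - m1^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  r_star <- (1 - lambda) * r
  diag(r_star) <- 1
  dimnames(r_star) <- list(rownames(expr), rownames(expr))
  list(R_star = r_star, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' With `W = R*^-1`, `pcor_ij = -W_ij / sqrt(W_ii W_jj)`; the diagonal is set
#' to 1.
#'
#' @param R_star Symmetric positive-definite correlation matrix.
#' @return Symmetric partial-correlation matrix.
#' @export
pcor_from_correlation <- function(R_star) {
  if (!isSymmetric(unname(R_star), tol = 1e-8)) stop("input must be symmetric")
  ch <- tryCatch(chol(R_star), error = function(e) {
    ev <- min(eigen(R_star, symmetric = TRUE, only.values = TRUE)$values)
    stop("correlation matrix not positive definite (min eigenvalue ",
         signif(ev, 4), ")")
  })
  w <- chol2inv(ch)
  d <- sqrt(diag(w))
  pc <- -w / tcrossprod(d)
  diag(pc) <- 1
  dimnames(pc) <- dimnames(R_star)
  pc
}

# null density f0(r; kappa); vectorized in r
null_density <- function(r, kappa) {
  exp(((kappa - 3) / 2) * log1p(-r^2) - lbeta(0.5, (kappa - 1) / 2))
}

#' Two-sided p-value of a partial correlation under the empirical null
#'
#' `p = P(|R| >= |r|)` where `R^2 ~ Beta(1/2, (kappa - 1) / 2)`.
#'
#' @param r Partial correlation value(s) in (-1, 1).
#' @param kappa Null degrees-of-freedom parameter, > 1.
#' @return p-value(s) in \[0, 1\].
#' @export
edge_pvalue <- function(r, kappa) {
  stopifnot(kappa > 1)
  out <- numeric(length(r))
  boundary <- abs(r) >= 1
  if (any(boundary)) {
    warning(sum(boundary), " value(s) with |r| >= 1; p set to 0")
    out[boundary] <- 0
  }
  out[!boundary] <- pbeta(r[!boundary]^2, 0.5, (kappa - 1) / 2,
                          lower.tail = FALSE)
  out
}

# E[R^2 | R^2 <= t] under the null: Beta(1/2, (kappa-1)/2) truncated at t
truncated_null_r2_mean <- function(kappa, t) {
  (1 / kappa) * pbeta(t, 1.5, (kappa - 1) / 2) /
    pbeta(t, 0.5, (kappa - 1) / 2)
}

#' Fit the empirical null of observed partial correlations
#'
#' `kappa` is estimated by matching the mean of `r^2` over the central mass
#' (|r| at or below its 80th percentile) to the truncated-null expectation
#' `E[R^2 | R^2 <= a^2]`, which corrects for the truncation analytically.
#' `eta0` is estimated Storey-style: `#(p > l) / (m (1 - l))` on the grid
#' `l = 0.3, 0.4, ..., 0.7`, taking the median and capping at 1.
#'
#' @param pcors Numeric vector of observed partial correlations (>= 100
#'   recommended; fewer triggers a warning).
#' @param n_samples,n_genes Bookkeeping recorded in the fit.
#' @return Object of class `ggm_fit`: list with `lambda` (filled by
#'   [edge_table()]), `kappa`, `eta0`, `n_samples`, `n_genes`.
#' @export
fit_null <- function(pcors, n_samples = NA_integer_, n_genes = NA_integer_) {
  pcors <- pcors[is.finite(pcors)]
  if (length(pcors) < 3L) stop("too few partial correlations to fit a null")
  if (length(pcors) < 100L) warning("fewer than 100 partial correlations; null fit unstable")
  if (sd(pcors) == 0) stop("degenerate partial correlations (all equal)")
  a <- quantile(abs(pcors), 0.8, names = FALSE)
  if (a == 0) stop("central partial-correlation mass is all zero")
  central <- pcors[abs(pcors) <= a]
  target <- mean(central^2)
  f <- function(kappa) truncated_null_r2_mean(kappa, a^2) - target
  kappa <- if (f(1e7) > 0) {
    1e7                                  # flatter than any admissible null
  } else if (f(3.0001) < 0) {
    3.0001                               # heavier-tailed than the null allows
  } else {
    uniroot(f, c(3.0001, 1e7), tol = 1e-9)$root
  }
  p <- edge_pvalue(pmin(abs(pcors), 1 - 1e-12) * sign(pcors), kappa)
  grid <- seq(0.3, 0.7, by = 0.1)
  eta0 <- min(1, median(vapply(grid, function(l) mean(p > l) / (1 - l),
                               numeric(1L))))
  structure(list(lambda = NA_real_, kappa = kappa, eta0 = eta0,
                 n_samples = n_samples, n_genes = n_genes),
            class = "ggm_fit")
}

#' @export
print.ggm_fit <- function(x, ...) {
  cat(sprintf("ggm_fit: lambda = %.4g, kappa = %.4g, eta0 = %.4g (n = %s, p = %s)\n",
              x$lambda, x$kappa, x$eta0, x$n_samples, x$n_genes))
  invisible(x)
}

#' Posterior edge probabilities from the fitted two-component mixture
#'
#' `prob = max(0, 1 - eta0 f0(r; kappa) / f(r))` where `f` is a Gaussian
#' kernel density estimate of the observed partial correlations (bandwidth
#' `bw.nrd0`, 512 grid points), i.e. one minus the local false discovery
#' rate. Monotonicity in `|r|` is then enforced by isotonic regression.
#'
#' @param r Vector of observed partial correlations (the full edge set; the
#'   mixture density is estimated from it unless `density_of_observed` is
#'   given).
#' @param fit `ggm_fit`.
#' @param density_of_observed Optional function mapping r to the estimated
#'   mixture density f(r).
#' @return Probabilities in \[0, 1\], same order as `r`.
#' @export
edge_probability <- function(r, fit, density_of_observed = NULL) {
  stopifnot(inherits(fit, "ggm_fit"))
  if (is.null(density_of_observed)) {
    de <- density(r, bw = "nrd0", n = 512,
                  from = min(r) - 0.05, to = max(r) + 0.05)
    density_of_observed <- function(x) approx(de$x, de$y, x, rule = 2)$y
  }
  fhat <- density_of_observed(r)
  bad <- !is.finite(fhat) | fhat <= 0
  if (any(bad)) {
    warning(sum(bad), " point(s) with zero mixture density; prob set to 0")
    fhat[bad] <- 1
  }
  prob <- pmax(0, 1 - fit$eta0 * null_density(r, fit$kappa) / fhat)
  prob[bad] <- 0
  # isotonic in |r|
  o <- order(abs(r))
  iso <- isoreg(abs(r)[o], prob[o])$yf
  prob[o] <- iso
  pmin(1, pmax(0, prob))
}

#' Full edge-statistics table for an expression matrix
#'
#' Composes shrinkage correlation -> partial correlation -> empirical-null
#' p-values (with BH q-values) -> posterior edge probabilities. One row per
#' unordered gene pair, node names in canonical (lexicographic) order.
#'
#' @param expr Numeric matrix (genes x samples).
#' @return List with `stats` (data.frame `node1, node2, pcor, pval, qval,
#'   prob`) and `fit` (`ggm_fit` including the shrinkage `lambda`).
#' @export
edge_table <- function(expr) {
  sc <- shrink_correlation(expr)
  pc <- pcor_from_correlation(sc$R_star)
  genes <- rownames(pc)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  g1 <- genes[ut[, 1L]]
  g2 <- genes[ut[, 2L]]
  swap <- g1 > g2
  tmp <- g1[swap]; g1[swap] <- g2[swap]; g2[swap] <- tmp
  r <- pc[ut]
  fit <- fit_null(r, n_samples = ncol(expr), n_genes = nrow(expr))
  fit$lambda <- sc$lambda
  pv <- edge_pvalue(pmin(abs(r), 1 - 1e-12) * sign(r), fit$kappa)
  stats <- data.frame(node1 = g1, node2 = g2, pcor = r, pval = pv,
                      qval = bh_adjust(pv),
                      prob = edge_probability(r, fit),
                      stringsAsFactors = FALSE)
  list(stats = stats, fit = fit)
}

#' Threshold an edge table into a network
#'
#' Keeps edges with `prob > prob_cutoff` (strict); the node set is the genes
#' incident to at least one retained edge.
#'
#' @param stats Edge-statistics data.frame from [edge_table()].
#' @param prob_cutoff Probability cutoff in \[0, 1).
#' @return igraph with edge attributes `pcor` and `prob`.
#' @export
threshold_network <- function(stats, prob_cutoff = 0.5) {
  stopifnot(prob_cutoff >= 0, prob_cutoff < 1)
  keep <- stats$prob > prob_cutoff
  universe <- unique(c(stats$node1, stats$node2))
  if (!any(keep)) {
    message("no edges above cutoff ", prob_cutoff, "; ", length(universe),
            " isolated gene(s) dropped")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  df <- stats[keep, c("node1", "node2", "pcor", "prob")]
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  n_iso <- length(universe) - igraph::vcount(g)
  if (n_iso > 0L) message(n_iso, " isolated gene(s) dropped at cutoff ",
                          prob_cutoff)
  g
}

#' The default edge-probability cutoff grid
#'
#' 0 to 0.95 in steps of 0.05, plus 0.96, 0.97, 0.98, 0.99 and 0.999
#' (25 values).
#'
#' @return Numeric vector of length 25.
#' @export
default_cutoff_grid <- function() {
  c(seq(0, 0.95, by = 0.05), 0.96, 0.97, 0.98, 0.99, 0.999)
}

#' Threshold an edge table over a grid of cutoffs
#'
#' @param stats Edge-statistics data.frame.
#' @param cutoffs Cutoff values in \[0, 1) (default [default_cutoff_grid()]).
#' @return Named list of igraphs (names = cutoff values); networks are nested
#'   (higher cutoff is a subgraph of lower cutoff).
#' @export
scan_cutoffs <- function(stats, cutoffs = default_cutoff_grid()) {
  stopifnot(all(cutoffs >= 0), all(cutoffs < 1))
  setNames(lapply(cutoffs, function(cc) threshold_network(stats, cc)),
           as.character(cutoffs))
}

#' Network density against a node universe
#'
#' @param net igraph.
#' @param node_universe Number of genes in the universe (>= 2).
#' @return `2 |E| / (u (u - 1))` in \[0, 1\].
#' @export
network_density <- function(net, node_universe) {
  stopifnot(node_universe >= 2)
  2 * igraph::ecount(net) / (node_universe * (node_universe - 1))
}
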