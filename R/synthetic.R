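# Synthetic perturbation studies sampled from known sparse Gaussian graphical
# models. The generator plants: a scale-free scaffold with one hub target
# gene, a knockdown time course (depth ramping to its maximum at the last
# harvest), overexpression clones with clone-specific gains, and a set of
# transfection-artifact genes shifted in every transfected condition.

#' Generate a scaffold graph for a synthetic gene association network
#'
#' Preferential attachment (default) yields the heavy-tailed degree
#' distribution observed in reconstructed gene association networks; an
#' Erdos-Renyi variant is available for calibration experiments.
#'
#' @param n_genes Number of genes (nodes); must exceed `attach_m`.
#' @param attach_m Edges attached by each incoming node (preferential
#'   attachment), or expected degree for the Erdos-Renyi variant.
#' @param seed Integer seed; the generator is deterministic given it.
#' @param method `"pa"` (preferential attachment, connected) or `"er"`.
#' @return igraph with gene-symbol vertex names (`G0001`, ...).
#' @export
generate_scaffold <- function(n_genes, attach_m = 2L, seed = 1L,
                              method = c("pa", "er")) {
  method <- match.arg(method)
  if (!is.numeric(n_genes) || n_genes <= attach_m || attach_m < 1L) {
    stop("require n_genes > attach_m >= 1")
  }
  n_genes <- as.integer(n_genes)
  withr_seed(seed, {
    g <- if (method == "pa") {
      igraph::sample_pa(n_genes, m = attach_m, directed = FALSE,
                        algorithm = "psumtree")
    } else {
      igraph::sample_gnp(n_genes, p = min(1, attach_m / (n_genes - 1)))
    }
    igraph::V(g)$name <- gene_names(n_genes)
    igraph::simplify(g)
  })
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))

# run expr under a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Build a positive-definite precision matrix on a scaffold
#'
#' Partial correlations are planted directly: at unit diagonal,
#' `pcor_ij = -precision_ij`. Edge magnitudes are drawn uniformly from
#' `[pcor_lo, pcor_hi]` with random signs, then damped by
#' `sqrt(budget / max(2, d_i, d_j))`: positive definiteness caps the
#' partial-correlation energy a node can carry at `sum_j pcor_ij^2 < 1`
#' (exactly 1 for a star), so a degree-d hub cannot hold d large partial
#' correlations and its edges are scaled to share a `budget < 1` of that
#' cap. If the damped matrix is still not positive definite (dense
#' scaffolds), all edges are shrunk by a geometric factor 0.9^k until the
#' smallest eigenvalue exceeds 0.01. The total damping applied to the
#' lightest edge is the rescaling constant `c` reported on the model, so
#' achieved magnitudes lie in `[pcor_lo * c, pcor_hi]`.
#'
#' @param scaffold Simple undirected igraph with named vertices.
#' @param pcor_lo,pcor_hi Target range of edge partial-correlation magnitudes
#'   before degree damping, both in (0, 1).
#' @param seed Integer seed.
#' @param budget Fraction of the per-node positive-definiteness cap allotted
#'   to edge weights (default 0.8).
#' @param max_attempts Maximum geometric rescaling steps before failing.
#' @return Object of class `precision_model`: list with `gene_ids`,
#'   `scaffold`, `precision`, `pcor` (implied partial correlations) and
#'   `rescale_c`.
#' @export
build_precision <- function(scaffold, pcor_lo = 0.8, pcor_hi = 0.95,
                            seed = 1L, budget = 0.8, max_attempts = 200L) {
  stopifnot(pcor_lo > 0, pcor_hi < 1, pcor_lo <= pcor_hi,
            budget > 0, budget < 1)
  if (any(igraph::which_loop(scaffold)) || any(igraph::which_multiple(scaffold))) {
    stop("scaffold must be a simple graph")
  }
  ids <- igraph::V(scaffold)$name
  p <- length(ids)
  el <- igraph::as_edgelist(scaffold, names = FALSE)
  P <- matrix(0, p, p, dimnames = list(ids, ids))
  gamma <- 1
  if (nrow(el) > 0L) {
    deg <- igraph::degree(scaffold)
    draw <- withr_seed(seed, list(mag = runif(nrow(el), pcor_lo, pcor_hi),
                                  sgn = sample(c(-1, 1), nrow(el),
                                               replace = TRUE)))
    damp <- sqrt(budget / pmax(2, deg[el[, 1L]], deg[el[, 2L]]))
    w <- draw$sgn * draw$mag * damp
    ok <- FALSE
    for (k in seq_len(max_attempts)) {
      P[el] <- w * gamma
      P[el[, c(2L, 1L)]] <- w * gamma
      omega <- diag(p) - P
      if (min(eigen(omega, symmetric = TRUE, only.values = TRUE)$values) > 0.01) {
        ok <- TRUE
        break
      }
      gamma <- gamma * 0.9
    }
    if (!ok) stop("could not reach positive definiteness after ", max_attempts,
                  " rescaling attempts")
    rescale_c <- gamma * min(damp)
  } else {
    rescale_c <- 1
  }
  omega <- diag(p) - P
  dimnames(omega) <- list(ids, ids)
  pcor <- P
  diag(pcor) <- 1
  structure(list(gene_ids = ids, scaffold = scaffold, precision = omega,
                 pcor = pcor, rescale_c = rescale_c),
            class = "precision_model")
}

#' @export
print.precision_model <- function(x, ...) {
  cat("precision_model:", length(x$gene_ids), "genes,",
      igraph::ecount(x$scaffold), "scaffold edges, rescale c =",
      signif(x$rescale_c, 3), "\n")
  invisible(x)
}

#' Default perturbation-study design
#'
#' Emulates a knockdown time course (two biological units, each with two
#' technical replicates, harvested at the given hours), untreated and
#' non-sense-transfected controls around the 48 h harvest, three
#' overexpression clones plus a transduction-negative clone (two technical
#' replicates each).
#'
#' @param timepoints_h Knockdown harvest times in hours.
#' @param n_bio Biological units per knockdown timepoint.
#' @param n_tech Technical replicates per biological unit.
#' @param ox_clones Labels of the overexpressing clones.
#' @return data.frame with columns `sample_id, condition, timepoint_h,
#'   clone_id, replicate_kind, bio_rep`.
#' @export
study_design <- function(timepoints_h = c(20, 28, 44, 48, 52, 68, 72, 76),
                         n_bio = 2L, n_tech = 2L,
                         ox_clones = c("OX1", "OX2", "OX3")) {
  rows <- list()
  add <- function(condition, timepoint, clone, bio, tech) {
    kind <- if (tech > 1L) "technical" else "biological"
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sprintf("%s_t%02d_%s_b%d_r%d", condition, timepoint,
                          if (nzchar(clone)) clone else "x", bio, tech),
      condition = condition, timepoint_h = timepoint, clone_id = clone,
      replicate_kind = kind, bio_rep = bio, stringsAsFactors = FALSE)
  }
  for (tp in timepoints_h) for (b in seq_len(n_bio)) for (r in seq_len(n_tech)) {
    add("sirna_kd", tp, "", b, r)
  }
  for (tp in c(0, 48)) for (b in seq_len(n_bio)) for (r in seq_len(n_tech)) {
    add("untreated", tp, "", b, r)
  }
  for (b in seq_len(n_bio)) for (r in seq_len(n_tech)) add("nonsense", 48, "", b, r)
  for (cl in ox_clones) for (r in seq_len(n_tech)) add("ox_clone", 0, cl, 1L, r)
  for (r in seq_len(n_tech)) add("negative_clone", 0, "NEG", 1L, r)
  out <- do.call(rbind, rows)
  validate_design(out)
  out
}

#' Sample baseline expression from a precision model
#'
#' One multivariate-normal draw per design row, covariance equal to the
#' inverse of the model precision, plus a per-gene baseline intensity on the
#' log2 microarray scale (mean 8, sd 1.5).
#'
#' @param model `precision_model`.
#' @param design Study design data.frame.
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param marginal_sd Scale applied to the graphical-model draw: the sample
#'   covariance is `marginal_sd^2 * solve(precision)`. The default 1 keeps
#'   the covariance equal to the inverse precision; [simulate_study()] uses
#'   0.4, a realistic within-condition replicate noise on the log2 array
#'   scale. Correlations (and hence the encoded network) are unaffected.
#' @return Numeric matrix (genes x samples), log2 scale.
#' @export
sample_expression <- function(model, design, seed = 1L,
                              baseline_mean = 8, baseline_sd = 1.5,
                              marginal_sd = 1) {
  stopifnot(inherits(model, "precision_model"), nrow(design) > 0L)
  validate_design(design)
  sigma <- tryCatch(solve(model$precision),
                    error = function(e) stop("singular precision matrix"))
  n <- nrow(design)
  p <- length(model$gene_ids)
  withr_seed(seed, {
    base <- rnorm(p, baseline_mean, baseline_sd)
    draws <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = sigma)
    expr <- marginal_sd * t(draws) + base
    dimnames(expr) <- list(model$gene_ids, design$sample_id)
    expr
  })
}

#' Knockdown depth ramp over the time course
#'
#' Monotone linear ramp of the knockdown depth fraction across sorted unique
#' timepoints, from `from` at the first harvest to 1 (full depth) at the last.
#'
#' @param timepoints_h Numeric vector of harvest times.
#' @param from Fraction of full depth at the earliest harvest.
#' @return Named numeric vector, one fraction per unique timepoint.
#' @export
kd_ramp <- function(timepoints_h, from = 0.6) {
  tp <- sort(unique(timepoints_h))
  if (length(tp) == 1L) return(setNames(1, tp))
  setNames(from + (1 - from) * (tp - tp[1L]) / (tp[length(tp)] - tp[1L]), tp)
}

#' Apply target, propagation and artifact shifts to baseline expression
#'
#' The target gene is shifted by `kd_depth_log2 * ramp(timepoint)` in
#' knockdown samples and by `ox_gain_log2 * clone multiplier` in
#' overexpression clones. Every scaffold neighbor of the target is shifted by
#' `propagation * edge sign * target shift` in the same samples. Artifact
#' genes are shifted by `artifact_shift_log2` in all transfected samples
#' (knockdown and non-sense); untreated and negative-clone samples are
#' untouched. Given fixed clone multipliers the operation is deterministic.
#'
#' @param expr Baseline expression matrix from [sample_expression()].
#' @param design Study design.
#' @param model `precision_model` providing the scaffold and edge signs.
#' @param target_gene Perturbed gene symbol (must be in the model).
#' @param kd_depth_log2 Negative log2 shift at full knockdown depth
#'   (default -5.32, i.e. ~2.5% of control mRNA at the last harvest).
#' @param ox_gain_log2 Positive log2 gain of the overexpression clones
#'   (default 5.83, ~57-fold).
#' @param propagation Fraction of the target shift passed to scaffold
#'   neighbors, in \[0, 1\].
#' @param artifact_genes Genes shifted by the transfection procedure itself.
#' @param artifact_shift_log2 Log2 shift applied to artifact genes.
#' @param clone_multipliers Named or unnamed multipliers per clone; `NULL`
#'   draws them uniformly from \[0.9, 1.1\] using `seed`.
#' @param response_sd Per-sample heterogeneity of the propagated neighbor
#'   response: each neighbor shift is multiplied by `1 + N(0, response_sd)`
#'   independently per gene and sample (expectation unchanged). 0 makes the
#'   perturbation fully deterministic; downstream responses in real cells are
#'   never exactly proportional to the perturbation, so [simulate_study()]
#'   keeps the default 0.25.
#' @param ramp Named depth-fraction vector per timepoint; default [kd_ramp()].
#' @param seed Integer seed (used for `response_sd > 0` and when
#'   `clone_multipliers` is `NULL`).
#' @return Object of class `synthetic_study`: list with `expression`,
#'   `design`, `truth` (model, target_gene, artifact_genes, shifts).
#' @export
apply_perturbation <- function(expr, design, model, target_gene,
                               kd_depth_log2 = -5.32, ox_gain_log2 = 5.83,
                               propagation = 0.35, artifact_genes = character(),
                               artifact_shift_log2 = 2,
                               clone_multipliers = c(0.9, 1.0, 1.1),
                               response_sd = 0.25, ramp = NULL, seed = 1L) {
  stopifnot(kd_depth_log2 <= 0, ox_gain_log2 >= 0,
            propagation >= 0, propagation <= 1)
  if (!target_gene %in% model$gene_ids) stop("unknown target gene: ", target_gene)
  if (!all(artifact_genes %in% model$gene_ids)) stop("artifact genes outside model")
  validate_design(design)
  need <- c("sirna_kd", "ox_clone", "nonsense")
  if (!all(need %in% design$condition)) {
    stop("design must contain conditions: ", paste(need, collapse = ", "))
  }
  kd <- design$condition == "sirna_kd"
  if (is.null(ramp)) ramp <- kd_ramp(design$timepoint_h[kd])
  clones <- unique(design$clone_id[design$condition == "ox_clone"])
  if (is.null(clone_multipliers)) {
    clone_multipliers <- withr_seed(seed, runif(length(clones), 0.9, 1.1))
  }
  if (is.null(names(clone_multipliers))) {
    if (length(clone_multipliers) < length(clones)) {
      stop("need one clone multiplier per overexpression clone")
    }
    clone_multipliers <- setNames(clone_multipliers[seq_along(clones)], clones)
  }

  shift <- matrix(0, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  # per-sample shift of the target gene
  target_shift <- numeric(ncol(expr))
  target_shift[kd] <- kd_depth_log2 * ramp[as.character(design$timepoint_h[kd])]
  ox <- design$condition == "ox_clone"
  target_shift[ox] <- ox_gain_log2 * clone_multipliers[design$clone_id[ox]]
  shift[target_gene, ] <- target_shift
  # one-step propagation along scaffold edges, signed by the implied pcor;
  # heterogeneity keeps the expectation and breaks exact collinearity of the
  # propagated responses
  nbrs <- igraph::neighbors(model$scaffold, target_gene)$name
  het <- if (response_sd > 0) {
    withr_seed(seed + 1L,
               matrix(1 + rnorm(length(nbrs) * ncol(expr), 0, response_sd),
                      length(nbrs), ncol(expr)))
  } else matrix(1, length(nbrs), ncol(expr))
  for (i in seq_along(nbrs)) {
    nb <- nbrs[i]
    shift[nb, ] <- shift[nb, ] +
      propagation * sign(model$pcor[target_gene, nb]) * target_shift * het[i, ]
  }
  transfected <- design$condition %in% c("sirna_kd", "nonsense")
  if (length(artifact_genes)) {
    shift[artifact_genes, transfected] <- shift[artifact_genes, transfected] +
      artifact_shift_log2
  }
  structure(list(
    expression = expr + shift,
    design = design,
    truth = list(model = model, target_gene = target_gene,
                 artifact_genes = artifact_genes,
                 shift = shift,
                 params = list(kd_depth_log2 = kd_depth_log2,
                               ox_gain_log2 = ox_gain_log2,
                               propagation = propagation,
                               artifact_shift_log2 = artifact_shift_log2,
                               clone_multipliers = clone_multipliers,
                               ramp = ramp))),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("synthetic_study:", nrow(x$expression), "genes x", ncol(x$expression),
      "samples; target", x$truth$target_gene, "with",
      length(igraph::neighbors(x$truth$model$scaffold, x$truth$target_gene)),
      "scaffold neighbors;", length(x$truth$artifact_genes),
      "artifact genes\n")
  invisible(x)
}

#' Degrade a true network into an imperfect curated reference
#'
#' Each true edge is dropped independently with probability `fn_rate`
#' (missed curation); each non-edge is added with probability `fp_rate`
#' (spurious annotation).
#'
#' @param net Simple undirected igraph.
#' @param fn_rate,fp_rate False-negative / false-positive rates in \[0, 1\].
#' @param seed Integer seed.
#' @param source Label recorded on the result.
#' @return Reference igraph with attributes `source` and `order_k = 1`.
#' @export
degrade_network <- function(net, fn_rate = 0, fp_rate = 0, seed = 1L,
                            source = "degraded") {
  stopifnot(fn_rate >= 0, fn_rate <= 1, fp_rate >= 0, fp_rate <= 1)
  ids <- igraph::V(net)$name
  n <- length(ids)
  adj <- as.matrix(igraph::as_adjacency_matrix(net)) > 0
  withr_seed(seed, {
    keep <- adj & upper.tri(adj)
    ek <- which(keep)
    ek <- ek[runif(length(ek)) >= fn_rate]
    nonedge <- which(!adj & upper.tri(adj))
    fp <- nonedge[runif(length(nonedge)) < fp_rate]
    idx <- c(ek, fp)
    # which() on a matrix is column-major: row = (idx-1) %% n + 1
    em <- cbind(ids[(idx - 1L) %% n + 1L], ids[(idx - 1L) %/% n + 1L])
    g <- igraph::graph_from_edgelist(em[, c(1L, 2L), drop = FALSE],
                                     directed = FALSE)
    g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
    as_reference(g, source = source, order_k = 1L)
  })
}

#' Simulate a complete perturbation study with planted ground truth
#'
#' Convenience wrapper tying the synthetic stages together: scale-free
#' scaffold, precision model, baseline sampling, perturbation of the
#' highest-degree gene (the hub target), planted artifact genes, three
#' degraded reference networks and a 50-set gene-set catalog (three
#' truth-derived sets plus random sets).
#'
#' @param seed Integer master seed; substreams are derived from it.
#' @param n_genes,attach_m Scaffold size parameters.
#' @param n_artifact Number of planted transfection-artifact genes.
#' @param ... Passed on to [apply_perturbation()].
#' @return `synthetic_study` with extra elements `references` (list of
#'   igraphs) and `catalog` (named list of gene sets).
#' @export
simulate_study <- function(seed = 1L, n_genes = 120L, attach_m = 2L,
                           n_artifact = 12L, ...) {
  scaffold <- generate_scaffold(n_genes, attach_m, seed = seed)
  model <- build_precision(scaffold, seed = seed + 1L)
  target <- names(which.max(igraph::degree(scaffold)))
  nbrs <- igraph::neighbors(scaffold, target)$name
  pool <- setdiff(model$gene_ids, c(target, nbrs))
  artifacts <- withr_seed(seed + 2L, sample(pool, n_artifact))
  design <- study_design()
  expr <- sample_expression(model, design, seed = seed + 3L,
                            marginal_sd = 0.4)
  study <- apply_perturbation(expr, design, model, target,
                              artifact_genes = artifacts, seed = seed + 4L, ...)
  study$references <- list(
    reactome_like = degrade_network(scaffold, 0.20, 0.002, seed = seed + 5L,
                                    source = "reactome_like"),
    biogrid_like = degrade_network(scaffold, 0.35, 0.005, seed = seed + 6L,
                                   source = "biogrid_like"),
    string_like = degrade_network(scaffold, 0.50, 0.010, seed = seed + 7L,
                                  source = "string_like"))
  study$catalog <- synthetic_catalog(study, seed = seed + 8L)
  study
}

# hallmark-like catalog: 3 truth-derived sets + random sets, 50 total
synthetic_catalog <- function(study, n_sets = 50L, seed = 1L) {
  ids <- study$truth$model$gene_ids
  scaffold <- study$truth$model$scaffold
  target <- study$truth$target_gene
  nb1 <- igraph::neighbors(scaffold, target)$name
  nb2 <- setdiff(igraph::ego(scaffold, 2, target)[[1L]]$name, target)
  sets <- list(true_first_neighbors = nb1,
               true_second_neighborhood = nb2,
               planted_artifacts = study$truth$artifact_genes)
  withr_seed(seed, {
    for (i in seq_len(n_sets - length(sets))) {
      sets[[sprintf("random_set_%02d", i)]] <- sample(ids, sample(8:25, 1L))
    }
  })
  sets
}

#' Write a synthetic study to plain-text fixture files
#'
#' Writes `expression.tsv`, `design.tsv`, `truth_edges.tsv` (scaffold edge
#' list with implied pcor weights) and `artifact_genes.gmt`; the files
#' round-trip losslessly through [read_fixture()].
#'
#' @param study `synthetic_study`.
#' @param directory Output directory.
#' @param create Create the directory if missing (default); otherwise a
#'   missing directory is an error.
#' @param digits Decimal places for expression values.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(study, directory, create = TRUE, digits = 6L) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(directory)) {
    if (!create) stop("directory does not exist: ", directory)
    dir.create(directory, recursive = TRUE)
  }
  paths <- c(expression = file.path(directory, "expression.tsv"),
             design = file.path(directory, "design.tsv"),
             truth = file.path(directory, "truth_edges.tsv"),
             artifacts = file.path(directory, "artifact_genes.gmt"))
  write_expression(study$expression, paths["expression"], digits = digits)
  write_design(study$design, paths["design"])
  scaffold <- study$truth$model$scaffold
  el <- igraph::as_edgelist(scaffold)
  df <- data.frame(node1 = pmin(el[, 1L], el[, 2L]),
                   node2 = pmax(el[, 1L], el[, 2L]),
                   weight = study$truth$model$pcor[el],
                   stringsAsFactors = FALSE)
  write.table(df, paths["truth"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(list(transfection_artifact = study$truth$artifact_genes),
            paths["artifacts"],
            descriptions = "planted transfection-artifact genes")
  invisible(paths)
}

#' Read back a fixture directory written by [write_fixture()]
#' @param directory Directory containing the fixture files.
#' @return List with `expression`, `design`, `truth_edges` (data.frame) and
#'   `artifact_genes`.
#' @export
read_fixture <- function(directory) {
  list(expression = read_expression(file.path(directory, "expression.tsv")),
       design = read_design(file.path(directory, "design.tsv")),
       truth_edges = read.delim(file.path(directory, "truth_edges.tsv"),
                                stringsAsFactors = FALSE),
       artifact_genes = read_gmt(file.path(directory,
                                           "artifact_genes.gmt"))[[1L]])
}
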