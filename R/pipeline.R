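# Configuration-driven orchestration: simulate (optional) -> normalize ->
# technical averaging -> DE contrasts -> candidate gene sets -> GGM inference
# -> cutoff scan -> evaluation grid -> network selection -> analysis.

#' Pipeline configuration
#'
#' Builds and validates the configuration object consumed by
#' [run_pipeline()]. All defaults follow the reference workflow: DE at
#' `|log2FC| >= 0.5` and `FDR < 0.1`, the 25-value edge-probability cutoff
#' grid, 1000 permutations per evaluation cell, expansion orders 1-3, and
#' enrichment significance at adjusted p < 0.05.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory for TSV artifacts (`NULL` = do not write).
#' @param simulate Generate the input study with [simulate_study()] (default
#'   TRUE). Otherwise `expression_path`, `design_path`, `reference_paths` and
#'   `target_gene` must be supplied.
#' @param expression_path,design_path,reference_paths,catalog_path Input
#'   files used when `simulate = FALSE` (`catalog_path` a GMT file).
#' @param target_gene Perturbed gene; filled from the simulated truth when
#'   simulating.
#' @param min_abs_lfc,max_fdr DE selection thresholds.
#' @param cutoffs Edge-probability cutoff grid in \[0, 1).
#' @param n_perm Permutations per evaluation cell.
#' @param orders Reference expansion orders, subset of 1:3.
#' @param algebra Candidate-set expressions, see [build_candidate_sets()].
#' @param min_neighbors Minimum direct neighbors of the target required of
#'   the selected network.
#' @param min_cutoff Smallest admissible cutoff for the final network.
#' @param enrichment_alpha Significance level for enrichment.
#' @param validation_max_fdr FDR for the neighbor co-expression validation.
#' @param sim_args List of extra arguments passed to [simulate_study()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = NULL, simulate = TRUE,
                            expression_path = NULL, design_path = NULL,
                            reference_paths = NULL, catalog_path = NULL,
                            target_gene = NULL,
                            min_abs_lfc = 0.5, max_fdr = 0.1,
                            cutoffs = default_cutoff_grid(),
                            n_perm = 1000L, orders = 1:3,
                            algebra = default_set_algebra(),
                            min_neighbors = 2L, min_cutoff = 0.5,
                            enrichment_alpha = 0.05,
                            validation_max_fdr = 0.1,
                            sim_args = list()) {
  cfg <- list(seed = as.integer(seed), outdir = outdir, simulate = simulate,
              expression_path = expression_path, design_path = design_path,
              reference_paths = reference_paths, catalog_path = catalog_path,
              target_gene = target_gene, min_abs_lfc = min_abs_lfc,
              max_fdr = max_fdr, cutoffs = cutoffs,
              n_perm = as.integer(n_perm), orders = as.integer(orders),
              algebra = algebra, min_neighbors = as.integer(min_neighbors),
              min_cutoff = min_cutoff, enrichment_alpha = enrichment_alpha,
              validation_max_fdr = validation_max_fdr, sim_args = sim_args)
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  if (any(cfg$cutoffs < 0 | cfg$cutoffs >= 1)) {
    stop("cutoffs must lie in [0, 1)")
  }
  if (cfg$min_abs_lfc < 0) stop("min_abs_lfc must be >= 0")
  if (cfg$max_fdr <= 0 || cfg$max_fdr > 1) stop("max_fdr must be in (0, 1]")
  if (cfg$n_perm < 1L) stop("n_perm must be >= 1")
  if (!all(cfg$orders %in% 1:3)) stop("orders must be a subset of 1:3")
  if (!cfg$simulate) {
    need <- c("expression_path", "design_path", "reference_paths",
              "target_gene")
    bad <- need[vapply(cfg[need], is.null, logical(1L))]
    if (length(bad)) stop("non-simulated run needs: ",
                          paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()].
#' @return `pipeline_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

# DE contrasts on the replicate-averaged design; returns the per-timepoint
# knockdown sets, the overexpression consensus, and the two 48 h artifact
# contrasts, at the configured thresholds
run_de_stage <- function(expr, design, cfg) {
  cols <- function(cond, tp = NULL, clone = NULL) {
    sel <- design$condition == cond
    if (!is.null(tp)) sel <- sel & design$timepoint_h == tp
    if (!is.null(clone)) sel <- sel & design$clone_id == clone
    design$sample_id[sel]
  }
  untreated <- cols("untreated")
  de_list <- list()
  kd_sets <- list()
  for (tp in sort(unique(design$timepoint_h[design$condition == "sirna_kd"]))) {
    id <- sprintf("kd_%gh_vs_untreated", tp)
    de <- differential_expression(expr, cols("sirna_kd", tp), untreated,
                                  contrast_id = id)
    de_list[[id]] <- de
    kd_sets[[as.character(tp)]] <- select_de(de, cfg$min_abs_lfc, cfg$max_fdr)
  }
  control_ox <- c(cols("negative_clone"), cols("untreated", 48))
  ox_sets <- list()
  for (cl in unique(design$clone_id[design$condition == "ox_clone"])) {
    id <- sprintf("ox_%s_vs_control", cl)
    de <- differential_expression(expr, cols("ox_clone", clone = cl),
                                  control_ox, contrast_id = id)
    de_list[[id]] <- de
    ox_sets[[cl]] <- select_de(de, cfg$min_abs_lfc, cfg$max_fdr)
  }
  untreated48 <- cols("untreated", 48)
  de_kd48 <- differential_expression(expr, cols("sirna_kd", 48), untreated48,
                                     contrast_id = "kd_48h_vs_untreated_48h")
  de_ns48 <- differential_expression(expr, cols("nonsense", 48), untreated48,
                                     contrast_id = "nonsense_48h_vs_untreated_48h")
  de_list[["kd_48h_vs_untreated_48h"]] <- de_kd48
  de_list[["nonsense_48h_vs_untreated_48h"]] <- de_ns48
  list(de = de_list, kd_sets = kd_sets,
       ox_consensus = consensus_de(ox_sets),
       artifact = artifact_genes(
         select_de(de_kd48, cfg$min_abs_lfc, cfg$max_fdr),
         select_de(de_ns48, cfg$min_abs_lfc, cfg$max_fdr)))
}

#' Select the final network from the evaluation grid
#'
#' Default rule: the gene set with the most grid cells at `p_edges < 0.1`,
#' then the smallest cutoff at or above `min_cutoff` whose network contains
#' the target with at least `min_neighbors` direct neighbors. When no
#' candidate qualifies the outcome is an explicit no-selection, never a
#' silent default.
#'
#' @param grid Evaluation grid from [evaluate_grid()].
#' @param networks Nested list gene set -> cutoff -> igraph.
#' @param target_gene Target gene symbol.
#' @param min_cutoff Smallest admissible cutoff (default 0.5).
#' @param min_neighbors Minimum direct neighbors of the target (default 2).
#' @return List with `selected` (flag), `gene_set`, `cutoff`, `network` and a
#'   human-readable `rationale`.
#' @export
select_final_network <- function(grid, networks, target_gene,
                                 min_cutoff = 0.5, min_neighbors = 2L) {
  if (!nrow(grid)) stop("empty evaluation grid")
  summ <- attr(grid, "summary")
  if (is.null(summ)) {
    summ <- sort(vapply(split(grid$p_edges, grid$gene_set),
                        function(p) sum(!is.na(p) & p < 0.1), integer(1L)),
                 decreasing = TRUE)
  }
  rationale <- sprintf("cells with p_edges < 0.1 per gene set: %s",
                       paste(names(summ), summ, sep = "=", collapse = ", "))
  for (gs in names(summ)) {
    nets <- networks[[gs]]
    cuts <- sort(as.numeric(names(nets)))
    for (co in cuts[cuts >= min_cutoff]) {
      net <- nets[[as.character(co)]]
      if (target_gene %in% igraph::V(net)$name &&
          length(k_neighborhood(net, target_gene, 1L)) >= min_neighbors) {
        return(list(selected = TRUE, gene_set = gs, cutoff = co,
                    network = net,
                    rationale = paste0(
                      rationale, "; chose ", gs,
                      if (length(summ) == 1L) " (only candidate)" else
                        paste0(" (ranked ", match(gs, names(summ)),
                               " of ", length(summ), " by rejections)"),
                      " at cutoff ", co,
                      ", the smallest cutoff >= ", min_cutoff,
                      " whose network keeps >= ", min_neighbors,
                      " direct neighbors of ", target_gene)))
      }
    }
  }
  list(selected = FALSE, gene_set = NA_character_, cutoff = NA_real_,
       network = NULL,
       rationale = paste0(rationale, "; no network at cutoff >= ", min_cutoff,
                          " contains ", target_gene, " with >= ",
                          min_neighbors, " direct neighbors: no selection"))
}

#' Run the full reconstruction and evaluation pipeline
#'
#' Executes every stage on either a simulated study (default) or user-supplied
#' files, writes all intermediates as TSV when `outdir` is set, and returns
#' the stage results. Deterministic for a fixed configuration.
#'
#' @param config `pipeline_config`.
#' @return List with elements `study`, `normalized`, `de`, `gene_sets`,
#'   `edge_tables`, `networks`, `grid`, `selection`, `analysis`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }

  # inputs
  if (config$simulate) {
    study <- do.call(simulate_study,
                     c(list(seed = config$seed), config$sim_args))
    refs <- study$references
    catalog <- study$catalog
    target <- study$truth$target_gene
  } else {
    study <- list(expression = read_expression(config$expression_path),
                  design = read_design(config$design_path))
    refs <- lapply(config$reference_paths, read_reference_edgelist)
    if (is.null(names(refs))) names(refs) <- basename(unlist(config$reference_paths))
    catalog <- if (!is.null(config$catalog_path)) read_gmt(config$catalog_path)
    target <- config$target_gene
  }
  tick("input")

  # preprocessing
  qn <- quantile_normalize(study$expression)
  avg <- average_technical_replicates(qn, study$design)
  tick("preprocess")

  # differential expression + candidate sets
  de_stage <- run_de_stage(avg$expression, avg$design, config)
  gene_sets <- build_candidate_sets(de_stage$kd_sets, de_stage$ox_consensus,
                                    de_stage$artifact, config$algebra)
  tick("gene_sets")

  # GGM inference and cutoff scan per candidate set
  edge_tables <- list()
  networks <- list()
  for (gs in names(gene_sets)) {
    genes <- intersect(gene_sets[[gs]], rownames(avg$expression))
    if (length(genes) < 4L) {
      message("gene set ", gs, " has ", length(genes),
              " genes; skipped (needs >= 4)")
      next
    }
    et <- edge_table(avg$expression[genes, , drop = FALSE])
    edge_tables[[gs]] <- et
    networks[[gs]] <- scan_cutoffs(et$stats, config$cutoffs)
  }
  if (!length(networks)) stop("no candidate gene set large enough for inference")
  tick("inference")

  # evaluation grid and selection
  grid <- evaluate_grid(networks, refs, orders = config$orders,
                        n_perm = config$n_perm, seed = config$seed)
  tick("evaluation")
  selection <- select_final_network(grid, networks, target,
                                    min_cutoff = config$min_cutoff,
                                    min_neighbors = config$min_neighbors)
  tick("selection")

  # analysis of the selected network
  analysis <- NULL
  if (selection$selected) {
    net <- selection$network
    cent <- consensus_centrality(centralities(net))
    nb1 <- k_neighborhood(net, target, 1L)
    nb2 <- k_neighborhood(net, target, 2L)
    enr <- if (!is.null(catalog)) {
      fisher_enrichment(unique(c(nb1, nb2)), catalog,
                        universe = rownames(avg$expression),
                        alpha = config$enrichment_alpha)
    }
    val <- if (length(nb1)) {
      neighbor_correlation_validation(avg$expression, target, nb1,
                                      max_fdr = config$validation_max_fdr)
    }
    top100 <- head(cent$node, 100L)
    analysis <- list(
      centrality = cent, first_neighborhood = nb1, second_neighborhood = nb2,
      enrichment = enr, validation = val,
      degree_diagnostic = if (igraph::vcount(net) >= 10L)
        degree_distribution_diagnostic(net),
      top100_in_second_neighborhood =
        sum(top100 %in% c(nb2, target)) / length(top100))
  }
  tick("analysis")

  manifest <- list(package_version = as.character(utils::packageVersion("gannet")),
                   r_version = R.version.string,
                   seed = config$seed,
                   config = config[setdiff(names(config), "outdir")],
                   target_gene = target,
                   stage_seconds = as.list(timings))
  result <- list(study = study, normalized = avg, de = de_stage,
                 gene_sets = gene_sets, edge_tables = edge_tables,
                 networks = networks, grid = grid, selection = selection,
                 analysis = analysis, manifest = manifest)
  if (!is.null(config$outdir)) write_run_artifacts(result, config)
  result
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_run_artifacts <- function(result, config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  write_expression(result$normalized$expression, out("expression_normalized.tsv"))
  write_design(result$normalized$design, out("design_averaged.tsv"))
  write_tsv(do.call(rbind, result$de$de), out("de_results.tsv"))
  write_gmt(c(result$gene_sets,
              list(transfection_artifact = result$de$artifact)),
            out("gene_sets.gmt"))
  for (gs in names(result$edge_tables)) {
    write_tsv(result$edge_tables[[gs]]$stats, out(paste0("edges_", gs, ".tsv")))
  }
  write_tsv(result$grid, out("evaluation_grid.tsv"))
  if (result$selection$selected) {
    write_edgelist(result$selection$network, out("final_network.tsv"))
    igraph::write_graph(result$selection$network, out("final_network.graphml"),
                        format = "graphml")
    an <- result$analysis
    write_tsv(an$centrality, out("centrality.tsv"))
    if (!is.null(an$enrichment)) write_tsv(an$enrichment, out("enrichment.tsv"))
    if (!is.null(an$validation)) write_tsv(an$validation, out("validation.tsv"))
  }
  writeLines(result$selection$rationale, out("selection_report.txt"))
  jsonlite::write_json(result$manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(config$outdir)
}
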