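# Candidate gene sets for network reconstruction: transfection-artifact
# exclusion and a small set-expression language over the knockdown /
# overexpression DE results.

#' Transfection-artifact gene set
#'
#' Genes differentially expressed both between knockdown and untreated cells
#' and between non-sense-transfected and untreated cells at the same harvest
#' (48 h): the expression response attributable to the transfection procedure
#' itself rather than to the perturbed gene.
#'
#' @param de_sirna_vs_untreated Character vector (DE genes, knockdown vs
#'   untreated at 48 h).
#' @param de_nonsense_vs_untreated Character vector (DE genes, non-sense vs
#'   untreated at 48 h).
#' @return Character vector named `"transfection_artifact"` via attribute.
#' @export
artifact_genes <- function(de_sirna_vs_untreated, de_nonsense_vs_untreated) {
  out <- intersect(de_sirna_vs_untreated, de_nonsense_vs_untreated)
  attr(out, "set_name") <- "transfection_artifact"
  out
}

# recursive evaluator for set expressions: symbols resolve in `sets`,
# `&` intersection, `|` union, `-` set difference, kd_atleast(n) the genes
# differentially expressed in at least n knockdown timepoints.
eval_set_expr <- function(e, sets, kd_sets) {
  if (is.symbol(e)) {
    nm <- as.character(e)
    if (!nm %in% names(sets)) stop("unknown set token: ", nm)
    return(sets[[nm]])
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(eval_set_expr(e[[2L]], sets, kd_sets))
    if (op == "kd_atleast") {
      n <- eval(e[[2L]], baseenv())
      tab <- table(unlist(lapply(kd_sets, unique)))
      return(names(tab)[tab >= n])
    }
    if (op %in% c("&", "|", "-") && length(e) == 3L) {
      a <- eval_set_expr(e[[2L]], sets, kd_sets)
      b <- eval_set_expr(e[[3L]], sets, kd_sets)
      return(switch(op, "&" = intersect(a, b), "|" = union(a, b),
                    "-" = setdiff(a, b)))
    }
    stop("unsupported operator in set expression: ", op)
  }
  stop("unsupported token in set expression")
}

#' Default candidate-set algebra
#'
#' Four expressions over the tokens `kd_union`, `kd_intersect`, `ox` and
#' `kd_atleast(n)`, ordered so that set1 is the strictest (intersection over
#' all knockdown timepoints and the overexpression consensus) and set2 the
#' most permissive (union of everything).
#'
#' @return Named character vector of set expressions.
#' @export
default_set_algebra <- function() {
  c(set1 = "kd_intersect & ox",
    set2 = "kd_union | ox",
    set3 = "kd_atleast(2)",
    set4 = "kd_union & ox")
}

#' Build the candidate gene sets for network reconstruction
#'
#' Evaluates each algebra expression against the knockdown per-timepoint DE
#' sets and the overexpression consensus set, then removes the
#' transfection-artifact genes from every candidate set.
#'
#' @param kd_sets_by_timepoint Named list: timepoint -> DE gene vector.
#' @param ox_consensus Character vector (overexpression consensus DE genes).
#' @param artifact Character vector of artifact genes to exclude.
#' @param algebra Named character vector of set expressions
#'   (default [default_set_algebra()]).
#' @return Named list of character vectors, one per algebra entry.
#' @export
build_candidate_sets <- function(kd_sets_by_timepoint, ox_consensus,
                                 artifact = character(),
                                 algebra = default_set_algebra()) {
  if (!length(kd_sets_by_timepoint)) stop("empty knockdown DE map")
  if (is.null(names(algebra)) || any(!nzchar(names(algebra)))) {
    stop("algebra expressions must be named")
  }
  sets <- list(kd_union = Reduce(union, kd_sets_by_timepoint),
               kd_intersect = Reduce(intersect, kd_sets_by_timepoint),
               ox = ox_consensus)
  out <- lapply(algebra, function(ex) {
    parsed <- tryCatch(str2lang(ex),
                       error = function(e) stop("bad set expression: ", ex))
    sort(setdiff(eval_set_expr(parsed, sets, kd_sets_by_timepoint), artifact))
  })
  names(out) <- names(algebra)
  out
}
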