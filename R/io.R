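#' Read a log2 expression matrix from TSV
#'
#' The file must have a `gene_id` first column; remaining columns are samples.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix (genes x samples) with gene/sample dimnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "gene_id") {
    stop("expression TSV must have a 'gene_id' first column and >=1 sample column")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$gene_id
  validate_expression(m)
  m
}

#' Write an expression matrix to TSV
#'
#' Values are formatted with a fixed number of decimal places so that a
#' write/read/write cycle is byte-identical.
#'
#' @param expr Numeric matrix (genes x samples).
#' @param path Output path.
#' @param digits Decimal places used for formatting (default 6).
#' @export
write_expression <- function(expr, path, digits = 6L) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr),
                   formatC(expr, format = "f", digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (!all(is.finite(expr))) stop("expression values must all be finite")
  invisible(expr)
}

#' Read a sample design table from TSV
#'
#' Columns: `sample_id, condition, timepoint_h, clone_id, replicate_kind,
#' bio_rep`.
#'
#' @param path Path to a tab-separated file.
#' @return data.frame, one row per sample.
#' @export
read_design <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE,
                   colClasses = c(clone_id = "character"))
  validate_design(df)
  df
}

#' Write a sample design table to TSV
#' @param design data.frame as returned by [study_design()].
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

design_conditions <- c("untreated", "sirna_kd", "nonsense", "ox_clone",
                       "negative_clone")

validate_design <- function(design) {
  need <- c("sample_id", "condition", "timepoint_h", "clone_id",
            "replicate_kind", "bio_rep")
  missing <- setdiff(need, names(design))
  if (length(missing)) stop("design lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  bad <- setdiff(unique(design$condition), design_conditions)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (!all(design$replicate_kind %in% c("technical", "biological"))) {
    stop("replicate_kind must be 'technical' or 'biological'")
  }
  invisible(design)
}

#' Read an undirected reference network from a delimited edge list
#'
#' Accepts plain two-column edge lists (whitespace or tab separated) and the
#' SIF dialect `node1<TAB>interaction<TAB>node2`. Reversed duplicates are
#' collapsed and self-loops dropped (with a message).
#'
#' @param path Path to the edge-list file.
#' @param source Label recorded on the returned graph (e.g. "reactome-like").
#' @return igraph, simple and undirected, with graph attributes `source` and
#'   `order_k = 1`.
#' @export
read_reference_edgelist <- function(path, source = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) {
    warning("empty edge list: ", path)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    fields <- strsplit(trimws(lines), "[\t ]+")
    nf <- lengths(fields)
    if (any(nf < 2L)) {
      stop("malformed edge-list line ", which(nf < 2L)[1L], " in ", path)
    }
    # SIF when every line has >= 3 fields (middle field = interaction type)
    sif <- all(nf >= 3L)
    a <- vapply(fields, `[[`, "", 1L)
    b <- vapply(fields, function(f) f[[if (sif) 3L else 2L]], "")
    keep <- a != b
    n_self <- sum(!keep)
    if (n_self) message("dropped ", n_self, " self-loop(s) from ", path)
    em <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
    em <- unique(em)
    g <- igraph::graph_from_edgelist(em, directed = FALSE)
  }
  as_reference(g, source = source, order_k = 1L)
}

as_reference <- function(g, source = "reference", order_k = 1L) {
  g <- igraph::simplify(g)
  g <- igraph::set_graph_attr(g, "source", source)
  igraph::set_graph_attr(g, "order_k", as.integer(order_k))
}

#' Write a network as a two/three-column TSV edge list
#' @param net igraph.
#' @param path Output path.
#' @param attrs Edge attributes to append as extra columns (those present).
#' @export
write_edgelist <- function(net, path, attrs = c("pcor", "prob", "weight")) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(node1 = pmin(el[, 1L], el[, 2L]),
                   node2 = pmax(el[, 1L], el[, 2L]),
                   stringsAsFactors = FALSE)
  for (a in intersect(attrs, igraph::edge_attr_names(net))) {
    df[[a]] <- igraph::edge_attr(net, a)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#' @param path Path to a GMT file (`name<TAB>description<TAB>gene...`).
#' @return Named list of character vectors; descriptions kept as an attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) stop("malformed GMT line ", bad[1L], " in ", path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("all gene sets must be named")
  }
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}
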