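# Normalization, technical-replicate averaging and two-group differential
# expression with optional empirical-Bayes variance moderation.

#' Quantile-normalize an expression matrix
#'
#' Each column's sorted values are replaced by the across-column means of the
#' order statistics; ties receive the mean of their tied target values. After
#' normalization every column carries the identical multiset of values.
#'
#' @param expr Numeric matrix (genes x samples), all values finite.
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2L) stop("quantile normalization needs >= 2 samples")
  out <- limma::normalizeQuantiles(expr, ties = TRUE)
  dimnames(out) <- dimnames(expr)
  out
}

#' Average technical replicates into one column per biological unit
#'
#' Replicate groups are defined by `(condition, timepoint_h, clone_id,
#' bio_rep)`; each group is collapsed to its per-gene arithmetic mean and the
#' design is collapsed accordingly (one `biological` row per group).
#'
#' @param expr Numeric matrix (genes x samples).
#' @param design Study design with one row per column of `expr`.
#' @return List with collapsed `expression` and `design`.
#' @export
average_technical_replicates <- function(expr, design) {
  validate_expression(expr)
  validate_design(design)
  if (!setequal(colnames(expr), design$sample_id)) {
    stop("expression columns and design sample_ids differ")
  }
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  key <- paste(design$condition, design$timepoint_h, design$clone_id,
               design$bio_rep, sep = "|")
  groups <- split(seq_len(ncol(expr)), key)
  if (any(lengths(groups) == 0L)) stop("replicate group with zero members")
  # keep first-appearance order of groups
  groups <- groups[unique(key)]
  avg <- vapply(groups, function(ix) rowMeans(expr[, ix, drop = FALSE]),
                numeric(nrow(expr)))
  first <- vapply(groups, `[[`, integer(1L), 1L)
  new_design <- design[first, , drop = FALSE]
  new_design$sample_id <- sub("_r[0-9]+$", "", new_design$sample_id)
  new_design$replicate_kind <- "biological"
  rownames(new_design) <- NULL
  colnames(avg) <- new_design$sample_id
  list(expression = avg, design = new_design)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, clipped to \[0, 1\]; `NA` inputs propagate.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# moment-matched scaled-F prior for per-gene variances: s2 ~ s0^2 * F(d, d0).
# Var/E^2 = 2 (d + d0 - 2) / (d (d0 - 4)) is solved for d0; cv2*d <= 2 means
# no excess dispersion and the prior degenerates to a point (d0 = Inf).
fit_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2L) return(list(d0 = Inf, s0_2 = mean(s2)))
  m <- mean(s2)
  cv2 <- var(s2) / m^2
  if (!is.finite(cv2) || cv2 * df <= 2) return(list(d0 = Inf, s0_2 = m))
  d0 <- (2 * df - 4 + 4 * cv2 * df) / (cv2 * df - 2)
  if (!is.finite(d0) || d0 <= 4) d0 <- 4.1
  list(d0 = d0, s0_2 = m * (d0 - 2) / d0)
}

#' Two-group differential expression
#'
#' Per gene, `log2FC = mean(group_a) - mean(group_b)` and a t-statistic with
#' pooled variance; with `moderation = TRUE` the per-gene variances are
#' shrunk toward a moment-matched scaled-F prior (posterior variance
#' `(d0 s0^2 + d s^2) / (d0 + d)`, t on `d + d0` degrees of freedom), which
#' also allows single-sample groups. Adjusted values are Benjamini-Hochberg.
#'
#' @param expr Numeric matrix (genes x samples).
#' @param group_a,group_b Disjoint sets of column names.
#' @param moderation Borrow variance information across genes (default TRUE).
#' @param contrast_id Label stored in the result.
#' @return data.frame with columns `gene_id, log2fc, p, q, contrast_id`.
#' @export
differential_expression <- function(expr, group_a, group_b, moderation = TRUE,
                                    contrast_id = "contrast") {
  validate_expression(expr)
  group_a <- as.character(group_a)
  group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b))) stop("overlapping groups")
  missing <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  na <- length(group_a)
  nb <- length(group_b)
  if (!moderation && (na < 2L || nb < 2L)) {
    stop("both groups need >= 2 samples unless moderation is on")
  }
  if (na < 1L || nb < 1L) stop("both groups need >= 1 sample")
  df <- na + nb - 2L
  if (df < 1L) stop("no residual degrees of freedom (1 vs 1 comparison)")
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  lfc <- ma - mb
  ssq <- rowSums((a - ma)^2) + rowSums((b - mb)^2)
  s2 <- ssq / df
  se_factor <- 1 / na + 1 / nb
  if (moderation) {
    prior <- fit_variance_prior(s2, df)
    if (is.infinite(prior$d0)) {
      s2_post <- rep(prior$s0_2, length(s2))
      df_t <- Inf
    } else {
      s2_post <- (prior$d0 * prior$s0_2 + df * s2) / (prior$d0 + df)
      df_t <- df + prior$d0
    }
    tstat <- lfc / sqrt(s2_post * se_factor)
    p <- 2 * pt(-abs(tstat), df = df_t)
  } else {
    tstat <- lfc / sqrt(s2 * se_factor)
    p <- 2 * pt(-abs(tstat), df = df)
    bad <- s2 <= 0
    if (any(bad)) {
      message(sum(bad), " gene(s) with zero residual variance; p set to NA")
      p[bad] <- NA_real_
    }
  }
  data.frame(gene_id = rownames(expr), log2fc = lfc, p = p,
             q = bh_adjust(p), contrast_id = contrast_id,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differentially expressed genes
#'
#' Keeps genes with `|log2FC| >= min_abs_lfc` (inclusive) and `q < max_fdr`
#' (strict); genes with missing q are never selected.
#'
#' @param de DE result from [differential_expression()].
#' @param min_abs_lfc Minimum absolute log2 fold change (default 0.5).
#' @param max_fdr FDR threshold (default 0.1).
#' @return Character vector of gene ids.
#' @export
select_de <- function(de, min_abs_lfc = 0.5, max_fdr = 0.1) {
  keep <- !is.na(de$q) & abs(de$log2fc) >= min_abs_lfc & de$q < max_fdr
  de$gene_id[keep]
}

#' Consensus of differential-expression gene sets
#'
#' Intersection of all input sets (genes differentially expressed in each
#' comparison); a majority-vote variant keeps genes present in more than half
#' of the sets.
#'
#' @param sets Non-empty list of character vectors.
#' @param method `"intersection"` (default) or `"majority"`.
#' @return Character vector.
#' @export
consensus_de <- function(sets, method = c("intersection", "majority")) {
  method <- match.arg(method)
  if (!length(sets)) stop("empty list of gene sets")
  out <- if (method == "intersection") {
    Reduce(intersect, sets)
  } else {
    tab <- table(unlist(lapply(sets, unique)))
    names(tab)[tab > length(sets) / 2]
  }
  if (!length(out)) warning("consensus gene set is empty")
  out
}
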