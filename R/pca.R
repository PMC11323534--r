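#' Principal component analysis of replicate expression profiles
#'
#' Centered (optionally unit-variance) PCA of a sample x gene expression
#' matrix via singular value decomposition. Signs are fixed by a
#' deterministic convention: each dimension's loading vector is flipped so
#' its sum is non-negative, making results reproducible across BLAS
#' implementations.
#'
#' @param expr sample x gene numeric matrix (e.g. CPM values) with
#'   dimnames; at least 2 samples and 2 genes.
#' @param standardize scale genes to unit variance before the SVD.
#'   Zero-variance genes are dropped (with a message) when standardizing.
#' @return List of class `pca_result`: `scores` (sample x dimension),
#'   `explained` (variance fractions, non-increasing), `loadings`
#'   (gene x dimension).
#' @export
run_pca <- function(expr, standardize = FALSE) {
  if (!is.matrix(expr) || nrow(expr) < 2L || ncol(expr) < 2L)
    stop("expr must be a sample x gene matrix with >= 2 samples and genes")
  v <- apply(expr, 2L, stats::var)
  if (all(v == 0)) stop("constant expression matrix: PCA undefined")
  if (standardize && any(v == 0)) {
    message("dropping ", sum(v == 0), " zero-variance gene(s) before scaling")
    expr <- expr[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(expr, center = TRUE, scale. = standardize)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  scores <- sweep(pc$x, 2L, flip, `*`)
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  k <- ncol(scores)
  structure(list(scores = scores,
                 explained = expl[seq_len(k)],
                 loadings = loadings),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", nrow(x$scores), "samples,", nrow(x$loadings),
      "genes,", ncol(x$scores), "dimensions\n")
  cat("  explained:", paste(sprintf("%.1f%%", 100 * utils::head(x$explained, 4)),
                            collapse = ", "), "...\n")
  invisible(x)
}

#' Find the principal component separating the two conditions
#'
#' For every dimension, computes a standardized separation statistic,
#' |mean score difference between conditions| / pooled score SD, and
#' returns the dimension maximizing it (ties broken toward the lowest
#' index). When a condition effect dominates the transcriptome this is
#' dimension 1.
#'
#' @param pca a [run_pca()] result.
#' @param labels named character vector, sample id -> condition; exactly
#'   two conditions must be present.
#' @return List of class `axis_selection`: `dimension` (1-based),
#'   `separation`, and the per-dimension statistics (`all_separations`).
#' @export
find_condition_axis <- function(pca, labels) {
  stopifnot(inherits(pca, "pca_result"))
  samples <- rownames(pca$scores)
  if (!all(samples %in% names(labels)))
    stop("labels missing for sample(s): ",
         paste(setdiff(samples, names(labels)), collapse = ", "))
  lab <- labels[samples]
  lv <- unique(lab)
  if (length(lv) != 2L)
    stop("need exactly two conditions; found ", length(lv))
  g1 <- lab == lv[1L]
  sep <- apply(pca$scores, 2L, function(s) {
    n1 <- sum(g1); n2 <- sum(!g1)
    pooled <- sqrt(((n1 - 1) * stats::var(s[g1]) +
                    (n2 - 1) * stats::var(s[!g1])) / (n1 + n2 - 2))
    delta <- abs(mean(s[g1]) - mean(s[!g1]))
    if (pooled == 0) { if (delta == 0) 0 else Inf } else delta / pooled
  })
  dim <- which.max(sep)
  structure(list(dimension = unname(dim),
                 separation = unname(sep[dim]),
                 all_separations = unname(sep)),
            class = "axis_selection")
}

#' Correlation of each gene with the condition axis
#'
#' Pearson correlation of a gene's expression across samples with the
#' scores of the selected principal component. Zero-variance genes get
#' r = 0 and are flagged in the `zero_variance` attribute.
#'
#' @param expr sample x gene expression matrix (>= 3 samples).
#' @param axis_scores numeric vector of scores for the selected dimension,
#'   in the row order of `expr` (or named by sample).
#' @return Named numeric vector of correlations in `[-1, 1]` with logical
#'   attribute `zero_variance`.
#' @export
gene_axis_correlation <- function(expr, axis_scores) {
  if (nrow(expr) < 3L) stop("need >= 3 samples for correlation")
  if (!is.null(names(axis_scores)) && !is.null(rownames(expr)))
    axis_scores <- axis_scores[rownames(expr)]
  if (length(axis_scores) != nrow(expr))
    stop("axis_scores length does not match sample count")
  v <- apply(expr, 2L, stats::var)
  r <- rep(0, ncol(expr))
  names(r) <- colnames(expr)
  if (stats::var(axis_scores) == 0)
    stop("axis scores are constant")
  ok <- v > 0
  if (any(ok))
    r[ok] <- suppressWarnings(stats::cor(expr[, ok, drop = FALSE], axis_scores))
  attr(r, "zero_variance") <- !ok
  r
}

#' Correlation-threshold presets for candidate selection
#'
#' The gene-selection correlation cutoff is a required choice with two
#' documented presets: a permissive screen (`results_preset`, r > 0.5)
#' and a stringent one (`methods_preset`, r > 0.90). There is no silent
#' default.
#'
#' @param name `"results_preset"` or `"methods_preset"`.
#' @return The numeric cutoff.
#' @export
r_cutoff_preset <- function(name = c("results_preset", "methods_preset")) {
  c(results_preset = 0.5, methods_preset = 0.90)[[match.arg(name)]]
}

#' Select sulfur-responsive candidate genes
#'
#' A gene is a candidate when it is significantly differentially expressed,
#' its fold change exceeds `fold_change_cutoff`, and its expression
#' correlates with the condition axis beyond `r_cutoff` (both in absolute
#' value). Each candidate carries the direction of regulation (sign of the
#' log2 fold change in the sulfur condition).
#'
#' @param de a [test_de()] result covering the same genes as `corr`.
#' @param corr a [gene_axis_correlation()] vector.
#' @param fold_change_cutoff linear fold-change cutoff (> 1); default 2.
#' @param r_cutoff correlation cutoff in `[0, 1]`; no default, see
#'   [r_cutoff_preset()].
#' @return Data frame: `gene_id`, `log2_fold_change`, `r`, `direction`
#'   (`"up"`/`"down"`), sorted by descending |log2FC|.
#' @export
select_candidates <- function(de, corr, fold_change_cutoff = 2, r_cutoff) {
  if (missing(r_cutoff))
    stop("config error: r_cutoff is required (see r_cutoff_preset())")
  if (r_cutoff < 0 || r_cutoff > 1)
    stop("config error: r_cutoff must lie in [0, 1]")
  if (fold_change_cutoff <= 1)
    stop("config error: fold_change_cutoff must exceed 1")
  genes <- de$gene_id
  if (!all(genes %in% names(corr)))
    stop("correlations missing for gene(s): ",
         paste(utils::head(setdiff(genes, names(corr)), 5), collapse = ", "))
  r <- corr[genes]
  keep <- de$significant &
    abs(de$log2_fold_change) > log2(fold_change_cutoff) &
    abs(r) > r_cutoff
  out <- data.frame(gene_id = genes[keep],
                    log2_fold_change = de$log2_fold_change[keep],
                    r = unname(r[keep]),
                    direction = ifelse(de$log2_fold_change[keep] > 0,
                                       "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2_fold_change), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
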