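#' Build and validate a sample design table
#'
#' @param design data frame with columns `sample_id`, `species_id`,
#'   `condition` (one of `"sulfur"`, `"no_sulfur"`), `replicate`.
#' @param require_replication require >= 2 replicates per condition
#'   (needed for dispersion estimation and testing).
#' @return The validated design (class `sample_design`).
#' @export
sample_design <- function(design, require_replication = TRUE) {
  need <- c("sample_id", "species_id", "condition", "replicate")
  if (!all(need %in% names(design)))
    stop("design needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample ids")
  bad <- setdiff(unique(design$condition), c("sulfur", "no_sulfur"))
  if (length(bad))
    stop("condition must be 'sulfur' or 'no_sulfur'; found: ",
         paste(bad, collapse = ", "))
  tab <- table(design$condition)
  if (length(tab) < 2L)
    stop("both conditions must be present; found only: ", names(tab))
  if (require_replication && any(tab < 2L))
    stop("need >= 2 replicates per condition for testing")
  class(design) <- c("sample_design", "data.frame")
  design
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must be a matrix with gene row names and sample column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("duplicate gene or sample ids in count matrix")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  invisible(counts)
}

#' Counts per million
#'
#' Plain total-count library-size normalization:
#' `1e6 * count / column sum`.
#'
#' @param counts gene x sample non-negative integer matrix with dimnames.
#' @return Matrix of CPM values, same dimnames.
#' @export
compute_cpm <- function(counts) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  t(t(counts) / lib) * 1e6
}

#' Remove genes with negligible expression
#'
#' Keeps genes whose CPM reaches `min_cpm` in at least `min_samples`
#' samples.
#'
#' @param counts gene x sample count matrix.
#' @param min_cpm CPM threshold (0 keeps everything).
#' @param min_samples minimum number of samples at or above `min_cpm`.
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_cpm = 1, min_samples = 2) {
  cpm <- compute_cpm(counts)
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  counts[keep, , drop = FALSE]
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimator on library-size-normalized counts within
#' each condition (variance = mu + phi * mu^2), pooled across conditions by
#' residual degrees of freedom, then shrunk toward the common dispersion (a
#' 10%-trimmed mean over genes) with a prior weight of `shrink_weight`
#' pseudo-replicates. Estimates are floored at 1e-6 so downstream
#' negative-binomial fits stay defined.
#'
#' @param counts gene x sample count matrix.
#' @param design a [sample_design()] (or coercible data frame).
#' @param shrink_weight prior weight, in residual-df units, pulling
#'   per-gene estimates toward the common dispersion.
#' @return Named numeric vector of dispersions; the common (pre-shrink)
#'   dispersion is attached as attribute `common`.
#' @export
estimate_dispersions <- function(counts, design, shrink_weight = 10) {
  check_count_matrix(counts)
  design <- sample_design(as.data.frame(design), require_replication = FALSE)
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (any(is.na(design$sample_id)))
    stop("design missing sample(s): ",
         paste(setdiff(colnames(counts), design$sample_id), collapse = ", "))
  tab <- table(design$condition)
  if (any(tab < 2L))
    stop("single replicate in a condition: dispersion cannot be estimated; ",
         "supply a common dispersion to test_de(dispersion = ...)")
  lib <- colSums(counts)
  norm <- t(t(counts) / lib) * mean(lib)
  conds <- unique(design$condition)
  num <- matrix(0, nrow(counts), length(conds))
  dfs <- numeric(length(conds))
  for (k in seq_along(conds)) {
    sel <- design$condition == conds[k]
    x <- norm[, sel, drop = FALSE]
    mu <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    phi <- ifelse(mu > 0, pmax(0, (v - mu) / mu^2), NA_real_)
    num[, k] <- phi * (sum(sel) - 1L)
    dfs[k] <- sum(sel) - 1L
  }
  dfg <- as.vector((!is.na(num)) %*% dfs)
  phi_raw <- rowSums(num, na.rm = TRUE) / pmax(dfg, 1)
  phi_raw[dfg == 0] <- NA_real_
  common <- mean(phi_raw, trim = 0.1, na.rm = TRUE)
  if (!is.finite(common)) common <- 0
  phi <- (dfg * ifelse(is.na(phi_raw), 0, phi_raw) + shrink_weight * common) /
    (dfg + shrink_weight)
  phi <- pmax(phi, 1e-6)
  names(phi) <- rownames(counts)
  attr(phi, "common") <- max(common, 1e-6)
  phi
}

#' Two-condition differential expression by NB quasi-likelihood F-test
#'
#' Per gene, a negative-binomial GLM with log link and log-library-size
#' offset is fit for the condition model and compared with the
#' intercept-only model. The deviance drop is scaled by an
#' empirical-Bayes-moderated quasi-dispersion (the per-gene residual
#' deviance per degree of freedom, squeezed toward its trimmed mean across
#' genes with `shrink_weight` prior degrees of freedom) and referred to an
#' F distribution with `1` and `residual df + shrink_weight` degrees of
#' freedom. Fold changes are log2 ratios of condition mean CPM computed
#' with a 0.5-count offset (sulfur over no_sulfur); multiplicity is
#' controlled by Benjamini-Hochberg FDR.
#'
#' @param counts gene x sample count matrix.
#' @param design a [sample_design()] (or coercible data frame).
#' @param alpha FDR threshold for the `significant` flag.
#' @param dispersion optional fixed NB dispersion (scalar or per-gene
#'   vector); when `NULL`, estimated by [estimate_dispersions()].
#' @param shrink_weight prior weight for dispersion and quasi-dispersion
#'   moderation.
#' @return Data frame of class `de_result`: `gene_id`,
#'   `log2_fold_change`, `dispersion`, `p_value`, `fdr`, `significant`.
#' @export
test_de <- function(counts, design, alpha = 0.05, dispersion = NULL,
                    shrink_weight = 10) {
  check_count_matrix(counts)
  design <- sample_design(as.data.frame(design))
  design <- design[match(colnames(counts), design$sample_id), , drop = FALSE]
  if (any(is.na(design$sample_id)))
    stop("design missing sample(s): ",
         paste(setdiff(colnames(counts), design$sample_id), collapse = ", "))
  if (!all(c("sulfur", "no_sulfur") %in% design$condition))
    stop("a condition is entirely missing")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  ng <- nrow(counts)
  if (is.null(dispersion)) {
    phi <- estimate_dispersions(counts, design, shrink_weight = shrink_weight)
  } else {
    if (any(dispersion <= 0)) stop("dispersion must be positive")
    phi <- rep_len(dispersion, ng)
    names(phi) <- rownames(counts)
  }
  lib <- colSums(counts)
  cond <- factor(design$condition, levels = c("no_sulfur", "sulfur"))
  ## log2FC from condition mean CPM with a 0.5-count stabilizing offset
  cpm0 <- t(t(counts + 0.5) / (lib + 1)) * 1e6
  m_s <- rowMeans(cpm0[, cond == "sulfur", drop = FALSE])
  m_n <- rowMeans(cpm0[, cond == "no_sulfur", drop = FALSE])
  lfc <- log2(m_s) - log2(m_n)
  d0 <- d1 <- numeric(ng)
  dfr <- rep(length(cond) - 2L, ng)
  off <- log(lib)
  for (i in seq_len(ng)) {
    y <- counts[i, ]
    if (all(y == y[1L])) { d0[i] <- d1[i] <- 0; next }
    fit <- suppressWarnings(stats::glm(
      y ~ cond + offset(off),
      family = MASS::negative.binomial(1 / phi[i])))
    d0[i] <- fit$null.deviance
    d1[i] <- fit$deviance
    dfr[i] <- fit$df.residual
  }
  s2 <- d1 / dfr
  pos <- s2[s2 > 0 & is.finite(s2)]
  s2_0 <- if (length(pos)) mean(pos, trim = 0.1) else 1
  s2_post <- (dfr * s2 + shrink_weight * s2_0) / (dfr + shrink_weight)
  fstat <- (d0 - d1) / pmax(s2_post, 1e-12)
  p <- stats::pf(fstat, 1, dfr + shrink_weight, lower.tail = FALSE)
  p[d0 <= d1] <- 1
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene_id = rownames(counts),
                    log2_fold_change = unname(lfc),
                    dispersion = unname(phi),
                    p_value = p, fdr = fdr,
                    significant = fdr < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}
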