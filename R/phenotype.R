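#' Fit a sulfate standard curve
#'
#' Ordinary least-squares fit of assay absorbance against sulfate standard
#' concentration (turbidimetric BaCl2 assay, standards spanning 0-10 mM).
#'
#' @param standards data frame with columns `concentration_mM` and
#'   `absorbance`, or a two-column matrix in that order.
#' @return List of class `standard_curve` with `slope` (absorbance per mM),
#'   `intercept` (absorbance), and `r_squared`.
#' @export
fit_standard_curve <- function(standards) {
  standards <- as.data.frame(standards)
  if (!all(c("concentration_mM", "absorbance") %in% names(standards)))
    names(standards)[1:2] <- c("concentration_mM", "absorbance")
  conc <- standards$concentration_mM
  abso <- standards$absorbance
  if (length(conc) < 2L || length(unique(conc)) < 2L)
    stop("fit error: need at least two distinct standard concentrations")
  fit <- stats::lm(abso ~ conc)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((abso - mean(abso))^2)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: A = %.5g * c[mM] + %.5g  (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Convert assay absorbance to sulfate concentration
#'
#' Inverts the standard curve and multiplies by the dilution applied to
#' bring samples into the 0-10 mM assay range. Blank-subtracted readings
#' can dip below the intercept; the back-calculated concentration is then
#' clamped to 0 and flagged (attribute `clamped`) rather than erroring.
#'
#' @param curve a [fit_standard_curve()] result.
#' @param absorbance numeric vector of sample absorbances.
#' @param dilution_factor dilution applied before the assay (>= 1).
#' @return Numeric vector of sulfate concentrations (mM) with a logical
#'   attribute `clamped`.
#' @export
absorbance_to_sulfate <- function(curve, absorbance, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("standard curve has zero slope")
  if (any(dilution_factor < 1)) stop("dilution_factor must be >= 1")
  conc <- dilution_factor * (absorbance - curve$intercept) / curve$slope
  clamped <- conc < -sqrt(.Machine$double.eps)  # ignore float dust at zero
  if (any(clamped))
    warning(sum(clamped), " negative back-calculated concentration(s) clamped to 0")
  conc[conc < 0] <- 0
  attr(conc, "clamped") <- clamped
  conc
}

#' Specific sulfate production
#'
#' Sulfate generated per unit planktonic cell density (mM per OD600 unit),
#' the normalization that separates efficient sulfur oxidation from plain
#' cell growth.
#'
#' @param sulfate_mM non-negative sulfate concentration(s), mM.
#' @param od600 positive optical density at 600 nm.
#' @return `sulfate_mM / od600`.
#' @export
specific_production <- function(sulfate_mM, od600) {
  if (any(od600 <= 0)) stop("od600 must be positive")
  if (any(sulfate_mM < 0)) stop("sulfate_mM must be non-negative")
  sulfate_mM / od600
}

#' Default oxidizer classification thresholds
#'
#' `weak_max` (1 mM over 72 h) is the published weak-oxidizer boundary.
#' `strong_min` and `strong_specific_min` delimit the strong class; a
#' species above `strong_min` total sulfate but below the specific floor is
#' demoted one class, encoding the case of a species whose high sulfate
#' total reflects high cell density rather than efficient oxidation.
#'
#' @param weak_max mM; at or below, a species is weak.
#' @param strong_min mM; candidate-strong total sulfate boundary.
#' @param strong_specific_min mM per OD; specific-production floor for the
#'   strong class.
#' @return Named list of thresholds.
#' @export
oxidizer_thresholds <- function(weak_max = 1, strong_min = 20,
                                strong_specific_min = 30) {
  if (weak_max >= strong_min)
    stop("config error: weak_max must be below strong_min")
  if (any(c(weak_max, strong_min, strong_specific_min) < 0))
    stop("config error: thresholds must be non-negative")
  list(weak_max = weak_max, strong_min = strong_min,
       strong_specific_min = strong_specific_min)
}

#' Classify sulfur-oxidation strength
#'
#' Three-way classification from 72-h total sulfate and cell-density
#' normalized (specific) production: weak at or below `weak_max` total;
#' strong when both total and specific production clear their thresholds;
#' moderate otherwise. A species clearing `strong_min` on total sulfate
#' alone but failing the specific floor is demoted to moderate.
#'
#' @param sulfate_mM total sulfate after the culturing period, mM.
#' @param specific_production mM sulfate per OD600 unit.
#' @param thresholds see [oxidizer_thresholds()].
#' @return Character vector in `c("weak", "moderate", "strong")`.
#' @export
classify_oxidizer <- function(sulfate_mM, specific_production,
                              thresholds = oxidizer_thresholds()) {
  if (any(sulfate_mM < 0) || any(specific_production < 0))
    stop("inputs must be non-negative")
  thresholds <- do.call(oxidizer_thresholds, thresholds)
  cls <- ifelse(sulfate_mM <= thresholds$weak_max, "weak",
         ifelse(sulfate_mM >= thresholds$strong_min &
                specific_production >= thresholds$strong_specific_min,
                "strong", "moderate"))
  unname(cls)
}

#' Partition species into phenotype groups A and B
#'
#' Group B collects the weak sulfur oxidizers; group A collects every
#' species that demonstrated more than weak oxidation (moderate or strong).
#' This partition parameterizes the phenotype score.
#'
#' @param classifications named character vector, species id ->
#'   `"weak"`/`"moderate"`/`"strong"`.
#' @return List of class `phenotype_grouping`: `group_a`, `group_b`,
#'   `n_a_species`, `n_b_species`.
#' @export
assign_groups <- function(classifications) {
  if (is.null(names(classifications)) || any(!nzchar(names(classifications))))
    stop("`classifications` must be named by species id")
  if (anyDuplicated(names(classifications)))
    stop("duplicate species ids")
  bad <- setdiff(unique(classifications), c("weak", "moderate", "strong"))
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  group_b <- sort(names(classifications)[classifications == "weak"])
  group_a <- sort(setdiff(names(classifications), group_b))
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("phenotype score undefined: both groups must be non-empty ",
         "(", length(group_a), " non-weak, ", length(group_b), " weak)")
  structure(list(group_a = group_a, group_b = group_b,
                 n_a_species = length(group_a),
                 n_b_species = length(group_b)),
            class = "phenotype_grouping")
}

#' @export
print.phenotype_grouping <- function(x, ...) {
  cat("phenotype_grouping: A (", x$n_a_species, " oxidizers): ",
      paste(x$group_a, collapse = ", "), "\n  B (", x$n_b_species,
      " weak): ", paste(x$group_b, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Phenotype score of one gene cluster
#'
#' The score contrasts a cluster's presence fraction between the two
#' phenotype groups,
#' \deqn{Score = N_{A,gene}/N_{A,species} - N_{B,gene}/N_{B,species},}
#' ranging from -1 (present only in weak oxidizers) to 1 (present only in
#' more-than-weak oxidizers). Presence is binary; paralog copies do not
#' raise the score.
#'
#' @param presence named 0/1 (or logical) vector over genomes; must cover
#'   every grouped species.
#' @param grouping an [assign_groups()] result.
#' @param cluster_id optional identifier carried into the record.
#' @return One-row data frame: `cluster_id`, `n_a_gene`, `n_b_gene`,
#'   `score`.
#' @export
phenotype_score <- function(presence, grouping, cluster_id = NA_character_) {
  stopifnot(inherits(grouping, "phenotype_grouping"))
  species <- c(grouping$group_a, grouping$group_b)
  missing <- setdiff(species, names(presence))
  if (length(missing))
    stop("presence not defined for species: ", paste(missing, collapse = ", "))
  pres <- as.integer(presence[species] > 0)
  names(pres) <- species
  n_a <- sum(pres[grouping$group_a])
  n_b <- sum(pres[grouping$group_b])
  data.frame(cluster_id = cluster_id,
             n_a_gene = n_a, n_b_gene = n_b,
             score = n_a / grouping$n_a_species - n_b / grouping$n_b_species,
             stringsAsFactors = FALSE)
}

#' Phenotype scores for every cluster of a pangenome matrix
#'
#' Binarizes the matrix, then scores every cluster against the phenotype
#' grouping. Output is sorted by descending score, ties by cluster id, so
#' perfectly phenotype-linked clusters (score 1) lead the table.
#'
#' @param m a [pangenome_matrix()] whose columns cover all grouped species.
#' @param grouping an [assign_groups()] result.
#' @return Data frame with one row per cluster: `cluster_id`, `n_a_gene`,
#'   `n_b_gene`, `score`.
#' @export
score_all_clusters <- function(m, grouping) {
  stopifnot(inherits(m, "pangenome_matrix"),
            inherits(grouping, "phenotype_grouping"))
  species <- c(grouping$group_a, grouping$group_b)
  missing <- setdiff(species, colnames(m))
  if (length(missing))
    stop("grouped species absent from matrix: ",
         paste(missing, collapse = ", "))
  b <- unclass(binarize(m))
  n_a <- rowSums(b[, grouping$group_a, drop = FALSE])
  n_b <- rowSums(b[, grouping$group_b, drop = FALSE])
  out <- data.frame(cluster_id = rownames(m),
                    n_a_gene = as.integer(n_a),
                    n_b_gene = as.integer(n_b),
                    score = n_a / grouping$n_a_species -
                            n_b / grouping$n_b_species,
                    stringsAsFactors = FALSE)
  if (nrow(out) > 0L)
    out <- out[order(-out$score, out$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
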