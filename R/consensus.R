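#' Lift per-species candidate genes to homolog clusters
#'
#' Maps each species' candidate genes onto homologous gene clusters via a
#' gene-to-cluster membership table. Genes without a cluster assignment are
#' reported separately rather than dropped silently.
#'
#' @param candidates named list (species id -> [select_candidates()]
#'   data frame).
#' @param membership data frame with columns `gene_id`, `species_id`,
#'   `cluster_id`; a gene may belong to at most one cluster.
#' @return List of class `cluster_candidates`: `table` (data frame
#'   `cluster_id`, `species_id`, `gene_id`, `direction`,
#'   `log2_fold_change`) and `unassigned` (data frame `species_id`,
#'   `gene_id`).
#' @export
genes_to_clusters <- function(candidates, membership) {
  if (!all(c("gene_id", "species_id", "cluster_id") %in% names(membership)))
    stop("membership needs columns gene_id, species_id, cluster_id")
  key <- paste(membership$species_id, membership$gene_id)
  amb <- tapply(membership$cluster_id, key, function(x) length(unique(x)))
  if (any(amb > 1L))
    stop("ambiguity error: gene(s) mapped to more than one cluster: ",
         paste(names(amb)[amb > 1L], collapse = ", "))
  rows <- list(); un <- list()
  for (sp in names(candidates)) {
    cc <- candidates[[sp]]
    if (nrow(cc) == 0L) next
    hit <- match(paste(sp, cc$gene_id), key)
    miss <- is.na(hit)
    if (any(miss))
      un[[sp]] <- data.frame(species_id = sp, gene_id = cc$gene_id[miss],
                             stringsAsFactors = FALSE)
    if (any(!miss))
      rows[[sp]] <- data.frame(cluster_id = membership$cluster_id[hit[!miss]],
                               species_id = sp,
                               gene_id = cc$gene_id[!miss],
                               direction = cc$direction[!miss],
                               log2_fold_change = cc$log2_fold_change[!miss],
                               stringsAsFactors = FALSE)
  }
  empty <- data.frame(cluster_id = character(), species_id = character(),
                      gene_id = character(), direction = character(),
                      log2_fold_change = numeric(), stringsAsFactors = FALSE)
  tab <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else empty
  unassigned <- if (length(un)) do.call(rbind, c(un, make.row.names = FALSE))
    else data.frame(species_id = character(), gene_id = character(),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$cluster_id, tab$species_id, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab, unassigned = unassigned),
            class = "cluster_candidates")
}

#' Cross-species consensus of sulfur-responsive clusters
#'
#' A cluster earns a consensus record when, in every species of
#' `species_set` where it is encoded, ALL of its member genes are
#' significantly differentially expressed beyond the fold-change cutoff.
#' Tiers: `all_species_concordant` (encoded in every species of the set,
#' all members pass, one shared direction), `all_species_discordant`
#' (encoded and passing everywhere but directions conflict), `subset`
#' (missing from at least one genome of the set but passing wherever
#' encoded).
#'
#' @param cluster_candidates a [genes_to_clusters()] result (only its
#'   membership-wide `table` is used for candidate fold changes; passing is
#'   re-derived from the DE tables so non-candidate paralogs count too).
#' @param species_set character vector of species ids to intersect over.
#' @param de_tables named list (species id -> [test_de()] result). Member
#'   genes absent from their species' table (e.g. dropped by the low-count
#'   filter) count as failing the criterion.
#' @param membership the same gene-to-cluster membership used for lifting;
#'   defines which clusters a species encodes.
#' @param fold_change_cutoff linear fold-change cutoff; default 2.
#' @return List of class `consensus_result`: `summary` (data frame
#'   `cluster_id`, `tier`, `n_species`, `species`, `direction`) and
#'   `members` (per-gene rows with species, log2FC, significance).
#' @export
consensus_clusters <- function(cluster_candidates, species_set, de_tables,
                               membership, fold_change_cutoff = 2) {
  stopifnot(inherits(cluster_candidates, "cluster_candidates"))
  missing_de <- setdiff(species_set, names(de_tables))
  if (length(missing_de))
    stop("no DE table for species: ", paste(missing_de, collapse = ", "))
  species_set <- sort(species_set)
  lcut <- log2(fold_change_cutoff)
  mem <- membership[membership$species_id %in% species_set, , drop = FALSE]
  cand_clusters <- sort(unique(cluster_candidates$table$cluster_id))
  sum_rows <- list(); mem_rows <- list()
  for (cl in cand_clusters) {
    rows <- mem[mem$cluster_id == cl, , drop = FALSE]
    present_in <- sort(unique(rows$species_id))
    if (length(present_in) == 0L) next
    info <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      de <- de_tables[[rows$species_id[i]]]
      j <- match(rows$gene_id[i], de$gene_id)
      ## a member gene absent from the DE table (e.g. removed by the
      ## low-count filter) was not testable, hence cannot pass
      data.frame(cluster_id = cl, species_id = rows$species_id[i],
                 gene_id = rows$gene_id[i],
                 log2_fold_change = if (is.na(j)) 0 else de$log2_fold_change[j],
                 significant = !is.na(j) && de$significant[j],
                 stringsAsFactors = FALSE)
    }))
    pass <- all(info$significant & abs(info$log2_fold_change) > lcut)
    if (!pass) next
    dirs <- unique(sign(info$log2_fold_change))
    tier <- if (!setequal(present_in, species_set)) "subset"
            else if (length(dirs) == 1L) "all_species_concordant"
            else "all_species_discordant"
    sum_rows[[cl]] <- data.frame(
      cluster_id = cl, tier = tier,
      n_species = length(present_in),
      species = paste(present_in, collapse = ";"),
      direction = if (length(dirs) == 1L) {
        if (dirs > 0) "up" else "down"
      } else "mixed",
      stringsAsFactors = FALSE)
    mem_rows[[cl]] <- info
  }
  empty_sum <- data.frame(cluster_id = character(), tier = character(),
                          n_species = integer(), species = character(),
                          direction = character(), stringsAsFactors = FALSE)
  summary <- if (length(sum_rows))
    do.call(rbind, c(sum_rows, make.row.names = FALSE)) else empty_sum
  members <- if (length(mem_rows))
    do.call(rbind, c(mem_rows, make.row.names = FALSE)) else NULL
  structure(list(summary = summary, members = members),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  tab <- table(factor(x$summary$tier,
                      levels = c("all_species_concordant",
                                 "all_species_discordant", "subset")))
  cat("consensus_result:", nrow(x$summary), "clusters (",
      tab[1], "concordant,", tab[2], "discordant,", tab[3], "subset )\n")
  invisible(x)
}
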