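#' Achievable phenotype-score grid
#'
#' Scores realizable as `k/n_a - m/n_b` with integer presence counts.
#'
#' @param n_a,n_b group sizes.
#' @return Sorted unique numeric vector of achievable scores.
#' @export
achievable_scores <- function(n_a, n_b) {
  sort(unique(as.vector(outer(0:n_a / n_a, 0:n_b / n_b, `-`))))
}

#' Generate a synthetic pangenome matrix with planted phenotype-linked clusters
#'
#' Emulates a presence/absence pangenome over two phenotype groups:
#' planted clusters realize exact target phenotype scores (presence in the
#' first `k` group-A and first `m` group-B genomes, choosing the
#' achievable `(k, m)` with the largest `k`); background clusters draw
#' presence uniformly (probability 1/2 per cell). Present cells acquire
#' extra paralog copies geometrically at `paralog_rate`.
#'
#' @param n_species_a,n_species_b genomes per phenotype group (defaults:
#'   8 more-than-weak and 2 weak oxidizers, the benchmarked panel size).
#' @param n_clusters total clusters including planted ones.
#' @param planted data frame with columns `target_score`, `n` (clusters
#'   per score), or `NULL`.
#' @param paralog_rate probability weight of extra copies in present
#'   cells.
#' @param seed integer seed; fully determines the output.
#' @return List: `matrix` ([pangenome_matrix()]), `grouping`
#'   ([assign_groups()] result over the synthetic genomes), `truth`
#'   (data frame `cluster_id`, `target_score`), `seed`.
#' @export
gen_pangenome <- function(n_species_a = 8, n_species_b = 2,
                          n_clusters = 100, planted = NULL,
                          paralog_rate = 0.05, seed = 1) {
  stopifnot(n_species_a >= 1, n_species_b >= 1)
  set.seed(seed)
  genomes_a <- sprintf("spA%02d", seq_len(n_species_a))
  genomes_b <- sprintf("spB%02d", seq_len(n_species_b))
  genomes <- c(genomes_a, genomes_b)
  n_planted <- if (is.null(planted)) 0L else sum(planted$n)
  if (n_planted > n_clusters)
    stop("more planted clusters than n_clusters")
  m <- matrix(0L, n_clusters, length(genomes),
              dimnames = list(sprintf("CL%04d", seq_len(n_clusters)), genomes))
  truth <- data.frame(cluster_id = character(), target_score = numeric(),
                      stringsAsFactors = FALSE)
  row <- 1L
  if (n_planted > 0L) {
    grid <- expand.grid(k = 0:n_species_a, mm = 0:n_species_b)
    grid$score <- grid$k / n_species_a - grid$mm / n_species_b
    for (i in seq_len(nrow(planted))) {
      tgt <- planted$target_score[i]
      hit <- grid[abs(grid$score - tgt) < 1e-9, , drop = FALSE]
      if (nrow(hit) == 0L)
        stop("target score ", tgt, " not achievable; achievable grid: ",
             paste(round(achievable_scores(n_species_a, n_species_b), 4),
                   collapse = ", "))
      hit <- hit[which.max(hit$k), ]
      for (j in seq_len(planted$n[i])) {
        m[row, seq_len(hit$k)] <- 1L
        if (hit$mm > 0) m[row, n_species_a + seq_len(hit$mm)] <- 1L
        truth <- rbind(truth,
                       data.frame(cluster_id = rownames(m)[row],
                                  target_score = tgt,
                                  stringsAsFactors = FALSE))
        row <- row + 1L
      }
    }
  }
  if (row <= n_clusters) {
    bg <- matrix(stats::rbinom((n_clusters - row + 1L) * length(genomes),
                               1L, 0.5),
                 ncol = length(genomes))
    m[row:n_clusters, ] <- bg
  }
  if (paralog_rate > 0) {
    pres <- which(m > 0L)
    m[pres] <- m[pres] + stats::rgeom(length(pres), prob = 1 - paralog_rate)
  }
  cls <- stats::setNames(rep(c("moderate", "weak"),
                             c(n_species_a, n_species_b)), genomes)
  list(matrix = pangenome_matrix(m), grouping = assign_groups(cls),
       truth = truth, seed = seed)
}

#' Generate a synthetic RNA-seq count matrix with planted responders
#'
#' Gene baselines are log-normal; counts draw from a negative binomial
#' with variance `mu + dispersion * mu^2`. Planted genes have their
#' sulfur-condition means scaled by `2^log2fc`; expected column totals
#' equal the library sizes (relative-abundance parameterization, so strong
#' responders compositionally dilute the rest, as in real libraries).
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per condition (triplicate by
#'   default, matching the study design).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of the
#'   relative gene baselines.
#' @param dispersion NB dispersion (> 0).
#' @param planted data frame with columns `log2fc`, `n`, or `NULL`.
#' @param library_sizes scalar or per-sample vector of expected depths.
#' @param seed integer seed.
#' @param species_id label written into the design table.
#' @return List: `counts` (gene x sample integer matrix), `design`
#'   ([sample_design()]), `truth` (data frame `gene_id`, `true_log2fc`
#'   for planted genes), `seed`.
#' @export
gen_counts <- function(n_genes = 2000, n_replicates = 3,
                       baseline_meanlog = log(50), baseline_sdlog = 1,
                       dispersion = 0.1, planted = NULL,
                       library_sizes = 2e6, seed = 1,
                       species_id = "sp1") {
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  set.seed(seed)
  ns <- 2L * n_replicates
  lib <- rep_len(library_sizes, ns)
  genes <- sprintf("g%05d", seq_len(n_genes))
  samples <- c(sprintf("%s_no_sulfur_r%d", species_id, seq_len(n_replicates)),
               sprintf("%s_sulfur_r%d", species_id, seq_len(n_replicates)))
  cond <- rep(c("no_sulfur", "sulfur"), each = n_replicates)
  rel <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  lfc <- numeric(n_genes)
  truth <- data.frame(gene_id = character(), true_log2fc = numeric(),
                      stringsAsFactors = FALSE)
  if (!is.null(planted) && "gene_index" %in% names(planted)) {
    ## explicit placement: one row per planted gene
    if (any(planted$gene_index > n_genes)) stop("gene_index out of range")
    idx <- planted$gene_index
    lfc[idx] <- planted$log2fc
    truth <- data.frame(gene_id = genes[idx], true_log2fc = planted$log2fc,
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$gene_id), , drop = FALSE]
    rownames(truth) <- NULL
  } else if (!is.null(planted) && sum(planted$n) > 0L) {
    if (sum(planted$n) > n_genes) stop("more planted genes than n_genes")
    idx <- sample.int(n_genes, sum(planted$n))
    lfc[idx] <- rep(planted$log2fc, planted$n)
    truth <- data.frame(gene_id = genes[idx],
                        true_log2fc = lfc[idx],
                        stringsAsFactors = FALSE)
    truth <- truth[order(truth$gene_id), , drop = FALSE]
    rownames(truth) <- NULL
  }
  rel_s <- rel * 2^lfc
  p_n <- rel / sum(rel)
  p_s <- rel_s / sum(rel_s)
  mu <- cbind(outer(p_n, lib[cond == "no_sulfur"]),
              outer(p_s, lib[cond == "sulfur"]))
  counts <- matrix(stats::rnbinom(n_genes * ns, mu = mu,
                                  size = 1 / dispersion),
                   n_genes, ns, dimnames = list(genes, samples))
  design <- sample_design(data.frame(sample_id = samples,
                                     species_id = species_id,
                                     condition = cond,
                                     replicate = rep(seq_len(n_replicates), 2),
                                     stringsAsFactors = FALSE))
  list(counts = counts, design = design, truth = truth, seed = seed)
}

#' Generate a random rooted binary tree with planted gain/loss histories
#'
#' The topology grows by sequential leaf attachment: starting from a
#' two-leaf tree, each new leaf attaches to a uniformly chosen existing
#' branch. Each character receives a random root state and at most
#' `events_per_character` state-flip events on distinct branches; leaf
#' states follow from the history, so the planted history is by
#' construction one admissible explanation of the leaf data (not
#' necessarily the parsimony optimum - gate recovery checks on
#' [count_parsimony_optima()]).
#'
#' @param n_leaves number of leaves (>= 2).
#' @param n_characters number of binary characters to evolve.
#' @param events_per_character maximum planted events per character.
#' @param seed integer seed.
#' @param leaf_names optional character vector of leaf names (length
#'   `n_leaves`); defaults to `L01`, `L02`, ...
#' @return List: `tree` (`phylo` with `N*` internal labels), `states`
#'   (character x leaf 0/1 matrix), `truth` (data frame `character_id`,
#'   `child_id`, `event`), `seed`.
#' @export
gen_tree_history <- function(n_leaves = 20, n_characters = 10,
                             events_per_character = 2, seed = 1,
                             leaf_names = NULL) {
  stopifnot(n_leaves >= 2, n_characters >= 1, events_per_character >= 0)
  set.seed(seed)
  leaves <- if (is.null(leaf_names)) sprintf("L%02d", seq_len(n_leaves))
            else { stopifnot(length(leaf_names) == n_leaves); leaf_names }
  ## sequential attachment on Newick subtree strings
  sub <- leaves[1:2]
  if (n_leaves > 2) {
    for (k in 3:n_leaves) {
      ## attachable points = current subtree strings within the forest of
      ## the (implicit) root; represent tree as nested strings
      tree_str <- paste0("(", sub[1], ",", sub[2], ")")
      tr <- ape::read.tree(text = paste0(tree_str, ";"))
      edge_n <- nrow(tr$edge)
      target <- sample.int(edge_n, 1L)
      ## rebuild by splitting the chosen branch: attach at a random
      ## existing branch via ape::bind.tree equivalent string surgery is
      ## brittle; use edge-level attachment instead
      sub <- attach_leaf(tr, target, leaves[k])
    }
    tree <- ape::read.tree(text = paste0("(", sub[1], ",", sub[2], ");"))
  } else {
    tree <- ape::read.tree(text = paste0("(", leaves[1], ",", leaves[2], ");"))
  }
  tree$node.label <- paste0("N", seq_len(tree$Nnode))
  nedge <- nrow(tree$edge)
  if (events_per_character > nedge)
    stop("more events requested than branches (", nedge, ")")
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  ntip <- length(tree$tip.label)
  ids <- node_ids(tree)
  states <- matrix(0L, n_characters, ntip,
                   dimnames = list(sprintf("char%03d", seq_len(n_characters)),
                                   tree$tip.label))
  truth <- list()
  for (ch in seq_len(n_characters)) {
    root_state <- stats::rbinom(1L, 1L, 0.5)
    n_ev <- if (events_per_character == 0L) 0L
            else sample.int(events_per_character, 1L)
    ev_edges <- if (n_ev > 0L) sort(sample.int(nedge, n_ev)) else integer(0)
    st <- integer(ntip + tree$Nnode)
    st[ntip + 1L] <- root_state
    ev_rows <- list()
    for (e in seq_len(nrow(pre))) {
      u <- pre[e, 1L]; v <- pre[e, 2L]
      if (e %in% ev_edges) {
        st[v] <- 1L - st[u]
        ev_rows[[length(ev_rows) + 1L]] <-
          data.frame(character_id = rownames(states)[ch],
                     child_id = ids[v],
                     event = if (st[v] == 1L) "gain" else "loss",
                     stringsAsFactors = FALSE)
      } else st[v] <- st[u]
    }
    states[ch, ] <- st[seq_len(ntip)]
    if (length(ev_rows)) truth[[ch]] <- do.call(rbind, ev_rows)
  }
  truth <- if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE))
    else data.frame(character_id = character(), child_id = character(),
                    event = character(), stringsAsFactors = FALSE)
  list(tree = tree, states = states, truth = truth, seed = seed)
}

## attach a new leaf to branch `target` of `tr`, returning the two root
## child subtree strings of the new tree
attach_leaf <- function(tr, target, leaf) {
  edge <- tr$edge
  ntip <- length(tr$tip.label)
  subtree_str <- function(node) {
    if (node <= ntip) return(tr$tip.label[node])
    kids <- edge[edge[, 1L] == node, 2L]
    paste0("(", paste(vapply(kids, subtree_str, ""), collapse = ","), ")")
  }
  child <- edge[target, 2L]
  ## replace subtree under `child` with (subtree, leaf)
  rebuilt <- function(node) {
    if (node == child)
      return(paste0("(", subtree_str(node), ",", leaf, ")"))
    if (node <= ntip) return(tr$tip.label[node])
    kids <- edge[edge[, 1L] == node, 2L]
    paste0("(", paste(vapply(kids, rebuilt, ""), collapse = ","), ")")
  }
  root <- ntip + 1L
  kids <- edge[edge[, 1L] == root, 2L]
  vapply(kids, rebuilt, "")
}

#' Generate synthetic sulfate-assay standards
#'
#' Evenly spaced sulfate standards over 0-10 mM with Gaussian absorbance
#' noise around a true line.
#'
#' @param slope,intercept true line (absorbance per mM; absorbance).
#' @param noise_sd absorbance noise SD.
#' @param n_points number of standards (>= 2).
#' @param seed integer seed.
#' @return Data frame `concentration_mM`, `absorbance` with the true
#'   parameters attached as attribute `truth`.
#' @export
gen_standard_curve <- function(slope = 0.05, intercept = 0.05,
                               noise_sd = 0.005, n_points = 11, seed = 1) {
  if (n_points < 2) stop("need >= 2 standard points")
  set.seed(seed)
  conc <- seq(0, 10, length.out = n_points)
  out <- data.frame(concentration_mM = conc,
                    absorbance = slope * conc + intercept +
                      stats::rnorm(n_points, 0, noise_sd))
  attr(out, "truth") <- list(slope = slope, intercept = intercept,
                             noise_sd = noise_sd)
  out
}

#' Generate a complete synthetic study bundle
#'
#' Composes the stage generators into one coherent dataset mirroring the
#' study layout: a 10-genome pangenome over two phenotype groups with
#' planted phenotype-score clusters, a phenotype assay table consistent
#' with the grouping, per-species sulfur / no-sulfur count matrices whose
#' genes map one-to-one onto encoded clusters, a gene-to-cluster
#' membership table, and a rooted phylogeny over the genomes. Responder
#' clusters are planted at three consensus tiers: concordant (encoded and
#' responding with one direction in every transcriptome species),
#' discordant (responding everywhere, direction flipped in one species),
#' and subset (encoded in all but one species, responding where encoded);
#' additionally a few species-private responders exercise the
#' non-consensus path.
#'
#' @param seed integer seed; determines everything.
#' @param n_clusters pangenome clusters.
#' @param transcriptome_species genomes profiled by RNA-seq (consensus is
#'   taken over all of them).
#' @param n_concordant,n_discordant,n_subset,n_private planted responder
#'   clusters per tier.
#' @param responder_log2fc magnitude of planted responses.
#' @param dispersion NB dispersion of the counts.
#' @param n_replicates replicates per condition per species.
#' @param library_size expected per-sample depth.
#' @return List with components `pangenome` (matrix, grouping, score
#'   truth), `phenotype` (assay table), `standards`, `counts` (per-species
#'   list of counts + design), `membership`, `tree`, and `truth` (planted
#'   cluster tiers and per-species responder log2FCs).
#' @export
gen_study <- function(seed = 1, n_clusters = 600,
                      transcriptome_species = c("spA01", "spA02", "spA03"),
                      n_concordant = 5, n_discordant = 3, n_subset = 3,
                      n_private = 4, responder_log2fc = 3,
                      dispersion = 0.1, n_replicates = 3,
                      library_size = 1e6) {
  pg <- gen_pangenome(n_species_a = 8, n_species_b = 2,
                      n_clusters = n_clusters,
                      planted = data.frame(
                        target_score = c(1, 0.875, -1, 0),
                        n = c(2, 2, 2, 2)),
                      paralog_rate = 0.05, seed = seed)
  m <- unclass(pg$matrix)
  spp <- transcriptome_species
  stopifnot(all(spp %in% colnames(m)))
  set.seed(seed + 211)
  ## responder clusters are drawn from the background block and forced to
  ## the presence pattern their tier requires
  n_resp <- n_concordant + n_discordant + n_subset + n_private
  bg <- setdiff(rownames(m), pg$truth$cluster_id)
  resp <- sample(bg, n_resp)
  conc <- resp[seq_len(n_concordant)]
  disc <- resp[n_concordant + seq_len(n_discordant)]
  subs <- resp[n_concordant + n_discordant + seq_len(n_subset)]
  priv <- resp[n_concordant + n_discordant + n_subset + seq_len(n_private)]
  m[c(conc, disc, priv), spp] <- 1L
  drop_sp <- sample(spp, n_subset, replace = TRUE)
  m[subs, spp] <- 1L
  m[cbind(subs, drop_sp)] <- 0L
  pg$matrix <- pangenome_matrix(m)
  ## per-cluster direction, shared across species for concordant clusters
  dir_conc <- sample(c(-1, 1), n_concordant, replace = TRUE)
  dir_disc <- sample(c(-1, 1), n_discordant, replace = TRUE)
  dir_subs <- sample(c(-1, 1), n_subset, replace = TRUE)
  flip_sp <- sample(spp, n_discordant, replace = TRUE)  # discordant species
  priv_sp <- sample(spp, n_private, replace = TRUE)
  counts <- list(); membership <- list(); responders <- list()
  for (si in seq_along(spp)) {
    sp <- spp[si]
    encoded <- rownames(m)[m[, sp] > 0L]
    genes <- paste0(sp, "|", encoded)
    lfc <- stats::setNames(numeric(length(encoded)), encoded)
    lfc[conc] <- responder_log2fc * dir_conc
    lfc[disc] <- responder_log2fc * dir_disc * ifelse(flip_sp == sp, -1, 1)
    enc_subs <- intersect(subs, encoded)
    lfc[enc_subs] <- responder_log2fc * dir_subs[match(enc_subs, subs)]
    mine <- priv[priv_sp == sp]
    lfc[mine] <- responder_log2fc
    lfc <- lfc[encoded]
    planted_idx <- which(lfc != 0)
    gc <- gen_counts(n_genes = length(encoded), n_replicates = n_replicates,
                     dispersion = dispersion,
                     planted = data.frame(gene_index = planted_idx,
                                          log2fc = unname(lfc[planted_idx])),
                     library_sizes = library_size,
                     seed = seed + 97L * si, species_id = sp)
    rownames(gc$counts) <- genes
    gc$truth$gene_id <- paste0(sp, "|",
                               encoded[match(gc$truth$gene_id,
                                             sprintf("g%05d",
                                                     seq_along(encoded)))])
    counts[[sp]] <- gc
    membership[[sp]] <- data.frame(gene_id = genes, species_id = sp,
                                   cluster_id = encoded,
                                   stringsAsFactors = FALSE)
    responders[[sp]] <- data.frame(species_id = sp,
                                   cluster_id = encoded[planted_idx],
                                   gene_id = genes[planted_idx],
                                   true_log2fc = unname(lfc[planted_idx]),
                                   stringsAsFactors = FALSE)
  }
  membership <- do.call(rbind, c(membership, make.row.names = FALSE))
  responders <- do.call(rbind, c(responders, make.row.names = FALSE))
  ## phenotype assay table consistent with the grouping: strong, moderate
  ## and weak archetypes with mild seeded jitter
  set.seed(seed + 409)
  sp_all <- colnames(m)
  grp_a <- pg$grouping$group_a
  strong <- grp_a[1:2]
  sulfate <- stats::setNames(numeric(length(sp_all)), sp_all)
  od <- stats::setNames(numeric(length(sp_all)), sp_all)
  for (s in sp_all) {
    if (s %in% strong) { base <- 30; odv <- 0.45 }
    else if (s %in% grp_a) { base <- 10; odv <- 0.5 }
    else { base <- 0.6; odv <- 0.6 }
    sulfate[s] <- max(0, base * (1 + stats::rnorm(1, 0, 0.05)))
    od[s] <- odv * (1 + stats::rnorm(1, 0, 0.05))
  }
  phenotype <- data.frame(species_id = sp_all, sulfate_mM = unname(sulfate),
                          od600 = unname(od), stringsAsFactors = FALSE)
  standards <- gen_standard_curve(seed = seed + 613)
  th <- gen_tree_history(n_leaves = length(sp_all), n_characters = 1,
                         events_per_character = 0, seed = seed + 811,
                         leaf_names = sample(sp_all))
  list(pangenome = pg, phenotype = phenotype, standards = standards,
       counts = counts, membership = membership, tree = th$tree,
       truth = list(scores = pg$truth,
                    concordant_clusters = sort(conc),
                    discordant_clusters = sort(disc),
                    subset_clusters = sort(subs),
                    private_clusters = sort(priv),
                    responders = responders),
       seed = seed)
}
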