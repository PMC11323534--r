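write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write a synthetic study bundle to disk as pipeline inputs
#'
#' Materializes a [gen_study()] bundle in the TSV/Newick formats the
#' pipeline reads, plus the ground-truth tables for recovery scoring.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed passed to [gen_study()].
#' @param ... further arguments to [gen_study()].
#' @return Invisibly, a named list of the written file paths.
#' @export
simulate_inputs <- function(dir, seed = 1, ...) {
  study <- gen_study(seed = seed, ...)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    pangenome = file.path(dir, "pangenome.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    standards = file.path(dir, "standards.tsv"),
    membership = file.path(dir, "membership.tsv"),
    tree = file.path(dir, "tree.nwk"))
  write_pangenome_matrix(study$pangenome$matrix, paths$pangenome)
  write_tsv(study$phenotype, paths$phenotype)
  write_tsv(study$standards, paths$standards)
  write_tsv(study$membership, paths$membership)
  write_newick(study$tree, paths$tree)
  paths$counts <- list(); paths$design <- list()
  for (sp in names(study$counts)) {
    cp <- file.path(dir, paste0("counts_", sp, ".tsv"))
    dp <- file.path(dir, paste0("design_", sp, ".tsv"))
    cnt <- study$counts[[sp]]$counts
    df <- data.frame(gene_id = rownames(cnt), cnt, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write_tsv(df, cp)
    write_tsv(as.data.frame(study$counts[[sp]]$design), dp)
    paths$counts[[sp]] <- cp
    paths$design[[sp]] <- dp
  }
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_tsv(study$truth$scores, file.path(truth_dir, "planted_scores.tsv"))
  write_tsv(study$truth$responders,
            file.path(truth_dir, "planted_responders.tsv"))
  write_tsv(data.frame(cluster_id = study$truth$concordant_clusters),
            file.path(truth_dir, "planted_concordant.tsv"))
  invisible(paths)
}

#' Default pipeline configuration
#'
#' Returns the full default configuration; callers override fields, and
#' [run_pipeline()] validates the merged result before any stage runs.
#'
#' @return Named list of configuration defaults.
#' @export
pipeline_defaults <- function() {
  list(
    pangenome = NULL, phenotype = NULL, standards = NULL,
    counts = NULL, design = NULL, membership = NULL, tree = NULL,
    outdir = NULL, seed = 1,
    stages = c("phenotype", "de", "select", "consensus", "gainloss"),
    weak_max = 1, strong_min = 20, strong_specific_min = 30,
    alpha = 0.05, fold_change_cutoff = 2, r_cutoff = 0.5,
    min_cpm = 1, min_samples = 2, pca_log2 = FALSE, standardize = FALSE,
    gain_cost = 2, loss_cost = 1,
    species_set = NULL)
}

validate_config <- function(config) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$outdir)) stop("config error: outdir is required")
  bad <- setdiff(cfg$stages,
                 c("phenotype", "de", "select", "consensus", "gainloss"))
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  need_file <- function(key, stage) {
    p <- cfg[[key]]
    if (is.null(p))
      stop("config error: stage '", stage, "' requires `", key, "`")
    missing <- unlist(p)[!file.exists(unlist(p))]
    if (length(missing))
      stop("config error: file(s) not found for `", key, "`: ",
           paste(missing, collapse = ", "))
  }
  if ("phenotype" %in% cfg$stages) {
    need_file("pangenome", "phenotype"); need_file("phenotype", "phenotype")
  }
  if (any(c("de", "select", "consensus") %in% cfg$stages)) {
    need_file("counts", "de"); need_file("design", "de")
  }
  if ("consensus" %in% cfg$stages) need_file("membership", "consensus")
  if ("gainloss" %in% cfg$stages) {
    need_file("pangenome", "gainloss"); need_file("tree", "gainloss")
  }
  oxidizer_thresholds(cfg$weak_max, cfg$strong_min, cfg$strong_specific_min)
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must lie in (0, 1)")
  if (cfg$r_cutoff < 0 || cfg$r_cutoff > 1)
    stop("config error: r_cutoff must lie in [0, 1]")
  if (cfg$fold_change_cutoff <= 1)
    stop("config error: fold_change_cutoff must exceed 1")
  if (cfg$gain_cost <= 0 || cfg$loss_cost <= 0)
    stop("config error: gain/loss costs must be positive")
  cfg
}

stage_wrap <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: phenotype scoring over the pangenome,
#' per-species differential expression, PCA condition-axis candidate
#' selection, cross-species consensus, and gain/loss reconstruction.
#' Stage tables are written as TSV under `outdir` together with a
#' `manifest.json` recording parameters, seed, package version, and
#' per-stage record counts. Outputs are pure functions of (inputs,
#' config, seed): re-running with identical inputs is byte-identical.
#'
#' @param config named list (or path to a YAML file) overriding
#'   [pipeline_defaults()]. `counts` and `design` are named lists
#'   (species id -> path).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "sulfotrace",
                   version = as.character(utils::packageVersion("sulfotrace")),
                   seed = cfg$seed,
                   parameters = cfg[c("weak_max", "strong_min",
                                      "strong_specific_min", "alpha",
                                      "fold_change_cutoff", "r_cutoff",
                                      "min_cpm", "min_samples", "pca_log2",
                                      "standardize", "gain_cost",
                                      "loss_cost")],
                   stages = list())
  grouping <- NULL; pg <- NULL
  if (!is.null(cfg$pangenome))
    pg <- read_pangenome_matrix(cfg$pangenome)

  if ("phenotype" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    scores <- stage_wrap("phenotype", {
      ph <- read_tsv(cfg$phenotype)
      if (!"sulfate_mM" %in% names(ph)) {
        if (is.null(cfg$standards))
          stop("phenotype table lacks sulfate_mM and no standards given")
        curve <- fit_standard_curve(read_tsv(cfg$standards))
        dil <- if ("dilution_factor" %in% names(ph)) ph$dilution_factor else 1
        ph$sulfate_mM <- as.numeric(
          absorbance_to_sulfate(curve, ph$absorbance, dil))
      }
      ph$specific_production <- specific_production(ph$sulfate_mM, ph$od600)
      cls <- classify_oxidizer(ph$sulfate_mM, ph$specific_production,
                               oxidizer_thresholds(cfg$weak_max,
                                                   cfg$strong_min,
                                                   cfg$strong_specific_min))
      names(cls) <- ph$species_id
      grouping <- assign_groups(cls)
      write_tsv(data.frame(species_id = ph$species_id,
                           sulfate_mM = ph$sulfate_mM,
                           od600 = ph$od600,
                           specific_production = ph$specific_production,
                           oxidizer_class = unname(cls)),
                file.path(cfg$outdir, "phenotype_classes.tsv"))
      sc <- score_all_clusters(pg, grouping)
      write_tsv(sc, file.path(cfg$outdir, "phenotype_scores.tsv"))
      sc
    })
    message(sprintf("[phenotype] %d clusters scored (%.1fs)",
                    nrow(scores), proc.time()[["elapsed"]] - t0))
    manifest$stages$phenotype <- list(records = nrow(scores))
  }

  de_tables <- list(); cand_tables <- list()
  if (any(c("de", "select", "consensus") %in% cfg$stages)) {
    species <- names(cfg$counts)
    for (sp in species) {
      t0 <- proc.time()[["elapsed"]]
      stage_wrap("de", {
        cnt_df <- read_tsv(cfg$design[[sp]])
        design <- sample_design(cnt_df)
        raw <- read_tsv(cfg$counts[[sp]])
        cnt <- as.matrix(raw[, -1, drop = FALSE])
        rownames(cnt) <- raw[[1]]
        storage.mode(cnt) <- "integer"
        cnt <- filter_low_counts(cnt, cfg$min_cpm, cfg$min_samples)
        de <- test_de(cnt, design, alpha = cfg$alpha)
        write_tsv(de, file.path(cfg$outdir, paste0("de_", sp, ".tsv")))
        de_tables[[sp]] <- de
        if ("select" %in% cfg$stages) {
          cpm <- compute_cpm(cnt)
          expr <- t(cpm)
          if (isTRUE(cfg$pca_log2)) expr <- log2(expr + 1)
          pca <- run_pca(expr, standardize = isTRUE(cfg$standardize))
          labels <- stats::setNames(design$condition, design$sample_id)
          axis <- find_condition_axis(pca, labels)
          corr <- gene_axis_correlation(expr, pca$scores[, axis$dimension])
          cand <- select_candidates(de, corr,
                                    fold_change_cutoff = cfg$fold_change_cutoff,
                                    r_cutoff = cfg$r_cutoff)
          cand$species_id <- sp
          cand$selected_dimension <- axis$dimension
          write_tsv(cand,
                    file.path(cfg$outdir, paste0("candidates_", sp, ".tsv")))
          cand_tables[[sp]] <- cand
        }
      })
      message(sprintf("[de/select] %s: %d genes tested, %d candidates (%.1fs)",
                      sp, nrow(de_tables[[sp]]),
                      if (is.null(cand_tables[[sp]])) 0L
                      else nrow(cand_tables[[sp]]),
                      proc.time()[["elapsed"]] - t0))
    }
    manifest$stages$de <- list(records = sum(vapply(de_tables, nrow, 0L)))
    if ("select" %in% cfg$stages)
      manifest$stages$select <-
        list(records = sum(vapply(cand_tables, nrow, 0L)))
  }

  if ("consensus" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    cons <- stage_wrap("consensus", {
      membership <- read_tsv(cfg$membership)
      lifted <- genes_to_clusters(cand_tables, membership)
      species_set <- if (is.null(cfg$species_set)) names(cfg$counts)
                     else cfg$species_set
      cons <- consensus_clusters(lifted, species_set, de_tables, membership,
                                 fold_change_cutoff = cfg$fold_change_cutoff)
      write_tsv(cons$summary, file.path(cfg$outdir, "consensus.tsv"))
      cons
    })
    message(sprintf("[consensus] %d clusters (%.1fs)", nrow(cons$summary),
                    proc.time()[["elapsed"]] - t0))
    manifest$stages$consensus <- list(records = nrow(cons$summary))
  }

  if ("gainloss" %in% cfg$stages) {
    t0 <- proc.time()[["elapsed"]]
    nev <- stage_wrap("gainloss", {
      tree <- parse_newick(file = cfg$tree)
      b <- binarize(pg)
      missing <- setdiff(tree$tip.label, colnames(b))
      if (length(missing))
        stop("tree leaves absent from pangenome: ",
             paste(missing, collapse = ", "))
      histories <- lapply(stats::setNames(rownames(b), rownames(b)),
                          function(cl)
        sankoff_reconstruct(tree, b[cl, ], gain_cost = cfg$gain_cost,
                            loss_cost = cfg$loss_cost))
      ev <- do.call(rbind, lapply(names(histories), function(cl) {
        e <- histories[[cl]]$events
        e <- e[e$event != "none", , drop = FALSE]
        if (nrow(e) == 0L) return(NULL)
        cbind(cluster_id = cl, e)
      }))
      if (is.null(ev))
        ev <- data.frame(cluster_id = character(), parent_id = character(),
                         child_id = character(), event = character())
      write_tsv(ev, file.path(cfg$outdir, "gainloss_events.tsv"))
      write_tsv(summarize_events(histories),
                file.path(cfg$outdir, "gainloss_node_summary.tsv"))
      nrow(ev)
    })
    message(sprintf("[gainloss] %d events (%.1fs)", nev,
                    proc.time()[["elapsed"]] - t0))
    manifest$stages$gainloss <- list(records = nev)
  }

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
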