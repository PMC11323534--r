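#' Construct a pangenome matrix
#'
#' A pangenome matrix holds per-genome copy numbers of homologous gene
#' clusters: rows are clusters, columns are genomes, cells are non-negative
#' integer counts (0 = absent, >1 = in-paralogs).
#'
#' @param counts integer matrix, clusters in rows, genomes in columns, with
#'   row and column names set to cluster and genome identifiers.
#' @return An object of class `pangenome_matrix` (an integer matrix with
#'   validated dimnames).
#' @export
pangenome_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("`counts` must have row (cluster) and column (genome) names")
  if (is.null(dimnames(counts)))
    dimnames(counts) <- list(character(0), character(0))
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (is.null(colnames(counts))) colnames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cluster ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate genome ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (any(is.na(counts))) stop("missing values in copy-number matrix")
  if (any(counts < 0)) stop("negative copy numbers")
  if (any(counts != round(counts))) stop("non-integer copy numbers")
  storage.mode(counts) <- "integer"
  class(counts) <- c("pangenome_matrix", "matrix", "array")
  counts
}

#' @export
print.pangenome_matrix <- function(x, ...) {
  cat("pangenome_matrix:", nrow(x), "clusters x", ncol(x), "genomes\n")
  cat("  occupancy:", round(mean(x > 0), 3),
      " multi-copy cells:", sum(x > 1), "\n")
  invisible(x)
}

#' Read a pangenome matrix from TSV
#'
#' Expects a tab-delimited file with a header: the first column carries row
#' identifiers and remaining columns carry counts. The GET_HOMOLOGUES
#' `pangenome_matrix_t0.tab` layout (genomes as rows) is accepted through
#' `orientation = "genomes_as_rows"`; the returned matrix is always
#' normalized to clusters x genomes.
#'
#' @param path path to a tab-separated file.
#' @param orientation `"clusters_as_rows"` (default) or `"genomes_as_rows"`.
#' @return A [pangenome_matrix()].
#' @export
read_pangenome_matrix <- function(path,
                                  orientation = c("clusters_as_rows",
                                                  "genomes_as_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L)
    stop("parse error: ", path, " has no data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (length(unique(nfield)) != 1L)
    stop("parse error: ragged rows in ", path,
         " (field counts ", paste(unique(nfield), collapse = "/"), ")")
  header <- fields[[1L]][-1L]
  row_ids <- vapply(fields[-1L], `[[`, "", 1L)
  cells <- do.call(rbind, lapply(fields[-1L], function(f) f[-1L]))
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  if (any(is.na(num)))
    stop("value error: non-numeric cell(s) in ", path)
  if (any(num != round(num)))
    stop("value error: non-integer cell(s) in ", path)
  dimnames(num) <- list(row_ids, header)
  if (orientation == "genomes_as_rows") num <- t(num)
  pangenome_matrix(num)
}

#' Write a pangenome matrix to TSV
#'
#' Inverse of [read_pangenome_matrix()] in its default orientation.
#'
#' @param m a [pangenome_matrix()].
#' @param path output file path.
#' @param id_column name for the leading identifier column.
#' @export
write_pangenome_matrix <- function(m, path, id_column = "cluster_id") {
  df <- data.frame(rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reduce a pangenome matrix to presence/absence
#'
#' Copy numbers are clamped to presence (1) or absence (0). Downstream
#' phenotype scoring and gain/loss reconstruction operate on presence only,
#' so paralog counts never leak into scores.
#'
#' @param m a [pangenome_matrix()].
#' @return A [pangenome_matrix()] with all cells in \{0, 1\}.
#' @export
binarize <- function(m) {
  stopifnot(inherits(m, "pangenome_matrix"))
  b <- unclass(m)
  b[b > 0L] <- 1L
  pangenome_matrix(b)
}

#' Cross-map clusters between two pangenome databases by reference protein
#'
#' Each homolog cluster is represented by one reference protein. A cluster
#' in database A is paired with the cluster of database B that contains A's
#' reference protein (by default, B's own reference ids stand in for its
#' membership; supply `members_b` to match against full membership).
#'
#' @param clusters_a,clusters_b data frames with columns `cluster_id` and
#'   `reference_protein_id` (one row per cluster; reference ids unique
#'   within each database).
#' @param members_b optional data frame with columns `protein_id`,
#'   `cluster_id` giving the full membership of database B.
#' @return A list of class `cluster_mapping`: `pairs` (data frame
#'   `cluster_a`, `cluster_b`), `unmapped_a`, `unmapped_b`.
#' @export
map_clusters_by_reference <- function(clusters_a, clusters_b,
                                      members_b = NULL) {
  for (nm in c("clusters_a", "clusters_b")) {
    cl <- get(nm)
    if (!all(c("cluster_id", "reference_protein_id") %in% names(cl)))
      stop(nm, " needs columns cluster_id, reference_protein_id")
    if (anyDuplicated(cl$reference_protein_id))
      stop("reference protein id not unique within ", nm, ": ",
           paste(unique(cl$reference_protein_id[
             duplicated(cl$reference_protein_id)]), collapse = ", "))
  }
  if (is.null(members_b)) {
    members_b <- data.frame(protein_id = clusters_b$reference_protein_id,
                            cluster_id = clusters_b$cluster_id,
                            stringsAsFactors = FALSE)
  }
  amb <- tapply(members_b$cluster_id, members_b$protein_id,
                function(x) length(unique(x)))
  if (any(amb > 1L))
    stop("ambiguity error: protein(s) in more than one cluster of B: ",
         paste(names(amb)[amb > 1L], collapse = ", "))
  hit <- match(clusters_a$reference_protein_id, members_b$protein_id)
  pairs <- data.frame(cluster_a = clusters_a$cluster_id[!is.na(hit)],
                      cluster_b = members_b$cluster_id[hit[!is.na(hit)]],
                      stringsAsFactors = FALSE)
  if (anyDuplicated(pairs$cluster_b))
    stop("ambiguity error: cluster(s) of B matched by several A references: ",
         paste(unique(pairs$cluster_b[duplicated(pairs$cluster_b)]),
               collapse = ", "))
  structure(list(pairs = pairs,
                 unmapped_a = clusters_a$cluster_id[is.na(hit)],
                 unmapped_b = setdiff(clusters_b$cluster_id, pairs$cluster_b)),
            class = "cluster_mapping")
}

#' @export
print.cluster_mapping <- function(x, ...) {
  cat("cluster_mapping:", nrow(x$pairs), "pairs,",
      length(x$unmapped_a), "unmapped in A,",
      length(x$unmapped_b), "unmapped in B\n")
  invisible(x)
}

#' Consensus annotation across annotation sources
#'
#' Deterministic reconciliation of per-source functional annotations for a
#' cluster: whitespace- and case-normalized majority vote, ties broken by
#' the stated source priority, and `"hypothetical protein"` when every
#' source is absent. Invariant to the ordering of `annotations` given a
#' fixed `priority`.
#'
#' @param annotations named character vector of annotation strings, one per
#'   source; `NA` or `""` marks an absent annotation.
#' @param priority character vector ordering the source names from most to
#'   least trusted. Sources absent from `priority` rank last.
#' @return A single annotation string (whitespace-normalized; case taken
#'   from the most trusted source voting for the winning string).
#' @export
reconcile_annotations <- function(annotations, priority) {
  if (length(priority) == 0L) stop("config error: empty priority list")
  if (is.null(names(annotations)) || any(!nzchar(names(annotations))))
    stop("`annotations` must be named by source")
  squeeze <- function(x) gsub("\\s+", " ", trimws(x))
  ann <- squeeze(annotations)
  ok <- !is.na(ann) & nzchar(ann)
  if (!any(ok)) return("hypothetical protein")
  ann <- ann[ok]
  key <- tolower(ann)
  rank <- match(names(ann), priority)
  rank[is.na(rank)] <- length(priority) + 1L
  tab <- tapply(seq_along(key), key, function(i)
    c(votes = length(i), best = min(rank[i]), idx = i[which.min(rank[i])]))
  tab <- do.call(rbind, tab)
  win <- order(-tab[, "votes"], tab[, "best"])[1L]
  unname(ann[tab[win, "idx"]])
}
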