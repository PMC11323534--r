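make_matrix <- function(counts, clusters, genomes) {
  pangenome_matrix(matrix(as.integer(counts), length(clusters),
                          length(genomes),
                          dimnames = list(clusters, genomes)))
}

test_that("TSV round trip preserves the matrix, including a 1x1 case", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  m1 <- make_matrix(2, "c1", "g1")
  write_pangenome_matrix(m1, tmp)
  expect_equal(read_pangenome_matrix(tmp), m1)

  set.seed(42)
  m <- make_matrix(rpois(60, 1), sprintf("c%02d", 1:10), sprintf("g%d", 1:6))
  write_pangenome_matrix(m, tmp)
  expect_equal(read_pangenome_matrix(tmp), m)
})

test_that("transposed (genomes-as-rows) orientation is normalized", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  m <- make_matrix(c(1, 0, 2, 0, 0, 3), c("c1", "c2"), c("gA", "gB", "gC"))
  df <- data.frame(genome = colnames(m), t(unclass(m)), check.names = FALSE)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_pangenome_matrix(tmp, orientation = "genomes_as_rows"), m)
})

test_that("malformed matrix files are rejected with clear errors", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tmp)
  expect_error(read_pangenome_matrix(tmp), "no data rows")

  writeLines(c("id\tg1\tg2", "c1\t1\t2", "c2\t1"), tmp)
  expect_error(read_pangenome_matrix(tmp), "ragged")

  writeLines(c("id\tg1", "c1\t1.5"), tmp)
  expect_error(read_pangenome_matrix(tmp), "non-integer")

  writeLines(c("id\tg1", "c1\tx"), tmp)
  expect_error(read_pangenome_matrix(tmp), "non-numeric")

  writeLines(c("id\tg1", "c1\t1", "c1\t2"), tmp)
  expect_error(read_pangenome_matrix(tmp), "duplicate cluster")

  writeLines(c("id\tg1\tg1", "c1\t1\t2"), tmp)
  expect_error(read_pangenome_matrix(tmp), "duplicate genome")
})

test_that("constructor enforces non-negative integer counts", {
  expect_error(make_matrix(-1, "c1", "g1"), "negative")
  m <- matrix(1, 1, 1, dimnames = list("c1", "g1"))
  expect_error(pangenome_matrix(m * 1.5), "non-integer")
  expect_error(pangenome_matrix(unname(m)), "names")
})

test_that("binarize clamps to presence, is idempotent, keeps ordering", {
  set.seed(7)
  for (i in 1:5) {
    m <- make_matrix(rpois(40, 1.2), sprintf("c%d", 1:8), sprintf("g%d", 1:5))
    b <- binarize(m)
    expect_true(all(unclass(b) %in% 0:1))
    expect_true(all(unclass(b) <= unclass(m)))  # never increases a cell
    expect_equal(binarize(b), b)
    expect_identical(dimnames(b), dimnames(m))
  }
  expect_equal(unclass(binarize(make_matrix(c(3, 0), c("a", "b"), "g")))[, 1],
               c(a = 1L, b = 0L))
})

ref_df <- function(ids, refs) {
  data.frame(cluster_id = ids, reference_protein_id = refs,
             stringsAsFactors = FALSE)
}

test_that("cluster cross-mapping pairs by reference protein", {
  a <- ref_df(c("A1", "A2"), c("p1", "p2"))
  b <- ref_df(c("B1", "B2"), c("p1", "p2"))
  mp <- map_clusters_by_reference(a, b)
  expect_equal(mp$pairs$cluster_b[match(c("A1", "A2"), mp$pairs$cluster_a)],
               c("B1", "B2"))
  expect_length(mp$unmapped_a, 0)
  expect_length(mp$unmapped_b, 0)

  # A reference absent from B lands in unmapped_a; B clusters never hit
  # land in unmapped_b
  a2 <- ref_df(c("A1", "A3"), c("p1", "p9"))
  mp2 <- map_clusters_by_reference(a2, b)
  expect_equal(mp2$unmapped_a, "A3")
  expect_equal(mp2$unmapped_b, "B2")
})

test_that("cross-mapping is symmetric and recovers a planted mapping", {
  set.seed(3)
  n <- 12
  a <- ref_df(sprintf("A%02d", 1:n), sprintf("prot%02d", 1:n))
  perm <- sample(n)
  b <- ref_df(sprintf("B%02d", 1:n), sprintf("prot%02d", perm))
  mp <- map_clusters_by_reference(a, b)
  # planted truth: A_i pairs with the B cluster holding prot_i
  expect_equal(mp$pairs$cluster_b[match(a$cluster_id, mp$pairs$cluster_a)],
               b$cluster_id[match(1:n, perm)])
  rev <- map_clusters_by_reference(b, a)
  swapped <- data.frame(cluster_a = rev$pairs$cluster_b,
                        cluster_b = rev$pairs$cluster_a,
                        stringsAsFactors = FALSE)
  expect_equal(swapped[order(swapped$cluster_a), ],
               mp$pairs[order(mp$pairs$cluster_a), ],
               ignore_attr = TRUE)
})

test_that("ambiguous membership raises an error naming the protein", {
  a <- ref_df("A1", "p1")
  b <- ref_df(c("B1", "B2"), c("x1", "x2"))
  members <- data.frame(protein_id = c("p1", "p1"),
                        cluster_id = c("B1", "B2"))
  expect_error(map_clusters_by_reference(a, b, members), "ambiguity.*p1")
})

test_that("annotation consensus: unanimity, majority, and tie by priority", {
  pr <- c("ncbi", "kegg", "eggnog")
  expect_equal(reconcile_annotations(
    c(ncbi = "tetrathionate hydrolase", kegg = "tetrathionate  hydrolase",
      eggnog = "Tetrathionate hydrolase"), pr),
    "tetrathionate hydrolase")
  expect_equal(reconcile_annotations(
    c(ncbi = "sulfur oxygenase", kegg = "hydrolase", eggnog = "hydrolase"),
    pr), "hydrolase")
  # every 2-source tie permutation tracks the priority order
  for (p in list(c("s1", "s2"), c("s2", "s1"))) {
    for (ord in list(c(1, 2), c(2, 1))) {
      ann <- c(s1 = "alpha protein", s2 = "beta protein")[ord]
      expect_equal(reconcile_annotations(ann, p),
                   unname(c(s1 = "alpha protein",
                            s2 = "beta protein")[p[1]]),
                   label = paste("priority", paste(p, collapse = ">")))
    }
  }
})

test_that("annotation consensus ignores source ordering and handles absence", {
  pr <- c("a", "b", "c")
  ann <- c(a = "x", b = "y", c = "y")
  expect_equal(reconcile_annotations(ann, pr),
               reconcile_annotations(rev(ann), pr))
  expect_equal(reconcile_annotations(c(a = NA, b = "", c = NA), pr),
               "hypothetical protein")
  expect_error(reconcile_annotations(c(a = "x"), character(0)),
               "config error")
})
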