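test_that("standard-curve fit matches the closed-form least-squares oracle", {
  conc <- seq(0, 10, length.out = 11)
  exact <- data.frame(concentration_mM = conc,
                      absorbance = 0.05 * conc + 0.1)
  cv <- fit_standard_curve(exact)
  expect_equal(cv$slope, 0.05)
  expect_equal(cv$intercept, 0.1)
  expect_equal(cv$r_squared, 1)

  set.seed(5)
  noisy <- data.frame(concentration_mM = conc,
                      absorbance = 0.04 * conc + 0.08 + rnorm(11, 0, 0.01))
  cv2 <- fit_standard_curve(noisy)
  orc <- ols_oracle(noisy$concentration_mM, noisy$absorbance)
  expect_equal(cv2$slope, orc$slope, tolerance = 1e-10)
  expect_equal(cv2$intercept, orc$intercept, tolerance = 1e-10)
  expect_equal(cv2$r_squared, orc$r_squared, tolerance = 1e-10)

  expect_error(fit_standard_curve(exact[1, ]), "fit error")
  expect_error(fit_standard_curve(data.frame(concentration_mM = c(2, 2),
                                             absorbance = c(0.1, 0.2))),
               "fit error")
})

test_that("absorbance converts to sulfate with dilution, clamping, inversion", {
  cv <- fit_standard_curve(data.frame(concentration_mM = 0:10,
                                      absorbance = 0.05 * 0:10 + 0.1))
  expect_equal(as.numeric(absorbance_to_sulfate(cv, 0.35, 2)), 10)
  expect_equal(as.numeric(absorbance_to_sulfate(cv, 0.1)), 0)
  expect_warning(res <- absorbance_to_sulfate(cv, 0.05), "clamped")
  expect_equal(as.numeric(res), 0)
  expect_true(attr(res, "clamped"))
  # round trip concentration -> absorbance -> concentration
  c0 <- c(0, 1.7, 6.3, 10)
  expect_equal(as.numeric(absorbance_to_sulfate(cv, 0.05 * c0 + 0.1)), c0)
})

test_that("specific production is the sulfate / OD ratio", {
  expect_equal(specific_production(10, 0.5), 20)
  expect_equal(specific_production(0, 1), 0)
  set.seed(2)
  s <- runif(20, 0, 30); o <- runif(20, 0.1, 1)
  expect_equal(specific_production(s, o), s / o)
  expect_error(specific_production(1, 0), "positive")
})

test_that("oxidizer classes follow total sulfate and the specific floor", {
  # at or below 1 mM after 72 h -> weak, regardless of specific production
  expect_equal(classify_oxidizer(0.8, 50), "weak")
  expect_equal(classify_oxidizer(0, 0), "weak")
  expect_equal(classify_oxidizer(1, 100), "weak")
  # high total but low cell-density-normalized production is demoted from
  # strong (the high-growth, inefficient-oxidation pattern)
  expect_equal(classify_oxidizer(21.6, 5), "moderate")
  expect_equal(classify_oxidizer(30, 60), "strong")
  expect_equal(classify_oxidizer(10, 60), "moderate")
  expect_error(oxidizer_thresholds(weak_max = 25, strong_min = 20),
               "config error")
})

test_that("group assignment splits weak from more-than-weak species", {
  cls <- c(a1 = "strong", a2 = "moderate", a3 = "moderate", a4 = "moderate",
           a5 = "moderate", a6 = "moderate", a7 = "moderate", a8 = "strong",
           b1 = "weak", b2 = "weak")
  g <- assign_groups(cls)
  expect_equal(g$n_a_species, 8)
  expect_equal(g$n_b_species, 2)
  expect_setequal(g$group_b, c("b1", "b2"))
  # permutation invariance
  g2 <- assign_groups(cls[sample(names(cls))])
  expect_equal(g2, g)
  expect_error(assign_groups(c(x = "weak", y = "weak")), "non-empty")
  expect_error(assign_groups(c(x = "strong", y = "moderate")), "non-empty")
})

grouping_8_2 <- function() {
  assign_groups(c(setNames(rep("moderate", 8), paste0("A", 1:8)),
                  setNames(rep("weak", 2), paste0("B", 1:2))))
}

test_that("phenotype score reproduces the canonical presence patterns", {
  g <- grouping_8_2()
  pres <- function(a, b) setNames(c(rep(1, a), rep(0, 8 - a),
                                    rep(1, b), rep(0, 2 - b)),
                                  c(paste0("A", 1:8), paste0("B", 1:2)))
  expect_equal(phenotype_score(pres(8, 0), g)$score, 1.00)
  expect_equal(phenotype_score(pres(7, 0), g)$score, 0.875)
  expect_equal(phenotype_score(pres(0, 2), g)$score, -1.00)
  expect_equal(phenotype_score(pres(8, 2), g)$score, 0)
  expect_error(phenotype_score(pres(8, 2)[-1], g), "A1")
})

test_that("score table is sorted and bounded; matrix scoring composes", {
  g <- grouping_8_2()
  m <- matrix(0L, 4, 10,
              dimnames = list(paste0("cl", 1:4),
                              c(paste0("A", 1:8), paste0("B", 1:2))))
  m[1, 1:8] <- 1L          # 1.00
  m[2, 1:7] <- 1L          # 0.875
  m[3, ] <- 1L             # 0
  m[4, 9:10] <- 1L         # -1.00
  tab <- score_all_clusters(pangenome_matrix(m), g)
  expect_equal(tab$score, c(1, 0.875, 0, -1))
  expect_equal(tab$cluster_id, paste0("cl", c(1, 2, 3, 4)))

  empty <- pangenome_matrix(matrix(integer(0), 0, 10,
                                   dimnames = list(character(0),
                                                   colnames(m))))
  expect_equal(nrow(score_all_clusters(empty, g)), 0)

  set.seed(9)
  for (i in 1:5) {
    r <- matrix(rbinom(10 * 30, 2, 0.4), 30, 10,
                dimnames = list(sprintf("c%02d", 1:30), colnames(m)))
    sc <- score_all_clusters(pangenome_matrix(r), g)
    expect_true(all(sc$score >= -1 & sc$score <= 1))
    expect_true(all(diff(sc$score) <= 0))
  }
})

test_that("score antisymmetry, copy-number invariance, and monotonicity", {
  g <- grouping_8_2()
  swapped <- assign_groups(c(setNames(rep("weak", 8), paste0("A", 1:8)),
                             setNames(rep("moderate", 2), paste0("B", 1:2))))
  set.seed(31)
  m <- matrix(rbinom(10 * 20, 3, 0.3), 20, 10,
              dimnames = list(sprintf("c%02d", 1:20),
                              c(paste0("A", 1:8), paste0("B", 1:2))))
  pm <- pangenome_matrix(m)
  sc <- score_all_clusters(pm, g)
  sc_sw <- score_all_clusters(pm, swapped)
  expect_equal(sc_sw$score[match(sc$cluster_id, sc_sw$cluster_id)],
               -sc$score)
  # paralog copies beyond presence change nothing
  m2 <- m; m2[m2 > 0] <- m2[m2 > 0] + 3L
  expect_equal(score_all_clusters(pangenome_matrix(m2), g), sc)
  # adding a presence in A never decreases; in B never increases
  for (i in 1:10) {
    cl <- sample(rownames(m), 1)
    zero_a <- paste0("A", 1:8)[m[cl, paste0("A", 1:8)] == 0]
    if (length(zero_a)) {
      m3 <- m; m3[cl, zero_a[1]] <- 1L
      s3 <- score_all_clusters(pangenome_matrix(m3), g)
      expect_gte(s3$score[s3$cluster_id == cl], sc$score[sc$cluster_id == cl])
    }
    zero_b <- paste0("B", 1:2)[m[cl, paste0("B", 1:2)] == 0]
    if (length(zero_b)) {
      m4 <- m; m4[cl, zero_b[1]] <- 1L
      s4 <- score_all_clusters(pangenome_matrix(m4), g)
      expect_lte(s4$score[s4$cluster_id == cl], sc$score[sc$cluster_id == cl])
    }
  }
})
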