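test_that("phi correlations reproduce the reference 6x6 table at 4 d.p.", {
  C <- phi_correlation_matrix(table3_matrix())
  expect_equal(round(unclass(C), 4), table4_expected)
  expect_equal(C["IPR1", "IPR5"], 0.6124, tolerance = 1e-4)
  expect_equal(C["IPR2", "IPR6"], -0.6124, tolerance = 1e-4)
  expect_equal(unname(diag(unclass(C))), rep(1, 6))
  expect_lt(max(abs(C - t(unclass(C)))), 1e-12)
})

test_that("zero-variance columns follow the 0-correlation convention", {
  X <- cbind(a = c(1, 0, 1, 0), b = c(0, 0, 0, 0), c = c(1, 1, 1, 1))
  C <- phi_correlation_matrix(X)
  expect_equal(unname(unclass(C)["b", ]), c(0, 1, 0))
  expect_equal(unname(unclass(C)["c", "a"]), 0)
  expect_equal(unname(diag(unclass(C))), c(1, 1, 1))
})

test_that("single-row input is rejected", {
  expect_error(phi_correlation_matrix(matrix(c(0, 1), 1, 2)),
               class = "ipr2go_validation_error")
})

test_that("the transform reproduces the reference weighted table", {
  X <- table3_matrix()
  wt <- weighted_transform(X, phi_correlation_matrix(X), keep_weights = TRUE)
  expect_lt(max(abs(wt$values - table5_expected)), tol_4dp)

  # the worked intermediates for Protein 1 / IPR1
  d <- dplyr::filter(wt$weights, protein_id == "Protein1",
                     feature_id == "IPR1")
  expect_lt(abs(d$weight - 0.7791), tol_4dp)
  expect_lt(abs(d$group_total - 0.7418), tol_4dp)
  expect_lt(abs(d$weightsum - 0.5251), tol_4dp)

  # singleton group: Protein 3 carries only IPR6
  expect_equal(wt$values["Protein3", "IPR6"], 0.5)
  # negative group total still yields the reference ratio
  expect_lt(abs(wt$values["Protein2", "IPR4"] - 0.3750), tol_4dp)
  d2 <- dplyr::filter(wt$weights, protein_id == "Protein2",
                      feature_id == "IPR4")
  expect_lt(d2$group_total, 0)
})

test_that("per-protein group weights sum to the 0.5 group mass", {
  check_conservation <- function(X) {
    W <- weighted_transform(X, phi_correlation_matrix(X))$values
    for (i in seq_len(nrow(X))) {
      for (g in c(0, 1)) {
        members <- which(unclass(X)[i, ] == g)
        if (length(members) == 0) next
        expect_equal(sum(W[i, members]), 0.5, tolerance = 1e-9)
      }
    }
  }
  check_conservation(table3_matrix())
  withr::with_seed(31, {
    for (rep in 1:5) {
      check_conservation(random_binary_matrix(sample(4:12, 1),
                                              sample(3:8, 1), 0.4))
    }
  })
})

test_that("a protein carrying every feature forms one conserved group", {
  X <- rbind(all1 = rep(1L, 4),
             m1 = c(1L, 0L, 1L, 0L),
             m2 = c(0L, 1L, 1L, 0L))
  colnames(X) <- paste0("IPR", 1:4)
  W <- weighted_transform(X, phi_correlation_matrix(X))$values
  expect_equal(sum(W["all1", ]), 0.5, tolerance = 1e-9)
})

test_that("zero group denominators fall back to equal shares and are flagged", {
  # columns a and b are uncorrelated (phi = 0); the protein lacking both
  # splits its zero-group mass equally
  X <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  rownames(X) <- paste0("P", 1:4)
  wt <- weighted_transform(X, phi_correlation_matrix(X))
  expect_equal(unname(wt$values["P4", ]), c(0.25, 0.25))
  expect_true(wt$zero_denominator[4])
  # P1 carries both (one 2-member group); P2/P3 split into singletons
  expect_equal(wt$zero_denominator, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(unname(wt$values["P2", ]), c(0.5, 0.5))
})

test_that("transform commutes with feature permutation", {
  withr::with_seed(17, {
    X <- random_binary_matrix(10, 7, 0.4)
    perm <- sample(7)
  })
  W <- weighted_transform(X, phi_correlation_matrix(X))$values
  Wp <- weighted_transform(X[, perm], phi_correlation_matrix(X[, perm]))$values
  expect_equal(Wp, W[, perm], tolerance = 1e-12)
})

test_that("duplicating a protein row changes the transform (data-dependent)", {
  # correlations are estimated from the data, so the encoding of a row is
  # not invariant to resampling the rows: a documented non-invariance
  X <- unclass(table3_matrix())
  X2 <- rbind(X, dup = X[1, ])
  rownames(X2) <- c(rownames(X), "Protein1b")
  W1 <- weighted_transform(X, phi_correlation_matrix(X))$values
  W2 <- weighted_transform(X2, phi_correlation_matrix(X2))$values
  expect_gt(max(abs(W2["Protein1", ] - W1["Protein1", ])), 1e-4)
})

test_that("mismatched feature universes are rejected", {
  X <- table3_matrix()
  C <- phi_correlation_matrix(X)
  expect_error(weighted_transform(unclass(X)[, 1:4], C),
               class = "ipr2go_validation_error")
})

test_that("TSV round trip of correlation and weighted matrices", {
  X <- table3_matrix()
  C <- phi_correlation_matrix(X)
  wt <- weighted_transform(X, C)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(C, f)
  expect_equal(read_matrix_tsv(f), unclass(C), tolerance = 1e-12)
  write_matrix_tsv(wt, f)
  expect_equal(read_matrix_tsv(f), wt$values, tolerance = 1e-12)
})

test_that("tidy and glance views of the weighted object are consistent", {
  X <- table3_matrix()
  wt <- weighted_transform(X, phi_correlation_matrix(X))
  long <- tidy(wt)
  expect_equal(nrow(long), 30)
  expect_equal(
    long$weightsum[long$protein_id == "Protein3" & long$feature_id == "IPR6"],
    0.5)
  g <- glance(wt)
  expect_equal(g$n_proteins, 5)
  expect_equal(g$group_mass, 0.5)
})
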