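balanced_from <- function(X, y, term = "GO:0000001", seed = 1L) {
  structure(list(go_term = term,
                 protein_ids = rownames(X),
                 X = unclass(X), y = as.integer(y), seed = as.integer(seed)),
            class = "balanced_dataset")
}

null_dataset <- function(seed, n = 40, p = 25, density = 0.3) {
  withr::with_seed(seed, {
    X <- random_binary_matrix(n, p, density)
  })
  balanced_from(X, rep(c(1L, 0L), each = n / 2))
}

test_that("a perfectly separable column yields zero CV error for every learner", {
  n <- 40
  y <- rep(c(1L, 0L), each = n / 2)
  X <- cbind(signal = y, matrix(0L, n, 5))
  colnames(X) <- paste0("IPR", 1:6)
  rownames(X) <- sprintf("P%03d", 1:n)
  ds <- balanced_from(X, y)
  for (lrn in c("adaboost", "svm", "smo")) {
    for (fs in c(FALSE, TRUE)) {
      r <- crossval_error(ds, method_config(lrn, fs, FALSE, seed = 4))
      expect_equal(r$error_rate, 0, label = paste(lrn, "fs =", fs))
    }
  }
})

test_that("fold splits are stratified and seeded", {
  ds <- null_dataset(1)
  r1 <- crossval_error(ds, method_config("adaboost", seed = 9))
  r2 <- crossval_error(ds, method_config("adaboost", seed = 9))
  expect_identical(r1$fold_errors, r2$fold_errors)
  expect_equal(length(r1$fold_errors[[1]]), 10)
  expect_true(all(r1$fold_errors[[1]] >= 0 & r1$fold_errors[[1]] <= 1))
  expect_equal(r1$error_rate, mean(r1$fold_errors[[1]]))
})

test_that("too few proteins per class is a fold-infeasible error", {
  ds <- null_dataset(2, n = 16)
  expect_error(crossval_error(ds, method_config("svm")),
               class = "ipr2go_fold_infeasible")
  # but a smaller k works
  r <- crossval_error(ds, method_config("svm"), k = 4)
  expect_equal(length(r$fold_errors[[1]]), 4)
})

test_that("pooled and mean-over-folds errors agree on equal fold sizes", {
  ds <- null_dataset(3, n = 40)
  cfg <- method_config("adaboost", seed = 2)
  a <- crossval_error(ds, cfg)
  b <- crossval_error(ds, cfg, pooled = TRUE)
  expect_equal(a$error_rate, b$error_rate, tolerance = 1e-12)
})

test_that("error rates ignore protein identifier strings", {
  ds <- null_dataset(4)
  ds2 <- ds
  ds2$protein_ids <- paste0("RENAMED_", seq_along(ds$protein_ids))
  rownames(ds2$X) <- ds2$protein_ids
  for (lrn in c("adaboost", "svm")) {
    cfg <- method_config(lrn, TRUE, TRUE, seed = 6)
    expect_equal(crossval_error(ds, cfg)$error_rate,
                 crossval_error(ds2, cfg)$error_rate)
  }
})

test_that("feature selection does not hurt the margin learners on planted signal", {
  # sparse, high-dimensional scenario mirroring real annotation data; the
  # co-occurrence floor of 3 sits ~3 sd above the chance co-occurrence of a
  # background column with the 30 positives (E = 0.6), so selection screens
  # noise rather than chance hits
  errs <- list(fs = c(), nofs = c())
  for (s in 1:20) {
    syn <- generate_annotation_data(synth_config(
      n_proteins = 300, n_iprs = 300, n_go = 1, background_density = 0.02,
      n_informative_per_go = 8, assoc_strength = 0.9,
      positive_fraction = 0.1, seed = s))
    ds <- undersample(syn$ipr, syn$go[, 1], seed = s, go_term = "GO:0000001")
    for (lrn in c("svm", "smo")) {
      errs$fs <- c(errs$fs,
        crossval_error(ds, method_config(lrn, TRUE, FALSE, seed = s),
                       min_cooccur = 3)$error_rate)
      errs$nofs <- c(errs$nofs,
        crossval_error(ds, method_config(lrn, FALSE, FALSE, seed = s))$error_rate)
    }
  }
  expect_lte(mean(errs$fs), mean(errs$nofs) + 0.02)
})

test_that("leaking preprocessing into the folds is optimistically biased", {
  # pure-noise features, small n, many columns: fold-honest selection must
  # hover near chance while full-data selection peeks at held-out labels
  clean <- c(); leaky <- c()
  for (s in 1:15) {
    withr::with_seed(s, {
      X <- random_binary_matrix(40, 400, 0.15)
    })
    ds <- balanced_from(X, rep(c(1L, 0L), each = 20))
    cfg <- method_config("smo", TRUE, FALSE, seed = s)
    clean <- c(clean, crossval_error(ds, cfg, min_cooccur = 6)$error_rate)
    leaky <- c(leaky, crossval_error(ds, cfg, min_cooccur = 6,
                                     leak_preprocessing = TRUE)$error_rate)
  }
  expect_lt(mean(leaky), mean(clean))
})

test_that("run_grid produces one deterministic row per term and cell", {
  syn <- generate_annotation_data(synth_config(
    n_proteins = 250, n_iprs = 60, n_go = 2, background_density = 0.05,
    n_informative_per_go = 5, assoc_strength = 0.9,
    positive_fraction = 0.1, seed = 12))
  terms <- colnames(syn$go)
  rep1 <- run_grid(syn$ipr, syn$go, terms, seed = 5)
  expect_s3_class(rep1, "method_grid_report")
  expect_equal(nrow(rep1), 24)
  expect_false(any(rep1$skipped))
  expect_equal(dplyr::distinct(rep1[, c("learner", "feature_selection",
                                        "weighted")]) |> nrow(), 12)
  rep2 <- run_grid(syn$ipr, syn$go, terms, seed = 5)
  expect_identical(rep1, rep2)

  # serialization is byte-stable too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_grid_report(rep1, f1); write_grid_report(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("infeasible terms are reported as skipped rows, not failures", {
  withr::with_seed(8, {
    X <- new_annotation_matrix(random_binary_matrix(30, 10, 0.2))
  })
  go <- matrix(0L, 30, 2,
               dimnames = list(rownames(X), c("GO:0000001", "GO:0000002")))
  go[1:12, 1] <- 1L  # feasible
  go[1, 2] <- 1L     # one positive: balanced set far below 10 per class
  rep <- run_grid(X, new_annotation_matrix(go),
                  c("GO:0000001", "GO:0000002"), seed = 3)
  expect_equal(nrow(rep), 24)
  skipped <- rep[rep$go_term == "GO:0000002", ]
  expect_true(all(skipped$skipped))
  expect_true(all(grepl("fold|class", skipped$reason)))
  expect_false(any(rep[rep$go_term == "GO:0000001", ]$skipped))
})

test_that("glance summarises a grid report", {
  syn <- generate_annotation_data(synth_config(
    n_proteins = 250, n_iprs = 40, n_go = 1, background_density = 0.05,
    n_informative_per_go = 5, assoc_strength = 0.9,
    positive_fraction = 0.1, seed = 2))
  rep <- run_grid(syn$ipr, syn$go, colnames(syn$go),
                  grid = method_grid()[1:2, ], seed = 1)
  g <- glance(rep)
  expect_equal(g$n_cells, 2)
  expect_equal(g$n_skipped, 0)
  expect_true(g$mean_error >= 0 && g$mean_error <= 1)
})
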