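#' Configure one cell of the evaluation grid
#'
#' @param learner `"adaboost"`, `"svm"` (RBF kernel, libsvm) or `"smo"`
#'   (linear kernel, SMO-type solver).
#' @param use_feature_selection Run [select_features()] inside each training
#'   fold and restrict both folds to the selected columns?
#' @param use_weighted Re-encode features with [weighted_transform()], with
#'   correlations estimated on the training fold only? When combined with
#'   feature selection, selection runs first on the binary columns and the
#'   transform is computed on the selected columns.
#' @param learner_params Named list of learner options (`cost` for the SVMs,
#'   `n_rounds` for AdaBoost).
#' @param seed Integer seed for the fold split.
#' @return A `method_config` list.
#' @export
method_config <- function(learner = c("adaboost", "svm", "smo"),
                          use_feature_selection = FALSE,
                          use_weighted = FALSE,
                          learner_params = list(),
                          seed = 1L) {
  structure(list(
    learner = match.arg(learner),
    use_feature_selection = isTRUE(use_feature_selection),
    use_weighted = isTRUE(use_weighted),
    learner_params = learner_params,
    seed = as.integer(seed)
  ), class = "method_config")
}

#' The full 12-cell method grid
#'
#' Three learners crossed with original/weighted features and with/without
#' feature selection.
#'
#' @return A 12-row tibble with columns `learner`, `feature_selection`,
#'   `weighted`.
#' @export
method_grid <- function() {
  tidyr::expand_grid(
    learner = c("adaboost", "svm", "smo"),
    feature_selection = c(FALSE, TRUE),
    weighted = c(FALSE, TRUE)
  )
}

stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated error rate of one grid cell on one balanced dataset
#'
#' Stratified k-fold cross-validation. All data-dependent preprocessing —
#' feature selection and the weighted transform (its correlation matrix) —
#' is fitted on the training portion of each fold only; held-out proteins
#' are transformed with the training-fold correlations. A deliberate
#' `leak_preprocessing = TRUE` mode fits the preprocessing once on the full
#' dataset, for sensitivity analysis of selection leakage; it is never the
#' default.
#'
#' @param dataset A `balanced_dataset` from [undersample()].
#' @param config A [method_config()].
#' @param k Number of folds (default 10); each class must have at least `k`
#'   members.
#' @param min_cooccur Passed to [select_features()].
#' @param pooled Report the pooled misclassification fraction instead of the
#'   mean of per-fold error rates.
#' @param leak_preprocessing Fit selection/transform on all rows (see above).
#' @return One-row tibble: `go_term`, `learner`, `feature_selection`,
#'   `weighted`, `error_rate`, `fold_errors` (list column of k values),
#'   `n_train`, `n_features_used`, `seed`.
#' @export
crossval_error <- function(dataset, config, k = 10, min_cooccur = 1,
                           pooled = FALSE, leak_preprocessing = FALSE) {
  stopifnot(inherits(dataset, "balanced_dataset"),
            inherits(config, "method_config"))
  X <- dataset$X
  y <- dataset$y
  if (min(table(y)) < k) {
    abort(sprintf(
      "only %d proteins in the smaller class; %d-fold CV needs at least %d (use smaller k)",
      min(table(y)), k, k), class = "ipr2go_fold_infeasible")
  }
  fold <- stratified_folds(y, k, config$seed)

  full_sel <- NULL
  full_C <- NULL
  if (leak_preprocessing) {
    if (config$use_feature_selection) {
      full_sel <- selection_with_fallback(X, y, min_cooccur)
    }
    cols <- full_sel %||% seq_len(ncol(X))
    if (config$use_weighted) {
      full_C <- phi_correlation_matrix(X[, cols, drop = FALSE])
    }
  }

  fold_errors <- numeric(k)
  fold_sizes <- integer(k)
  n_feat <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- y[tr]
    Xte <- X[te, , drop = FALSE]

    cols <- seq_len(ncol(X))
    if (config$use_feature_selection) {
      cols <- if (leak_preprocessing) full_sel
              else selection_with_fallback(Xtr, ytr, min_cooccur)
    }
    Xtr_f <- Xtr[, cols, drop = FALSE]
    Xte_f <- Xte[, cols, drop = FALSE]
    if (config$use_weighted) {
      C <- if (leak_preprocessing) full_C else phi_correlation_matrix(Xtr_f)
      Xtr_f <- weighted_transform(Xtr_f, C)$values
      Xte_f <- weighted_transform(Xte_f, C)$values
    }
    model <- fit_classifier(config$learner, Xtr_f, ytr, config$learner_params)
    pred <- predict_classifier(model, Xte_f)
    fold_errors[f] <- mean(pred != y[te])
    fold_sizes[f] <- length(te)
    n_feat[f] <- length(cols)
  }

  err <- if (pooled) {
    sum(fold_errors * fold_sizes) / sum(fold_sizes)
  } else {
    mean(fold_errors)
  }
  tibble(
    go_term = dataset$go_term,
    learner = config$learner,
    feature_selection = config$use_feature_selection,
    weighted = config$use_weighted,
    error_rate = err,
    fold_errors = list(fold_errors),
    n_train = length(y),
    n_features_used = mean(n_feat),
    seed = config$seed
  )
}

selection_with_fallback <- function(X, y, min_cooccur) {
  sel <- suppressWarnings(select_features(X, y, min_cooccur = min_cooccur))
  if (attr(sel, "empty_selection")) {
    sel <- which(colSums(X) > 0)
    if (length(sel) == 0) sel <- seq_len(ncol(X))
  }
  as.integer(sel)
}

#' Run the method grid over a set of GO terms
#'
#' For each term: build the balanced training set by [undersample()], then
#' score every grid cell with [crossval_error()]. Per-(term, cell) seeds are
#' derived deterministically from `seed`, so a rerun reproduces the report
#' exactly. A term whose balanced set is infeasible (too few positives or
#' negatives) yields skipped rows carrying the reason instead of aborting
#' the grid.
#'
#' @param ipr_matrix Protein-by-IPR `annotation_matrix`.
#' @param go_matrix Protein-by-GO `annotation_matrix` over the same proteins
#'   (same row order).
#' @param go_terms Character vector of GO column ids to evaluate.
#' @param grid Tibble of grid cells as from [method_grid()] (subset to run
#'   fewer cells).
#' @param seed Integer master seed.
#' @param k,min_cooccur,pooled Passed to [crossval_error()].
#' @param learner_params Named list passed to every cell's learner.
#' @return A `method_grid_report` tibble: one row per (term, cell) with the
#'   [crossval_error()] columns plus `skipped` and `reason`.
#' @export
run_grid <- function(ipr_matrix, go_matrix, go_terms, grid = method_grid(),
                     seed = 1L, k = 10, min_cooccur = 1, pooled = FALSE,
                     learner_params = list()) {
  stopifnot(identical(rownames(ipr_matrix), rownames(go_matrix)))
  missing <- setdiff(go_terms, colnames(go_matrix))
  if (length(missing)) {
    abort(paste0("GO terms absent from go_matrix: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::imap(go_terms, function(term, it) {
    term_seed <- as.integer(seed) + 131L * as.integer(it)
    ds <- tryCatch(
      undersample(ipr_matrix, go_matrix[, term], seed = term_seed,
                  go_term = term),
      error = function(e) e
    )
    purrr::pmap(grid, function(learner, feature_selection, weighted, ...) {
      cfg_seed <- term_seed + which(
        grid$learner == learner &
          grid$feature_selection == feature_selection &
          grid$weighted == weighted)[1]
      base <- tibble(
        go_term = term, learner = learner,
        feature_selection = feature_selection, weighted = weighted,
        error_rate = NA_real_, fold_errors = list(rep(NA_real_, k)),
        n_train = NA_integer_, n_features_used = NA_real_,
        seed = cfg_seed, skipped = TRUE, reason = NA_character_
      )
      if (inherits(ds, "error")) {
        base$reason <- conditionMessage(ds)
        return(base)
      }
      cfg <- method_config(learner, feature_selection, weighted,
                           learner_params = learner_params, seed = cfg_seed)
      tryCatch({
        row <- crossval_error(ds, cfg, k = k, min_cooccur = min_cooccur,
                              pooled = pooled)
        row$skipped <- FALSE
        row$reason <- NA_character_
        row
      }, error = function(e) {
        base$reason <- conditionMessage(e)
        base
      })
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  structure(rows, class = c("method_grid_report", class(tibble())))
}

#' @describeIn run_grid `glance()` summarises a report: terms, cells, mean
#'   error over completed rows.
#' @param x A `method_grid_report`.
#' @param ... Unused.
#' @method glance method_grid_report
#' @export
glance.method_grid_report <- function(x, ...) {
  done <- dplyr::filter(x, !.data$skipped)
  tibble(
    n_terms = dplyr::n_distinct(x$go_term),
    n_cells = nrow(x),
    n_skipped = sum(x$skipped),
    mean_error = mean(done$error_rate),
    min_error = min(done$error_rate),
    max_error = max(done$error_rate)
  )
}

#' Write a grid report as TSV
#'
#' Fold errors are semicolon-joined into a single column.
#'
#' @param report A `method_grid_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  flat <- report
  flat$fold_errors <- vapply(report$fold_errors,
                             function(v) paste(signif(v, 8), collapse = ";"),
                             character(1))
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
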