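#' Pairwise phi correlation matrix of binary feature columns
#'
#' The Pearson correlation of two 0/1 columns (the phi coefficient):
#' near 1 for co-occurring features, near 0 for unrelated ones, negative for
#' mutually exclusive ones. Zero-variance columns (all 0 or all 1) have no
#' defined correlation; by convention they correlate 0 with every other
#' column and 1 with themselves, so they contribute nothing to any weight.
#'
#' @param X Binary protein-by-feature matrix with at least 2 rows.
#' @return A `phi_correlation` matrix (features x features, symmetric,
#'   unit diagonal).
#' @examples
#' X <- build_matrix(read_annotations(
#'   system.file("extdata", "table3_ipr.tsv", package = "ipr2go"), "IPR"))
#' round(phi_correlation_matrix(X), 4)
#' @export
phi_correlation_matrix <- function(X) {
  X <- unclass(X)
  if (nrow(X) < 2) {
    abort("correlation is undefined for a single-row matrix",
          class = "ipr2go_validation_error")
  }
  C <- suppressWarnings(stats::cor(X))
  C[is.na(C)] <- 0
  diag(C) <- 1
  structure(C, class = c("phi_correlation", "matrix", "array"))
}

#' @export
print.phi_correlation <- function(x, ...) {
  cat(sprintf("<phi_correlation> %d x %d feature correlation matrix\n",
              nrow(x), ncol(x)))
  print(round(unclass(x), 4), ...)
  invisible(x)
}

#' Correlation-based weighted re-encoding of binary feature profiles
#'
#' Re-encodes each protein's binary IPR profile as continuous weights. For a
#' protein, the features are split into the group it carries (value 1) and
#' the group it lacks (value 0). Within a group, each feature's raw weight is
#' the sum of its correlations with the other members of the same group, and
#' the group is then allocated total mass 0.5, shared in proportion to the
#' raw weights:
#'
#' \deqn{w_i = \sum_{j \in g, j \ne i} \mathrm{corr}(i, j), \qquad
#'       \mathrm{weightsum}_i = 0.5 \; w_i / \sum_{k \in g} w_k}
#'
#' A singleton group receives 0.5 outright. Group totals can be negative
#' (mutually exclusive features); the ratio is still taken, so individual
#' weights may exceed 0.5 or be negative while the group total stays 0.5.
#' When a group of two or more features has raw weights summing to exactly
#' zero the mass is split equally (0.5 per group member count) and the
#' protein is flagged in `zero_denominator`.
#'
#' Correlations are used at full floating-point precision throughout;
#' rounding, if any, is applied only to the final output.
#'
#' @param X Binary protein-by-feature matrix. Rows need not be the rows `C`
#'   was estimated from (e.g. held-out proteins transformed with training
#'   correlations).
#' @param C Feature correlation matrix over the same columns, typically from
#'   [phi_correlation_matrix()].
#' @param keep_weights Also return the per-(protein, feature) raw weights and
#'   group totals in a `weights` tibble (columns `protein_id`, `feature_id`,
#'   `group`, `weight`, `group_total`, `weightsum`, `singleton`).
#' @return A `weighted_ipr` object: list with `values` (numeric matrix),
#'   `protein_ids`, `feature_ids`, `group_mass` (0.5), `zero_denominator`
#'   (logical per protein), and optionally `weights`.
#' @examples
#' X <- build_matrix(read_annotations(
#'   system.file("extdata", "table3_ipr.tsv", package = "ipr2go"), "IPR"))
#' wt <- weighted_transform(X, phi_correlation_matrix(X))
#' round(wt$values, 4)
#' @export
weighted_transform <- function(X, C, keep_weights = FALSE) {
  X <- unclass(X)
  C <- unclass(C)
  if (ncol(X) != ncol(C)) {
    abort("X and C disagree on the number of features",
          class = "ipr2go_validation_error")
  }
  n <- nrow(X)
  p <- ncol(X)
  W <- matrix(NA_real_, n, p, dimnames = dimnames(X))
  raw <- if (keep_weights) matrix(NA_real_, n, p) else NULL
  tot <- if (keep_weights) matrix(NA_real_, n, p) else NULL
  zero_denom <- logical(n)

  for (i in seq_len(n)) {
    v <- X[i, ]
    for (g in c(0L, 1L)) {
      m <- which(v == g)
      if (length(m) == 0L) next
      if (length(m) == 1L) {
        W[i, m] <- 0.5
        if (keep_weights) {
          raw[i, m] <- 0
          tot[i, m] <- 0
        }
        next
      }
      Cg <- C[m, m, drop = FALSE]
      w <- rowSums(Cg) - diag(Cg)
      denom <- sum(w)
      if (abs(denom) < 1e-12) {
        W[i, m] <- 0.5 / length(m)
        zero_denom[i] <- TRUE
      } else {
        W[i, m] <- 0.5 * w / denom
      }
      if (keep_weights) {
        raw[i, m] <- w
        tot[i, m] <- denom
      }
    }
  }

  out <- structure(list(
    values = W,
    protein_ids = rownames(X) %||% as.character(seq_len(n)),
    feature_ids = colnames(X) %||% as.character(seq_len(p)),
    group_mass = 0.5,
    zero_denominator = zero_denom
  ), class = "weighted_ipr")
  if (keep_weights) {
    out$weights <- tibble(
      protein_id = rep(out$protein_ids, p),
      feature_id = rep(out$feature_ids, each = n),
      group = as.integer(X),
      weight = as.vector(raw),
      group_total = as.vector(tot),
      weightsum = as.vector(W),
      singleton = as.vector(tot) == 0 & as.vector(raw) == 0
    ) |> dplyr::arrange(.data$protein_id, .data$feature_id)
  }
  out
}

#' @export
print.weighted_ipr <- function(x, ...) {
  cat(sprintf("<weighted_ipr> %d proteins x %d features (group mass %.1f)\n",
              length(x$protein_ids), length(x$feature_ids), x$group_mass))
  print(round(x$values, 4), ...)
  invisible(x)
}

#' @describeIn weighted_transform `tidy()` returns the long form: one row per
#'   (protein, feature) with the binary group and the weighted value.
#' @param x A `weighted_ipr` object.
#' @param ... Unused.
#' @method tidy weighted_ipr
#' @export
tidy.weighted_ipr <- function(x, ...) {
  tibble(
    protein_id = rep(x$protein_ids, length(x$feature_ids)),
    feature_id = rep(x$feature_ids, each = length(x$protein_ids)),
    weightsum = as.vector(x$values)
  ) |> dplyr::arrange(.data$protein_id, .data$feature_id)
}

#' @describeIn weighted_transform `glance()` summarises dimensions, the group
#'   mass constant and how many proteins hit the zero-denominator fallback.
#' @method glance weighted_ipr
#' @export
glance.weighted_ipr <- function(x, ...) {
  tibble(
    n_proteins = length(x$protein_ids),
    n_features = length(x$feature_ids),
    group_mass = x$group_mass,
    n_zero_denominator = sum(x$zero_denominator)
  )
}

#' Write / read a weighted (or correlation) matrix as TSV
#'
#' Header row of feature ids, first column of row ids.
#'
#' @param x A `weighted_ipr`, `phi_correlation`, or plain named matrix.
#' @param path Output path.
#' @return `path` invisibly (write); a numeric matrix (read).
#' @export
write_matrix_tsv <- function(x, path) {
  m <- if (inherits(x, "weighted_ipr")) x$values else unclass(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
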