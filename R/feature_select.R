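#' Four-state contingency of one IPR column against a GO label vector
#'
#' Each protein falls into one of four states according to whether it carries
#' the IPR (IPos/INeg) and whether it carries the GO term (GPos/GNeg).
#'
#' @param ipr_column Binary vector of IPR presence per protein.
#' @param go_labels Binary vector of GO presence per protein (same length).
#' @return A `four_state_counts` list: `n_gpos_ipos`, `n_gneg_ipos`,
#'   `n_gpos_ineg`, `n_gneg_ineg`, plus marginals `n_ipos`, `n_ineg`.
#' @export
four_state_counts <- function(ipr_column, go_labels) {
  if (length(ipr_column) != length(go_labels)) {
    abort("ipr_column and go_labels differ in length",
          class = "ipr2go_validation_error")
  }
  if (length(ipr_column) < 1) abort("need at least one protein")
  i <- as.integer(ipr_column)
  g <- as.integer(go_labels)
  out <- list(
    n_gpos_ipos = sum(i == 1L & g == 1L),
    n_gneg_ipos = sum(i == 1L & g == 0L),
    n_gpos_ineg = sum(i == 0L & g == 1L),
    n_gneg_ineg = sum(i == 0L & g == 0L)
  )
  out$n_ipos <- out$n_gpos_ipos + out$n_gneg_ipos
  out$n_ineg <- out$n_gpos_ineg + out$n_gneg_ineg
  structure(out, class = "four_state_counts")
}

#' Conditional-probability profile of one IPR column
#'
#' Converts four-state counts into the four conditional probabilities of GO
#' status given IPR status, and their sum (the score plotted against feature
#' index to reveal the Area 1 / Area 2 split). With the default IPR
#' conditioning, each same-IPR-status pair of probabilities sums to 1, so a
#' column observed in both states scores exactly 2 and degenerate
#' (e.g. all-zero) columns score less; that deficit is what separates
#' uninformative Area 1 columns. Zero denominators yield probability 0 so
#' scores stay totally ordered.
#'
#' `condition = "go"` gives the literal alternative reading in which the
#' denominators are the GO-positive/GO-negative protein counts; its ratios
#' are not probabilities in general and it is exposed only for comparison.
#'
#' @param counts A `four_state_counts` object.
#' @param condition `"ipr"` (default) or `"go"` denominator convention.
#' @return A one-row tibble: `p_gpos_given_ipos`, `p_gneg_given_ipos`,
#'   `p_gpos_given_ineg`, `p_gneg_given_ineg`, `score`.
#' @examples
#' conditional_profile(four_state_counts(c(0, 1, 0, 1, 0), c(1, 1, 0, 0, 0)))
#' @export
conditional_profile <- function(counts, condition = c("ipr", "go")) {
  condition <- match.arg(condition)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  if (condition == "ipr") {
    d_pos <- counts$n_ipos
    d_neg <- counts$n_ineg
  } else {
    d_pos <- counts$n_gpos_ipos + counts$n_gpos_ineg
    d_neg <- counts$n_gneg_ipos + counts$n_gneg_ineg
  }
  p <- tibble(
    p_gpos_given_ipos = safe_div(counts$n_gpos_ipos, d_pos),
    p_gneg_given_ipos = safe_div(counts$n_gneg_ipos, d_pos),
    p_gpos_given_ineg = safe_div(counts$n_gpos_ineg, d_neg),
    p_gneg_given_ineg = safe_div(counts$n_gneg_ineg, d_neg)
  )
  p$score <- p$p_gpos_given_ipos + p$p_gneg_given_ipos +
    p$p_gpos_given_ineg + p$p_gneg_given_ineg
  p
}

#' Per-column conditional profiles of a feature matrix
#'
#' Vectorised [four_state_counts()] + [conditional_profile()] over every
#' column, the per-term view used for feature selection and for plotting the
#' Area 1 / Area 2 score distribution.
#'
#' @param X Binary protein-by-feature matrix (e.g. a `balanced_dataset$X`).
#' @param y Binary GO label vector, one per row of `X`.
#' @param condition Denominator convention, see [conditional_profile()].
#' @return A tibble with one row per column: `feature_id`, `column`, the four
#'   counts, the four probabilities, `score`.
#' @export
conditional_profiles <- function(X, y, condition = c("ipr", "go")) {
  condition <- match.arg(condition)
  X <- unclass(X)
  y <- as.numeric(y)
  stopifnot(length(y) == nrow(X))
  n11 <- as.vector(crossprod(X, y))
  n1. <- unname(colSums(X))
  n10 <- n1. - n11
  n01 <- sum(y) - n11
  n00 <- (nrow(X) - n1.) - n01
  if (condition == "ipr") {
    d_pos <- n1.
    d_neg <- nrow(X) - n1.
  } else {
    d_pos <- rep(sum(y), ncol(X))
    d_neg <- rep(nrow(X) - sum(y), ncol(X))
  }
  sd0 <- function(a, b) ifelse(b > 0, a / b, 0)
  out <- tibble(
    feature_id = colnames(X) %||% as.character(seq_len(ncol(X))),
    column = seq_len(ncol(X)),
    n_gpos_ipos = n11, n_gneg_ipos = n10,
    n_gpos_ineg = n01, n_gneg_ineg = n00,
    p_gpos_given_ipos = sd0(n11, d_pos),
    p_gneg_given_ipos = sd0(n10, d_pos),
    p_gpos_given_ineg = sd0(n01, d_neg),
    p_gneg_given_ineg = sd0(n00, d_neg)
  )
  out$score <- out$p_gpos_given_ipos + out$p_gneg_given_ipos +
    out$p_gpos_given_ineg + out$p_gneg_given_ineg
  out
}

#' Select informative ("Area 2") feature columns
#'
#' In a balanced per-term subset, the overwhelming majority of IPR columns
#' carry no 1 at all (joint-absence mass: Area 1); the retained Area 2
#' columns are those observed in the subset that co-occur with at least
#' `min_cooccur` positive proteins. A minimum-score threshold on the summed
#' conditional probabilities can be added via `area2_score_min`.
#'
#' @param X Binary protein-by-feature matrix of a balanced subset.
#' @param y Binary label vector.
#' @param min_cooccur Minimum `n_gpos_ipos` for a column to be kept (>= 1).
#' @param area2_score_min Optional lower bound on the conditional-probability
#'   score; `NULL` (default) disables it.
#' @param condition Denominator convention, see [conditional_profile()].
#' @return Integer vector of selected column indices, in original column
#'   order, with attributes `feature_ids` and `empty_selection` (TRUE when
#'   nothing passed; a warning is also raised so callers can fall back to all
#'   nonzero columns).
#' @export
select_features <- function(X, y, min_cooccur = 1, area2_score_min = NULL,
                            condition = c("ipr", "go")) {
  if (min_cooccur < 1) abort("min_cooccur must be >= 1")
  prof <- conditional_profiles(X, y, condition = match.arg(condition))
  nonzero <- (prof$n_gpos_ipos + prof$n_gneg_ipos) > 0
  keep <- nonzero & prof$n_gpos_ipos >= min_cooccur
  if (!is.null(area2_score_min)) keep <- keep & prof$score >= area2_score_min
  idx <- which(keep)
  if (length(idx) == 0) {
    warn("empty feature selection; callers may fall back to all nonzero columns")
  }
  structure(idx,
            feature_ids = prof$feature_id[idx],
            empty_selection = length(idx) == 0)
}
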