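#' Balance a per-term training set by undersampling negatives
#'
#' Seen from a single GO term, the annotation data is heavily skewed: a few
#' positive proteins against thousands of negatives. Training on the raw
#' labels yields classifiers that predict "absent" almost everywhere, so the
#' training set is rebalanced by keeping every positive protein and drawing,
#' uniformly without replacement, exactly as many negatives.
#'
#' Oversampling of the minority class is deliberately not offered.
#'
#' @param ipr_matrix Protein-by-IPR `annotation_matrix`.
#' @param go_labels Binary vector (one per row of `ipr_matrix`): 1 when the
#'   protein carries the GO term.
#' @param seed Integer seed for the negative draw; stored in the result.
#' @param go_term Optional GO id recorded in the result.
#' @return A `balanced_dataset`: list with `go_term`, `protein_ids`, `X`
#'   (row-subset feature matrix), `y` (0/1 labels), `seed`. Positives come
#'   first, then the sampled negatives, both in original row order.
#' @examples
#' syn <- generate_annotation_data(synth_config(n_proteins = 50, n_iprs = 20,
#'   n_go = 1, seed = 1))
#' undersample(syn$ipr, syn$go[, 1], seed = 1)
#' @export
undersample <- function(ipr_matrix, go_labels, seed = 1L, go_term = NA_character_) {
  stopifnot(length(go_labels) == nrow(ipr_matrix))
  y <- as.integer(go_labels)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0) {
    abort("no positive proteins for this term", class = "ipr2go_no_positives")
  }
  if (length(neg) < length(pos)) {
    abort(sprintf(
      "fewer negatives (%d) than positives (%d); oversampling is not implemented",
      length(neg), length(pos)), class = "ipr2go_insufficient_negatives")
  }
  drawn <- withr::with_seed(as.integer(seed),
                            sample(neg, length(pos), replace = FALSE))
  idx <- c(pos, sort(drawn))
  structure(list(
    go_term = go_term,
    protein_ids = rownames(ipr_matrix)[idx],
    X = unclass(ipr_matrix)[idx, , drop = FALSE],
    y = c(rep(1L, length(pos)), rep(0L, length(pos))),
    seed = as.integer(seed)
  ), class = "balanced_dataset")
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf("<balanced_dataset> %s: %d proteins (%d per class), %d features, seed %d\n",
              x$go_term, length(x$y), sum(x$y), ncol(x$X), x$seed))
  invisible(x)
}

#' @describeIn undersample `tidy()` returns one row per retained protein
#'   with its class label.
#' @param x A `balanced_dataset`.
#' @param ... Unused.
#' @method tidy balanced_dataset
#' @export
tidy.balanced_dataset <- function(x, ...) {
  tibble(go_term = x$go_term, protein_id = x$protein_ids, label = x$y)
}
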