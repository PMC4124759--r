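#' Build a binary protein-by-feature incidence matrix
#'
#' Turns an annotation table into the 0/1 matrix the rest of the pipeline
#' operates on: entry (p, f) is 1 iff protein p carries feature f. Rows are
#' ordered by sorted protein id; columns by the supplied `feature_universe`
#' (which may include features absent from the table, yielding all-zero
#' columns) or, when absent, by sorted term id. The deterministic ordering
#' makes every downstream seeded step reproducible.
#'
#' @param table An `annotation_table` (or data frame with `protein_id`,
#'   `term_id`).
#' @param feature_universe Optional ordered character vector of feature ids;
#'   every term in `table` must belong to it.
#' @return An `annotation_matrix`: an integer 0/1 matrix with protein ids as
#'   row names and feature ids as column names.
#' @examples
#' tab <- read_annotations(
#'   system.file("extdata", "table3_ipr.tsv", package = "ipr2go"), "IPR")
#' build_matrix(tab)
#' @export
build_matrix <- function(table, feature_universe = NULL) {
  proteins <- sort(unique(table$protein_id))
  if (is.null(feature_universe)) {
    features <- sort(unique(table$term_id))
  } else {
    features <- feature_universe
    missing <- setdiff(unique(table$term_id), features)
    if (length(missing)) {
      abort(paste0("terms outside the feature universe: ",
                   paste(head(missing, 10), collapse = ", ")),
            class = "ipr2go_validation_error")
    }
  }
  m <- matrix(0L, length(proteins), length(features),
              dimnames = list(proteins, features))
  m[cbind(match(table$protein_id, proteins),
          match(table$term_id, features))] <- 1L
  new_annotation_matrix(m)
}

#' Construct / validate an annotation matrix
#'
#' @param values 0/1 matrix with unique row and column names.
#' @return The validated `annotation_matrix`.
#' @export
new_annotation_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)) ||
      anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("annotation matrix needs unique row and column names")
  }
  if (!all(values %in% c(0L, 1L))) {
    abort("annotation matrix entries must be 0 or 1")
  }
  storage.mode(values) <- "integer"
  structure(values, class = c("annotation_matrix", "matrix", "array"))
}

#' @export
print.annotation_matrix <- function(x, ...) {
  cat(sprintf("<annotation_matrix> %d proteins x %d features, %d ones (density %.4f)\n",
              nrow(x), ncol(x), sum(x), mean(x)))
  invisible(x)
}

#' @describeIn build_matrix `tidy()` recovers the long pair list (1-entries
#'   only) from a matrix, inverting `build_matrix()` up to ordering.
#' @param x An `annotation_matrix`.
#' @param ... Unused.
#' @method tidy annotation_matrix
#' @export
tidy.annotation_matrix <- function(x, ...) {
  idx <- which(unclass(x) == 1L, arr.ind = TRUE)
  tibble(protein_id = rownames(x)[idx[, 1]],
         term_id = colnames(x)[idx[, 2]]) |>
    dplyr::arrange(.data$protein_id, .data$term_id)
}

#' Select GO terms with enough positive support to train on
#'
#' Under 10-fold cross-validation a term annotated to only a handful of
#' proteins cannot populate every fold with positives, so sparsely supported
#' terms are dropped. The default cut-off of 20 positives leaves at least two
#' positives per fold in the balanced design.
#'
#' @param go_matrix Protein-by-GO `annotation_matrix`.
#' @param min_positive Minimum column sum (number of annotated proteins);
#'   must be >= 2.
#' @return Character vector of GO term ids, in decreasing support order, ties
#'   broken alphabetically.
#' @export
trainable_go_terms <- function(go_matrix, min_positive = 20) {
  if (min_positive < 2) abort("min_positive must be >= 2")
  cs <- colSums(go_matrix)
  keep <- cs >= min_positive
  ids <- colnames(go_matrix)[keep]
  ids[order(-cs[keep], ids)]
}

#' Serialize an annotation matrix as Matrix Market + id sidecars
#'
#' Writes `<path>.mtx` (sparse MatrixMarket), `<path>.rows` and
#' `<path>.cols` (one id per line).
#'
#' @param x An `annotation_matrix`.
#' @param path Base path (without extension).
#' @return `path`, invisibly.
#' @export
write_annotation_mtx <- function(x, path) {
  Matrix::writeMM(Matrix::Matrix(unclass(x), sparse = TRUE),
                  paste0(path, ".mtx"))
  writeLines(rownames(x), paste0(path, ".rows"))
  writeLines(colnames(x), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname write_annotation_mtx
#' @export
read_annotation_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
  rownames(m) <- readLines(paste0(path, ".rows"))
  colnames(m) <- readLines(paste0(path, ".cols"))
  new_annotation_matrix(m)
}
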