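#' Read a protein-to-term annotation table
#'
#' Reads long-format annotation pairs (one protein, one term per line) into a
#' tidy annotation table. The plain format is a two-column, tab-separated file
#' `protein_id<TAB>term_id`; a header line is detected automatically (its
#' second field does not carry the namespace prefix). GAF 2.x files are
#' accepted for GO annotations via `format = "gaf"` (object id from column 2,
#' GO id from column 5; `!` comment lines skipped).
#'
#' Duplicate (protein, term) pairs are dropped, keeping the first occurrence,
#' so a downstream incidence matrix is strictly binary.
#'
#' @param path Path to the annotation file.
#' @param namespace `"IPR"` or `"GO"`; every term id must carry the matching
#'   prefix (`IPR` or `GO:`).
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return A tibble of class `annotation_table` with columns `protein_id` and
#'   `term_id`, in first-occurrence order, with a `namespace` attribute.
#' @examples
#' path <- system.file("extdata", "table3_ipr.tsv", package = "ipr2go")
#' read_annotations(path, "IPR")
#' @export
read_annotations <- function(path, namespace = c("IPR", "GO"),
                             format = c("tsv", "gaf")) {
  namespace <- match.arg(namespace)
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]

  if (format == "gaf") {
    data <- !startsWith(lines, "!")
    lineno <- lineno[data]
    fields <- strsplit(lines[data], "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 5L)
    if (length(bad)) {
      abort(sprintf("GAF line %d has fewer than 5 columns", lineno[bad[1]]),
            class = "ipr2go_parse_error")
    }
    protein <- vapply(fields, `[[`, character(1), 2L)
    term <- vapply(fields, `[[`, character(1), 5L)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2L)
    if (length(bad)) {
      abort(sprintf("line %d: expected 2 tab-separated columns, found %d",
                    lineno[bad[1]], lengths(fields)[bad[1]]),
            class = "ipr2go_parse_error")
    }
    protein <- vapply(fields, `[[`, character(1), 1L)
    term <- vapply(fields, `[[`, character(1), 2L)
    # header row: second field lacks the namespace prefix
    if (length(term) && !term_matches(term[1], namespace)) {
      protein <- protein[-1]
      term <- term[-1]
      lineno <- lineno[-1]
    }
  }

  ok <- term_matches(term, namespace)
  if (any(!ok)) {
    abort(sprintf(
      "term ids inconsistent with namespace %s: %s", namespace,
      paste(head(unique(term[!ok]), 5), collapse = ", ")
    ), class = "ipr2go_validation_error")
  }
  tab <- tibble(protein_id = protein, term_id = term)
  tab <- dplyr::distinct(tab, .data$protein_id, .data$term_id)
  new_annotation_table(tab, namespace)
}

term_matches <- function(term, namespace) {
  startsWith(term, if (namespace == "IPR") "IPR" else "GO:")
}

new_annotation_table <- function(tab, namespace) {
  structure(tab,
    namespace = namespace,
    class = c("annotation_table", class(tibble())))
}

#' Coerce a data frame of annotation pairs to an annotation table
#'
#' @param x Data frame with columns `protein_id` and `term_id` (or two
#'   columns taken positionally).
#' @param namespace `"IPR"` or `"GO"`.
#' @return An `annotation_table` tibble (deduplicated, validated).
#' @export
as_annotation_table <- function(x, namespace = c("IPR", "GO")) {
  namespace <- match.arg(namespace)
  x <- as_tibble(x)
  if (!all(c("protein_id", "term_id") %in% names(x))) {
    if (ncol(x) < 2) abort("need columns protein_id and term_id")
    names(x)[1:2] <- c("protein_id", "term_id")
  }
  x <- dplyr::distinct(x, .data$protein_id, .data$term_id)
  ok <- term_matches(x$term_id, namespace)
  if (any(!ok)) {
    abort(sprintf("term ids inconsistent with namespace %s: %s", namespace,
                  paste(head(unique(x$term_id[!ok]), 5), collapse = ", ")),
          class = "ipr2go_validation_error")
  }
  new_annotation_table(x, namespace)
}

#' Write an annotation table as two-column TSV
#'
#' @param table An `annotation_table` (or any data frame with `protein_id`
#'   and `term_id` columns).
#' @param path Output path.
#' @param header Write a `protein_id	term_id` header line?
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path, header = TRUE) {
  out <- paste(table$protein_id, table$term_id, sep = "\t")
  if (header) out <- c("protein_id\tterm_id", out)
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
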