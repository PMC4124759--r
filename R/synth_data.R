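#' Configuration for the synthetic annotation generator
#'
#' The generator emulates the pathology of real IPR/GO annotation data: a
#' sparse binary feature matrix in which most columns are almost entirely
#' zero, and per-GO-term positives form a small minority, with a planted set
#' of informative IPR columns per GO term. Defaults mirror the shape of a
#' realistic single-species extraction (thousands of proteins, hundreds of
#' mostly-empty IPR columns, ~5% positives per term) scaled for fast tests.
#'
#' @param n_proteins,n_iprs,n_go Matrix dimensions.
#' @param background_density Probability that an uninformative cell is 1.
#' @param n_informative_per_go Planted informative IPR columns per GO term
#'   (disjoint across terms).
#' @param assoc_strength Probability that an informative column is 1 for a
#'   positive protein; must exceed 0.5 (and the background) to carry signal.
#' @param positive_fraction Fraction of proteins positive per GO term,
#'   in (0, 0.5].
#' @param seed Integer seed; the whole draw is deterministic given it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_proteins = 2000, n_iprs = 500, n_go = 5,
                         background_density = 0.01,
                         n_informative_per_go = 10,
                         assoc_strength = 0.8,
                         positive_fraction = 0.05,
                         seed = 7L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    n_iprs = as.integer(n_iprs),
    n_go = as.integer(n_go),
    background_density = background_density,
    n_informative_per_go = as.integer(n_informative_per_go),
    assoc_strength = assoc_strength,
    positive_fraction = positive_fraction,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_proteins >= 2, cfg$n_iprs >= 1, cfg$n_go >= 1,
    cfg$background_density > 0, cfg$background_density < 1,
    cfg$n_informative_per_go >= 0,
    cfg$n_informative_per_go * cfg$n_go <= cfg$n_iprs,
    cfg$assoc_strength > 0.5, cfg$assoc_strength <= 1,
    cfg$positive_fraction > 0, cfg$positive_fraction <= 0.5
  )
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic IPR/GO annotation dataset with planted signal
#'
#' Per GO term, `round(positive_fraction * n_proteins)` proteins are drawn
#' as positives (exactly). Each term owns a disjoint set of informative IPR
#' columns that are 1 with probability `assoc_strength` for its positives
#' and `background_density` for everyone else; all remaining columns are
#' pure background. The planted truth map is returned so feature-selection
#' recovery can be scored directly.
#'
#' @param config A [synth_config()].
#' @return List with `ipr` and `go` (`annotation_matrix` objects over the
#'   same proteins) and `truth` (named list: GO id -> informative IPR ids).
#' @examples
#' syn <- generate_annotation_data(synth_config(n_proteins = 100,
#'   n_iprs = 40, n_go = 2, seed = 1))
#' syn$truth
#' @export
generate_annotation_data <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_proteins
  p <- config$n_iprs
  protein_ids <- sprintf("P%05d", seq_len(n))
  ipr_ids <- sprintf("IPR%06d", seq_len(p))
  go_ids <- sprintf("GO:%07d", seq_len(config$n_go))

  withr::with_seed(config$seed, {
    ipr <- matrix(rbinom(n * p, 1L, config$background_density), n, p,
                  dimnames = list(protein_ids, ipr_ids))
    go <- matrix(0L, n, config$n_go,
                 dimnames = list(protein_ids, go_ids))
    n_pos <- round(config$positive_fraction * n)
    n_inf <- config$n_informative_per_go
    inf_cols <- if (n_inf > 0) {
      split(sample(p, n_inf * config$n_go),
            rep(seq_len(config$n_go), each = n_inf))
    } else {
      rep(list(integer(0)), config$n_go)
    }
    for (t in seq_len(config$n_go)) {
      pos <- sample(n, n_pos)
      go[pos, t] <- 1L
      for (j in inf_cols[[t]]) {
        ipr[pos, j] <- rbinom(n_pos, 1L, config$assoc_strength)
      }
    }
  })

  truth <- setNames(lapply(inf_cols, function(j) sort(ipr_ids[j])), go_ids)
  list(
    ipr = new_annotation_matrix(ipr),
    go = new_annotation_matrix(go),
    truth = truth
  )
}
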