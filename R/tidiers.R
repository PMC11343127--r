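# broom-style accessors for the pipeline result.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ontology-level results of a pipeline run
#'
#' @param x A `proteostasis_run`.
#' @param ... Unused.
#' @return The ontology summary tibble with the quadrant class attached:
#'   one row per term with means, test statistics, adjusted p-values,
#'   significance, redundancy flags, and `regulation_class`.
#' @method tidy proteostasis_run
#' @export
tidy.proteostasis_run <- function(x, ...) {
  x$report$scatter
}

#' One-row summary of a pipeline run
#'
#' @param x A `proteostasis_run`.
#' @param ... Unused.
#' @return One-row tibble: seed, counts per stage, number of significant
#'   terms, and (for synthetic runs) the quadrant-recovery accuracy.
#' @method glance proteostasis_run
#' @export
glance.proteostasis_run <- function(x, ...) {
  r <- x$manifest$rows
  tibble::tibble(
    seed = x$manifest$seed,
    n_fits = r$fits,
    n_fits_passed = r$fits_passed,
    n_abundance_fc = r$abundance_fc,
    n_turnover_fc = r$turnover_fc,
    n_ontology_terms = r$ontology_terms,
    n_significant = r$significant_terms,
    quadrant_accuracy = if (!is.null(x$recovery)) x$recovery$accuracy else NA_real_
  )
}
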