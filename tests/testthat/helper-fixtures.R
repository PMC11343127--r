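# Fixture builders shared across test files. All fixtures are generated
# in code; `design_timepoints` is the six-point labeling design (hour 6
# encoded as 0.25 days).

design_timepoints <- c(0, 0.25, 1, 4, 16, 32)

# noiseless (or peptide-offset) pooled time course for one protein/cohort
make_courses <- function(k, peptide_offsets = c(0, 0),
                         timepoints = design_timepoints) {
  dplyr::bind_rows(lapply(seq_along(peptide_offsets), function(i) {
    tibble::tibble(
      peptide = paste0("PEP", i),
      time_days = timepoints,
      fraction_new = pmin(pmax(
        fraction_new(k, timepoints) + peptide_offsets[i], 0), 1)
    )
  }))
}

# minimal ontology records tibble
make_records <- function(members, sources = NULL) {
  n <- length(members)
  tibble::tibble(
    term_id = names(members) %||% sprintf("T%02d", seq_len(n)),
    source = sources %||% rep("GO Process", n),
    description = paste("term", seq_len(n)),
    observed_gene_count = unname(lengths(members)),
    background_gene_count = unname(2L * lengths(members)),
    matching_labels = unname(members)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
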