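# Quadrant classification: the sign pair (delta abundance, delta
# turnover) identifies the dominant proteostasis driver. More protein
# with faster turnover means synthesis rose; less protein with faster
# turnover means degradation rose; and symmetrically for the decreases.

.regulation_levels <- c("SynUp", "SynDown", "DegUp", "DegDown", "Indeterminate")

#' Classify the proteostasis regulation quadrant
#'
#' Maps the signs of scaled delta-abundance (x) and delta-turnover (y)
#' to a regulation class: `(+, +)` SynUp, `(+, -)` DegDown, `(-, -)`
#' SynDown, `(-, +)` DegUp. An exact zero or missing value in either
#' coordinate gives `Indeterminate` — a zero carries no direction.
#'
#' @param delta_abundance,delta_turnover Numeric vectors (recycled).
#' @return Factor with levels SynUp, SynDown, DegUp, DegDown,
#'   Indeterminate.
#' @examples
#' classify_quadrant(c(0.3, -0.3, 0), c(0.2, 0.2, 0.4))
#' @export
classify_quadrant <- function(delta_abundance, delta_turnover) {
  out <- dplyr::case_when(
    is.na(delta_abundance) | is.na(delta_turnover) ~ "Indeterminate",
    delta_abundance == 0 | delta_turnover == 0 ~ "Indeterminate",
    delta_abundance > 0 & delta_turnover > 0 ~ "SynUp",
    delta_abundance > 0 & delta_turnover < 0 ~ "DegDown",
    delta_abundance < 0 & delta_turnover < 0 ~ "SynDown",
    delta_abundance < 0 & delta_turnover > 0 ~ "DegUp"
  )
  factor(out, levels = .regulation_levels)
}

#' Build plot-ready proteostasis report tables
#'
#' Produces (i) the proteostasis scatter table — one row per ontology
#' term with its mean scaled abundance and turnover fold changes, the
#' quadrant class, and significance; (ii) the per-ontology paired bar
#' table — one row per member protein and metric (abundance / turnover)
#' with its scaled fold change; and (iii) the overlap matrix of the
#' significant terms (when at least two are significant).
#'
#' @param summaries Ontology summary tibble (with `significant`).
#' @param records Ontology records with `matching_labels`; must cover
#'   every summarized term.
#' @param abundance_fcs,turnover_fcs Scaled per-protein fold-change
#'   tibbles (`protein_id`, `fc_scaled`).
#' @return List of class `proteostasis_report`: `scatter`, `bars`,
#'   `overlap` (matrix or `NULL`).
#' @export
build_report <- function(summaries, records, abundance_fcs,
                         turnover_fcs = NULL) {
  orphans <- setdiff(summaries$term_id, records$term_id)
  if (length(orphans) > 0) {
    stop("Summarized term(s) absent from the ontology records: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  scatter <- summaries |>
    dplyr::mutate(regulation_class = classify_quadrant(
      .data$mean_abundance_fc, .data$mean_turnover_fc
    ))

  member_tbl <- records |>
    dplyr::filter(.data$term_id %in% summaries$term_id) |>
    dplyr::select("term_id", "matching_labels") |>
    tidyr::unnest_longer("matching_labels", values_to = "protein_id") |>
    dplyr::distinct()
  ab <- dplyr::transmute(abundance_fcs, .data$protein_id,
                         metric = "abundance", fc_scaled = .data$fc_scaled)
  bars_parts <- list(dplyr::inner_join(member_tbl, ab, by = "protein_id"))
  if (!is.null(turnover_fcs)) {
    tu <- dplyr::transmute(turnover_fcs, .data$protein_id,
                           metric = "turnover", fc_scaled = .data$fc_scaled)
    bars_parts <- c(bars_parts,
                    list(dplyr::inner_join(member_tbl, tu, by = "protein_id")))
  }
  bars <- dplyr::bind_rows(bars_parts) |>
    dplyr::arrange(.data$term_id, .data$metric, .data$protein_id)

  sig_terms <- summaries$term_id[summaries$significant %in% TRUE]
  overlap <- if (length(sig_terms) >= 2) {
    overlap_matrix(records[match(sig_terms, records$term_id), , drop = FALSE])
  }
  structure(list(scatter = scatter, bars = bars, overlap = overlap),
            class = "proteostasis_report")
}

#' Score quadrant recovery against synthetic ground truth
#'
#' Compares term-level quadrant calls with the regulation classes the
#' generator injected. Accuracy is computed over significant terms whose
#' true class is not Null; the Null false-call rate is the fraction of
#' Null terms flagged significant.
#'
#' @param scatter Scatter table from [build_report()] (term-level calls
#'   with `significant`).
#' @param ground_truth Ground-truth tibble with `ontology_id` and
#'   `regulation_class` (per protein, constant within a term).
#' @return List: `confusion` (tibble `truth`, `called`, `n`), `accuracy`
#'   (on significant non-Null terms), `null_significant_rate`.
#' @export
score_recovery <- function(scatter, ground_truth) {
  if (is.null(ground_truth) ||
      !all(c("ontology_id", "regulation_class") %in% names(ground_truth))) {
    stop("Ground truth with `ontology_id` and `regulation_class` is required.",
         call. = FALSE)
  }
  term_truth <- ground_truth |>
    dplyr::distinct(.data$ontology_id, truth_class = .data$regulation_class)
  if (anyDuplicated(term_truth$ontology_id)) {
    stop("Ground-truth regulation class is not constant within ontologies.",
         call. = FALSE)
  }
  joined <- dplyr::inner_join(scatter, term_truth,
                              by = c(term_id = "ontology_id"))
  if (nrow(joined) == 0) {
    stop("No overlap between scored terms and ground-truth ontologies.",
         call. = FALSE)
  }
  confusion <- joined |>
    dplyr::count(truth = .data$truth_class,
                 called = as.character(.data$regulation_class),
                 name = "n")
  sig_non_null <- dplyr::filter(joined, .data$significant %in% TRUE,
                                .data$truth_class != "Null")
  accuracy <- if (nrow(sig_non_null) > 0) {
    mean(as.character(sig_non_null$regulation_class) ==
           sig_non_null$truth_class)
  } else {
    NA_real_
  }
  null_terms <- dplyr::filter(joined, .data$truth_class == "Null")
  null_rate <- if (nrow(null_terms) > 0) {
    mean(null_terms$significant %in% TRUE)
  } else {
    NA_real_
  }
  list(confusion = confusion, accuracy = accuracy,
       null_significant_rate = null_rate)
}
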