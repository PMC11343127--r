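# Ontology-level synthesis of scaled fold changes.
#
# Terms come from a StringDB multiprotein-style enrichment export; the
# six curated sources are kept, terms must cover at least 25% of their
# background, member fold changes are averaged and tested against zero
# with a one-sample t-test, p-values are Benjamini-Hochberg adjusted, and
# highly overlapping significant terms are collapsed to the largest one.

.stringdb_required <- c(
  "category", "term ID", "term description", "observed gene count",
  "background gene count", "matching proteins in your network (labels)"
)

.default_sources <- c("GO Process", "GO Function", "GO Component",
                      "KEGG", "Reactome", "WikiPathways")

#' Parse a StringDB multiprotein-style enrichment export
#'
#' Reads the TSV, splits the matching-protein labels on commas, and
#' de-duplicates them. If a row's "observed gene count" disagrees with
#' the number of labels, the count is recomputed from the labels with a
#' warning naming the line.
#'
#' @param path Path to the TSV. A leading `#` on the first header (as in
#'   web exports) is tolerated.
#' @return Tibble: `term_id`, `source`, `description`,
#'   `observed_gene_count`, `background_gene_count`, `matching_labels`
#'   (list-column).
#' @export
parse_stringdb_table <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- sub("^#", "", names(raw)[1])
  missing_cols <- setdiff(.stringdb_required, names(raw))
  if (length(missing_cols) > 0) {
    stop("Missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  labels <- purrr::map(
    stringr::str_split(raw[["matching proteins in your network (labels)"]], ","),
    function(x) unique(stringr::str_trim(x[x != "" & !is.na(x)]))
  )
  out <- tibble::tibble(
    term_id = as.character(raw[["term ID"]]),
    source = as.character(raw[["category"]]),
    description = as.character(raw[["term description"]]),
    observed_gene_count = as.integer(raw[["observed gene count"]]),
    background_gene_count = as.integer(raw[["background gene count"]]),
    matching_labels = labels
  )
  bad <- which(lengths(labels) == 0 | is.na(out$term_id))
  if (length(bad) > 0) {
    warning("Dropping malformed row(s) at line(s) ",
            paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
    out <- out[-bad, , drop = FALSE]
  }
  mismatch <- which(out$observed_gene_count != lengths(out$matching_labels))
  if (length(mismatch) > 0) {
    warning("Observed gene count disagrees with label count at line(s) ",
            paste(mismatch + 1L, collapse = ", "),
            "; recounted from labels.", call. = FALSE)
    out$observed_gene_count[mismatch] <-
      lengths(out$matching_labels)[mismatch]
  }
  out
}

#' Filter ontology terms by source and coverage
#'
#' Keeps terms from the allowed databases whose coverage — observed gene
#' count over background gene count — is at least `min_coverage`.
#'
#' @param records Tibble from [parse_stringdb_table()].
#' @param sources Allowed source databases (default: GO Process, GO
#'   Function, GO Component, KEGG, Reactome, WikiPathways).
#' @param min_coverage Minimum coverage fraction (default 0.25).
#' @return Filtered records with a `coverage_pct` column added.
#' @export
filter_ontologies <- function(records, sources = .default_sources,
                              min_coverage = 0.25) {
  records |>
    dplyr::mutate(coverage_pct = 100 * .data$observed_gene_count /
                    .data$background_gene_count) |>
    dplyr::filter(.data$source %in% sources,
                  .data$coverage_pct >= 100 * min_coverage)
}

#' One-sample t-test of scaled fold changes against zero
#'
#' @param values Numeric vector of scaled fold changes.
#' @return One-row tibble: `t_statistic`, `p_value`, `testable`. Terms
#'   with fewer than two values or zero spread are flagged untestable
#'   (`NA` statistics) rather than raising.
#' @export
ontology_t_test <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2 || stats::sd(values) == 0) {
    return(tibble::tibble(t_statistic = NA_real_, p_value = NA_real_,
                          testable = FALSE))
  }
  ht <- stats::t.test(values, mu = 0)
  tibble::tibble(t_statistic = unname(ht$statistic),
                 p_value = ht$p.value, testable = TRUE)
}

#' Aggregate scaled protein fold changes to ontology terms
#'
#' For every term, averages the scaled abundance and turnover fold
#' changes over the member proteins present in each table (the turnover
#' set is typically smaller) and runs the one-sample t-test on the
#' abundance values. Terms with no member in the abundance table are
#' dropped.
#'
#' @param records Tibble of ontology records (with `matching_labels`).
#' @param abundance_fcs Tibble `protein_id`, `fc_scaled` of scaled
#'   abundance fold changes.
#' @param turnover_fcs Optional tibble `protein_id`, `fc_scaled` of
#'   scaled turnover fold changes.
#' @return Tibble: `term_id`, `source`, `description`, `coverage_pct`
#'   (when present), `n_abundance`, `n_turnover`, `mean_abundance_fc`,
#'   `mean_turnover_fc`, `t_statistic`, `p_value`, `testable`.
#' @export
aggregate_fcs <- function(records, abundance_fcs, turnover_fcs = NULL) {
  stopifnot(all(c("protein_id", "fc_scaled") %in% names(abundance_fcs)))
  ab <- stats::setNames(abundance_fcs$fc_scaled, abundance_fcs$protein_id)
  tu <- if (!is.null(turnover_fcs)) {
    stats::setNames(turnover_fcs$fc_scaled, turnover_fcs$protein_id)
  }
  per_term <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    members <- unique(records$matching_labels[[i]])
    ab_vals <- unname(ab[members[members %in% names(ab)]])
    tu_vals <- if (!is.null(tu)) unname(tu[members[members %in% names(tu)]])
    test <- ontology_t_test(ab_vals)
    tibble::tibble(
      term_id = records$term_id[i],
      n_abundance = length(ab_vals),
      n_turnover = length(tu_vals %||% numeric(0)),
      mean_abundance_fc = if (length(ab_vals)) mean(ab_vals) else NA_real_,
      mean_turnover_fc = if (length(tu_vals %||% numeric(0))) {
        mean(tu_vals)
      } else {
        NA_real_
      },
      t_statistic = test$t_statistic,
      p_value = test$p_value,
      testable = test$testable
    )
  })
  meta_cols <- intersect(c("term_id", "source", "description", "coverage_pct"),
                         names(records))
  out <- dplyr::left_join(per_term, records[, meta_cols, drop = FALSE],
                          by = "term_id") |>
    dplyr::relocate(dplyr::any_of(c("term_id", "source", "description",
                                    "coverage_pct")))
  dropped <- out$term_id[out$n_abundance == 0]
  out <- dplyr::filter(out, .data$n_abundance > 0)
  attr(out, "dropped_terms") <- dropped
  out
}

#' Benjamini-Hochberg adjustment of p-values
#'
#' Step-up false-discovery-rate adjustment; a thin validated wrapper over
#' [stats::p.adjust()]. `NA` entries (untestable terms) are excluded from
#' the family and returned as `NA`.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# union-find over term indices
.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, integer(1))
}

#' Collapse redundant significant ontologies to representatives
#'
#' Significant terms whose member overlap (intersection over the smaller
#' set) reaches `overlap_threshold` are clustered (transitively); within
#' each cluster the term with the most abundance-quantified proteins
#' represents the results, ties broken by lexicographic term id. All
#' terms are retained, flagged.
#'
#' @param summaries Tibble from [aggregate_fcs()] with a `significant`
#'   column.
#' @param records Ontology records supplying `matching_labels`.
#' @param overlap_threshold Overlap fraction defining "highly similar"
#'   (default 0.75).
#' @return `summaries` with `cluster` (integer, `NA` for non-significant
#'   terms) and `representative` (logical, `NA` for non-significant
#'   terms) columns added.
#' @export
resolve_redundancy <- function(summaries, records, overlap_threshold = 0.75) {
  stopifnot("significant" %in% names(summaries))
  sig <- which(summaries$significant %in% TRUE)
  summaries$cluster <- NA_integer_
  summaries$representative <- NA
  if (length(sig) == 0) return(summaries)
  members <- records$matching_labels[match(summaries$term_id[sig],
                                           records$term_id)]
  members <- purrr::map(members, unique)
  n <- length(sig)
  edges <- matrix(integer(0), ncol = 2)
  if (n > 1) {
    pairs <- utils::combn(n, 2)
    ov <- apply(pairs, 2, function(pr) {
      a <- members[[pr[1]]]; b <- members[[pr[2]]]
      length(intersect(a, b)) / min(length(a), length(b))
    })
    edges <- t(pairs[, ov >= overlap_threshold, drop = FALSE])
  }
  comp <- .components(n, edges)
  summaries$cluster[sig] <- comp
  for (cl in unique(comp)) {
    idx <- sig[comp == cl]
    ord <- order(-summaries$n_abundance[idx], summaries$term_id[idx])
    summaries$representative[idx] <- FALSE
    summaries$representative[idx[ord[1]]] <- TRUE
  }
  summaries
}

#' Percentage of member proteins shared between ontology terms
#'
#' Entry (A, B) is `100 |A intersect B| / |A|` with row normalization
#' (the default), or `100 |A intersect B| / min(|A|, |B|)` for the
#' symmetric variant. The diagonal is 100.
#'
#' @param records Ontology records (at least two rows).
#' @param normalize `"row"` (default) or `"min"`.
#' @return Square numeric matrix with term ids as dimnames.
#' @export
overlap_matrix <- function(records, normalize = c("row", "min")) {
  normalize <- match.arg(normalize)
  if (nrow(records) < 2) stop("Need at least two terms.", call. = FALSE)
  members <- purrr::map(records$matching_labels, unique)
  n <- length(members)
  out <- matrix(0, n, n, dimnames = list(records$term_id, records$term_id))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(members[[i]], members[[j]]))
      denom <- if (normalize == "row") {
        length(members[[i]])
      } else {
        min(length(members[[i]]), length(members[[j]]))
      }
      out[i, j] <- 100 * inter / denom
    }
  }
  out
}
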