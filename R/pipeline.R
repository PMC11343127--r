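# End-to-end orchestration: synthetic data (or user files) -> turnover
# fitting -> abundance workflow -> ontology synthesis -> quadrant report.

.default_thresholds <- function() {
  list(
    rsq_min = 0.6,
    min_unique_peptides = 2L,
    min_nonzero_timepoints = 3L,
    max_rms_deviation = 0.1,
    min_n_value = 5,
    min_peptide_length = 6L,
    min_m0_change = 0.04,
    min_coverage = 0.25,
    f_test_alpha = 0.05,
    bh_alpha = 0.05,
    redundancy_overlap = 0.75,
    max_missing_per_genotype = 1L
  )
}

.threshold_ranges <- list(
  rsq_min = c(0, 1), min_unique_peptides = c(1, Inf),
  min_nonzero_timepoints = c(1, Inf), max_rms_deviation = c(0, Inf),
  min_n_value = c(0, Inf), min_peptide_length = c(1, Inf),
  min_m0_change = c(0, 1), min_coverage = c(0, 1),
  f_test_alpha = c(0, 1), bh_alpha = c(0, 1),
  redundancy_overlap = c(0, 1), max_missing_per_genotype = c(0, Inf)
)

#' Validate and complete a pipeline configuration
#'
#' Fills defaults for anything unspecified — every analysis cutoff
#' (fit gates, peptide filters, coverage, test levels) is a config
#' default, never hard-coded downstream — and rejects unknown keys and
#' out-of-range values, reporting each violation by its key path.
#'
#' @param config Named list; recognized keys are `seed`, `enrichment`,
#'   `genotype_labels` (list with `control` and `experimental`),
#'   `thresholds` (named list, see [run_pipeline()]), and `paths`.
#' @return A completed list of class `proteoturn_config`.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    enrichment = 0.05,
    genotype_labels = list(control = "control", experimental = "experimental"),
    thresholds = .default_thresholds(),
    paths = list()
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("Unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(config$thresholds)) {
    unknown_t <- setdiff(names(config$thresholds), names(defaults$thresholds))
    if (length(unknown_t) > 0) {
      stop("Unknown configuration key(s): ",
           paste(paste0("thresholds.", unknown_t), collapse = ", "),
           call. = FALSE)
    }
  }
  out <- utils::modifyList(defaults, config)
  if (!is.numeric(out$seed) || is.na(out$seed)) {
    stop("Invalid value for seed: must be an integer.", call. = FALSE)
  }
  out$seed <- as.integer(out$seed)
  if (out$enrichment < 0 || out$enrichment >= 1) {
    stop("Invalid value for enrichment: must be in [0, 1).", call. = FALSE)
  }
  for (nm in names(out$thresholds)) {
    v <- out$thresholds[[nm]]
    rng <- .threshold_ranges[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        v < rng[1] || v > rng[2]) {
      stop("Invalid value for thresholds.", nm, ": must be a number in [",
           rng[1], ", ", rng[2], "].", call. = FALSE)
    }
  }
  gl <- out$genotype_labels
  if (is.null(gl$control) || is.null(gl$experimental) ||
      gl$control %in% gl$experimental) {
    stop("genotype_labels.control must be distinct from the experimental ",
         "label(s).", call. = FALSE)
  }
  structure(out, class = "proteoturn_config")
}

.read_inputs <- function(paths) {
  needed <- c("areas", "sample_info", "time_courses", "ontology")
  missing_p <- setdiff(needed, names(paths))
  if (length(missing_p) > 0) {
    stop("paths must name: ", paste(missing_p, collapse = ", "), call. = FALSE)
  }
  list(
    areas = readr::read_csv(paths$areas, show_col_types = FALSE,
                            progress = FALSE),
    sample_info = readr::read_tsv(paths$sample_info, show_col_types = FALSE,
                                  progress = FALSE),
    courses = readr::read_tsv(paths$time_courses, show_col_types = FALSE,
                              progress = FALSE),
    records = parse_stringdb_table(paths$ontology),
    truth = if (!is.null(paths$ground_truth)) {
      readr::read_tsv(paths$ground_truth, show_col_types = FALSE,
                      progress = FALSE)
    }
  )
}

#' Run the proteostasis pipeline end to end
#'
#' In `"simulate"` mode, generates a synthetic dataset from `synth`
#' (written to `file.path(outdir, "inputs")` when `outdir` is given) and
#' analyzes it; in `"real"` mode, reads the input files named in
#' `config$paths` (`areas`, `sample_info`, `time_courses`, `ontology`,
#' optionally `ground_truth`). The stages run in the fixed order:
#' peptide filtering and pooled rate fitting per cohort, turnover fold
#' changes with auto scaling; abundance missingness filter, log2 +
#' centering, slope normalization, 2-NN imputation, variance-gated
#' tests and fold changes with range scaling; ontology filtering,
#' aggregation, one-sample t-tests, Benjamini-Hochberg adjustment and
#' redundancy resolution; quadrant classification and report tables.
#'
#' @param config A [validate_config()] result or the raw list for it.
#' @param mode `"simulate"` or `"real"`.
#' @param synth A [synth_config()] (simulate mode); its seed is aligned
#'   to `config$seed` unless supplied explicitly.
#' @param outdir Optional directory; when given, every stage writes its
#'   TSV and a JSON run manifest is emitted.
#' @return A list of class `proteostasis_run`: `fits`, `turnover_fc`,
#'   `abundance_fc`, `ontology`, `report`, `recovery` (simulate mode),
#'   `truth`, `config`, `manifest`.
#' @export
run_pipeline <- function(config = list(), mode = c("simulate", "real"),
                         synth = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (!inherits(config, "proteoturn_config")) config <- validate_config(config)
  th <- config$thresholds
  gl <- config$genotype_labels

  if (mode == "simulate") {
    if (is.null(synth)) synth <- synth_config(seed = config$seed)
    truth <- generate_ground_truth(synth)
    courses <- dplyr::bind_rows(
      simulate_time_courses(truth, synth, "control"),
      simulate_time_courses(truth, synth, "experimental")
    )
    lfq <- simulate_lfq(truth, synth)
    records <- .ontology_records_from_truth(truth)
    gl <- list(control = "control", experimental = "experimental")
    if (!is.null(outdir)) {
      emit_fixture_files(truth, courses, lfq, file.path(outdir, "inputs"))
    }
  } else {
    inputs <- .read_inputs(config$paths)
    truth <- inputs$truth
    courses <- inputs$courses
    lfq <- list(areas = inputs$areas, sample_info = inputs$sample_info)
    records <- inputs$records
  }

  # --- kinetics ---------------------------------------------------------
  filt <- filter_peptides(courses, enrichment = config$enrichment,
                          min_n_value = th$min_n_value,
                          min_peptide_length = th$min_peptide_length,
                          min_m0_change = th$min_m0_change)
  fits <- fit_turnover_all(filt$retained, rsq_min = th$rsq_min,
                           min_unique_peptides = th$min_unique_peptides,
                           min_nonzero_timepoints = th$min_nonzero_timepoints,
                           max_rms_deviation = th$max_rms_deviation)
  turnover_fc <- turnover_fold_changes(fits, experimental = gl$experimental,
                                       control = gl$control)
  turnover_fc$fc_scaled <- auto_scale(turnover_fc$fc_log2)

  # --- abundance --------------------------------------------------------
  normalized <- lfq$areas |>
    filter_missingness(lfq$sample_info,
                       max_missing = th$max_missing_per_genotype) |>
    log2_and_center() |>
    slope_normalize() |>
    impute_knn(k = 2L)
  abundance_fc <- protein_fold_changes(normalized, lfq$sample_info,
                                       experimental = gl$experimental,
                                       control = gl$control,
                                       f_alpha = th$f_test_alpha)
  averaged <- average_fc_across_datasets(list(abundance_fc))
  abundance_fc <- dplyr::left_join(
    averaged, dplyr::select(abundance_fc, -"fc_log2"), by = "protein_id"
  )
  abundance_fc$fc_scaled <- range_scale(abundance_fc$fc_log2)

  # --- ontology ---------------------------------------------------------
  kept <- filter_ontologies(records, min_coverage = th$min_coverage)
  ontology <- aggregate_fcs(kept, abundance_fc, turnover_fc) |>
    dplyr::mutate(
      bh_adjusted_p = bh_adjust(.data$p_value),
      significant = .data$bh_adjusted_p < th$bh_alpha & !is.na(.data$bh_adjusted_p)
    ) |>
    resolve_redundancy(kept, overlap_threshold = th$redundancy_overlap)

  # --- proteostasis -----------------------------------------------------
  report <- build_report(ontology, kept, abundance_fc, turnover_fc)
  recovery <- if (!is.null(truth)) score_recovery(report$scatter, truth)

  manifest <- list(
    package_version = as.character(utils::packageVersion("proteoturn")),
    seed = config$seed,
    mode = mode,
    thresholds = th,
    enrichment = config$enrichment,
    rows = list(
      time_course_observations = nrow(courses),
      peptides_rejected = nrow(filt$rejected),
      fits = nrow(fits),
      fits_passed = sum(fits$passed),
      turnover_fc = nrow(turnover_fc),
      abundance_fc = nrow(abundance_fc),
      ontology_terms = nrow(ontology),
      significant_terms = sum(ontology$significant, na.rm = TRUE)
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  run <- structure(
    list(fits = fits, peptide_rejections = filt$rejected,
         turnover_fc = turnover_fc, normalized = normalized,
         abundance_fc = abundance_fc, ontology = ontology, report = report,
         recovery = recovery, truth = truth, config = config,
         manifest = manifest),
    class = "proteostasis_run"
  )
  if (!is.null(outdir)) .write_run(run, outdir)
  run
}

.write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  flat_fits <- run$fits |>
    dplyr::mutate(reject_reasons = vapply(.data$reject_reasons, paste,
                                          character(1), collapse = ";"))
  readr::write_tsv(flat_fits, file.path(outdir, "turnover_rates.tsv"))
  readr::write_tsv(run$turnover_fc, file.path(outdir, "turnover_fc.tsv"))
  readr::write_tsv(run$normalized, file.path(outdir, "normalized_matrix.tsv"))
  readr::write_tsv(run$abundance_fc, file.path(outdir, "abundance_fc.tsv"))
  readr::write_tsv(run$ontology, file.path(outdir, "ontology_summary.tsv"))
  readr::write_tsv(run$report$scatter, file.path(outdir, "proteostasis_scatter.tsv"))
  readr::write_tsv(run$report$bars, file.path(outdir, "ontology_bars.tsv"))
  if (!is.null(run$report$overlap)) {
    readr::write_tsv(
      tibble::as_tibble(run$report$overlap, rownames = "term_id"),
      file.path(outdir, "overlap_matrix.tsv")
    )
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.proteostasis_run <- function(x, ...) {
  r <- x$manifest$rows
  cat("<proteostasis_run>\n")
  cat("  seed:", x$manifest$seed, " mode:", x$manifest$mode, "\n")
  cat("  fits:", r$fits, "(", r$fits_passed, "passed )\n")
  cat("  fold changes:", r$abundance_fc, "abundance /", r$turnover_fc,
      "turnover\n")
  cat("  ontology terms:", r$ontology_terms, "(", r$significant_terms,
      "significant )\n")
  if (!is.null(x$recovery)) {
    cat("  quadrant accuracy (significant non-Null):",
        round(x$recovery$accuracy, 3), "\n")
  }
  invisible(x)
}
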