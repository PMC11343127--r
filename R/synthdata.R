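# Seeded synthetic datasets with known ground-truth kinetics.
#
# The generator emulates the structure of a two-genotype D2O labeling +
# LFQ study: a six-timepoint labeling design, first-order labeling
# kinetics with asymptote 1, lognormal LFQ noise with per-sample scale
# effects and completely-at-random missingness, and ontology memberships
# with injected group-level regulation effects. Every draw is governed by
# the config seed, so identical configs yield byte-identical outputs.

# run `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.regulation_classes <- c("SynUp", "SynDown", "DegUp", "DegDown", "Null")

#' Configuration for the synthetic-data generator
#'
#' Defaults reproduce the study design this package models: six labeling
#' timepoints (day 0, hour 6, day 1, day 4, day 16, day 32), four
#' biological replicates per genotype, 50 ontologies of 20 proteins each,
#' a half-log2 regulation effect, and modest measurement noise.
#'
#' @param seed Integer seed governing every random draw.
#' @param n_proteins Number of proteins (default `n_ontologies *
#'   proteins_per_ontology`).
#' @param n_ontologies Number of ontology terms.
#' @param proteins_per_ontology Members per term (terms partition the
#'   proteins).
#' @param timepoints Labeling times in days, sorted, starting at 0.
#' @param replicates_per_genotype Biological replicates per genotype in
#'   the LFQ arm.
#' @param peptides_per_protein Peptides simulated per protein.
#' @param effect_size_log2 Magnitude of the injected regulation effect on
#'   the log2 scale.
#' @param fraction_new_noise_sd Additive Gaussian noise on fraction-new
#'   observations (truncated to `[0, 1]`).
#' @param lfq_noise_sd_log2 Log2-scale Gaussian noise on LFQ areas.
#' @param sample_effect_sd_log2 Spread of the per-sample multiplicative
#'   scale effects (log2 scale), removed later by normalization.
#' @param missing_rate Fraction of LFQ cells deleted completely at
#'   random; must be below 0.25 so the missingness filter retains most
#'   proteins.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_ontologies = 50L,
                         proteins_per_ontology = 20L,
                         n_proteins = n_ontologies * proteins_per_ontology,
                         timepoints = c(0, 0.25, 1, 4, 16, 32),
                         replicates_per_genotype = 4L,
                         peptides_per_protein = 5L,
                         effect_size_log2 = 0.5,
                         fraction_new_noise_sd = 0.03,
                         lfq_noise_sd_log2 = 0.25,
                         sample_effect_sd_log2 = 0.5,
                         missing_rate = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    n_proteins = as.integer(n_proteins),
    n_ontologies = as.integer(n_ontologies),
    proteins_per_ontology = as.integer(proteins_per_ontology),
    timepoints = as.numeric(timepoints),
    replicates_per_genotype = as.integer(replicates_per_genotype),
    peptides_per_protein = as.integer(peptides_per_protein),
    effect_size_log2 = effect_size_log2,
    fraction_new_noise_sd = fraction_new_noise_sd,
    lfq_noise_sd_log2 = lfq_noise_sd_log2,
    sample_effect_sd_log2 = sample_effect_sd_log2,
    missing_rate = missing_rate
  )
  counts <- c("n_proteins", "n_ontologies", "proteins_per_ontology",
              "replicates_per_genotype", "peptides_per_protein")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("`", nm, "` must be a positive count.", call. = FALSE)
    }
  }
  if (is.unsorted(cfg$timepoints) || cfg$timepoints[1] != 0) {
    stop("`timepoints` must be sorted with the first equal to 0.",
         call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 0.25) {
    stop("`missing_rate` must lie in [0, 0.25).", call. = FALSE)
  }
  for (nm in c("effect_size_log2", "fraction_new_noise_sd",
               "lfq_noise_sd_log2", "sample_effect_sd_log2")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 0) {
      stop("`", nm, "` must be a non-negative number.", call. = FALSE)
    }
  }
  structure(cfg, class = "synth_config")
}

.random_peptide <- function(min_len = 6L, max_len = 30L) {
  len <- sample(min_len:max_len, 1L)
  paste(sample(names(deuterium_site_counts), len, replace = TRUE),
        collapse = "")
}

#' Generate ground-truth proteins with known kinetics
#'
#' Each protein gets control-condition kinetic parameters (degradation
#' rate log-uniform on 0.01-2 per day; steady-state abundance lognormal)
#' and an ontology whose regulation class dictates the experimental
#' parameters. Degradation-driven classes shift `kdeg` alone by
#' `effect_size_log2`; synthesis-driven classes shift `ksyn` twice as far
#' (log2 scale) while `kdeg` moves with it, so abundance and turnover
#' both move by `effect_size_log2` with the sign pattern characteristic
#' of the class: SynUp (+, +), SynDown (-, -), DegUp (-, +),
#' DegDown (+, -).
#'
#' @param config A [synth_config()].
#' @return Tibble with one row per protein: `protein_id`, `ontology_id`,
#'   `regulation_class`, `ksyn_control`, `kdeg_control`,
#'   `ksyn_experimental`, `kdeg_experimental`, and a `peptides`
#'   list-column of sequences.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, {
    n <- config$n_proteins
    protein_id <- sprintf("P%04d", seq_len(n))
    ont_index <- ((ceiling(seq_len(n) / config$proteins_per_ontology) - 1L) %%
                    config$n_ontologies) + 1L
    ontology_id <- sprintf("T%03d", ont_index)
    class_of_ont <- .regulation_classes[((seq_len(config$n_ontologies) - 1L) %%
                                           5L) + 1L]
    regulation_class <- class_of_ont[ont_index]

    kdeg <- exp(stats::runif(n, log(0.01), log(2)))
    log2_ss <- stats::rnorm(n, mean = 20, sd = 2)
    ksyn <- 2^log2_ss * kdeg

    e <- config$effect_size_log2
    kd_mult <- dplyr::case_match(
      regulation_class,
      "SynUp" ~ 2^e, "SynDown" ~ 2^-e,
      "DegUp" ~ 2^e, "DegDown" ~ 2^-e,
      "Null" ~ 1
    )
    ks_mult <- dplyr::case_match(
      regulation_class,
      "SynUp" ~ 2^(2 * e), "SynDown" ~ 2^(-2 * e),
      .default = 1
    )

    peptides <- purrr::map(seq_len(n), function(i) {
      vapply(seq_len(config$peptides_per_protein), function(j) {
        .random_peptide()
      }, character(1))
    })

    tibble::tibble(
      protein_id = protein_id,
      ontology_id = ontology_id,
      regulation_class = regulation_class,
      ksyn_control = ksyn,
      kdeg_control = kdeg,
      ksyn_experimental = ksyn * ks_mult,
      kdeg_experimental = kdeg * kd_mult,
      peptides = peptides
    )
  })
}

#' Simulate peptide fraction-new time courses for one genotype
#'
#' For every peptide of every protein, evaluates the labeling curve
#' `1 - exp(-kdeg t)` at the design timepoints, adds Gaussian noise, and
#' truncates to `[0, 1]`. n-values are computed from the peptide
#' sequences via [peptide_n_value()].
#'
#' @param truth Tibble from [generate_ground_truth()].
#' @param config The [synth_config()] used to generate `truth`.
#' @param genotype `"control"` or `"experimental"`.
#' @return Long tibble: `peptide`, `protein_id`, `n_value`, `time_days`,
#'   `fraction_new`, `cohort`.
#' @export
simulate_time_courses <- function(truth, config, genotype = "control") {
  stopifnot(inherits(config, "synth_config"))
  genotype <- match.arg(genotype, c("control", "experimental"))
  kdeg <- if (genotype == "control") truth$kdeg_control else truth$kdeg_experimental
  .with_seed(config$seed + if (genotype == "control") 101L else 202L, {
    grid <- tidyr::expand_grid(
      idx = seq_len(nrow(truth)),
      pep = seq_len(config$peptides_per_protein),
      time_days = config$timepoints
    )
    peptide <- vapply(seq_len(nrow(grid)), function(r) {
      truth$peptides[[grid$idx[r]]][grid$pep[r]]
    }, character(1))
    fn <- fraction_new(kdeg[grid$idx], grid$time_days)
    if (config$fraction_new_noise_sd > 0) {
      fn <- fn + stats::rnorm(length(fn), 0, config$fraction_new_noise_sd)
    }
    fn <- pmin(pmax(fn, 0), 1)
    out <- tibble::tibble(
      peptide = peptide,
      protein_id = truth$protein_id[grid$idx],
      time_days = grid$time_days,
      fraction_new = fn,
      cohort = genotype
    )
    nv <- peptide_n_value(unique(out$peptide))
    names(nv) <- unique(out$peptide)
    out$n_value <- unname(nv[out$peptide])
    out[, c("peptide", "protein_id", "n_value", "time_days",
            "fraction_new", "cohort")]
  })
}

#' Simulate a label-free quantification area matrix
#'
#' Each sample's areas are the genotype's steady-state concentrations
#' `ksyn / kdeg`, multiplied by a per-sample scale effect (drawn once per
#' sample) and lognormal measurement noise, with cells deleted completely
#' at random at `missing_rate`.
#'
#' @inheritParams simulate_time_courses
#' @return A list with `areas` (wide tibble: `protein_id` plus one column
#'   per sample, raw area scale) and `sample_info` (tibble `sample_id`,
#'   `genotype`).
#' @export
simulate_lfq <- function(truth, config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed + 303L, {
    reps <- config$replicates_per_genotype
    genotypes <- rep(c("control", "experimental"), each = reps)
    sample_id <- paste0(genotypes, "_", rep(seq_len(reps), times = 2))
    ss <- cbind(
      control = truth$ksyn_control / truth$kdeg_control,
      experimental = truth$ksyn_experimental / truth$kdeg_experimental
    )
    sample_effect <- stats::rnorm(length(sample_id), 0,
                                  config$sample_effect_sd_log2)
    n <- nrow(truth)
    mat <- matrix(NA_real_, n, length(sample_id),
                  dimnames = list(truth$protein_id, sample_id))
    for (j in seq_along(sample_id)) {
      noise <- stats::rnorm(n, 0, config$lfq_noise_sd_log2)
      mat[, j] <- ss[, genotypes[j]] * 2^(sample_effect[j] + noise)
    }
    if (config$missing_rate > 0) {
      drop <- stats::runif(length(mat)) < config$missing_rate
      mat[drop] <- NA_real_
    }
    list(
      areas = dplyr::bind_cols(
        tibble::tibble(protein_id = truth$protein_id),
        tibble::as_tibble(mat)
      ),
      sample_info = tibble::tibble(sample_id = sample_id, genotype = genotypes)
    )
  })
}

# StringDB-style term table derived from the ground-truth memberships;
# background counts are set to twice the observed counts (50% coverage).
.ontology_records_from_truth <- function(truth) {
  sources <- c("GO Process", "GO Function", "GO Component",
               "KEGG", "Reactome", "WikiPathways")
  truth |>
    dplyr::group_by(.data$ontology_id, .data$regulation_class) |>
    dplyr::summarise(matching_labels = list(unique(.data$protein_id)),
                     .groups = "drop") |>
    dplyr::arrange(.data$ontology_id) |>
    dplyr::mutate(
      term_id = .data$ontology_id,
      source = sources[((dplyr::row_number() - 1L) %% length(sources)) + 1L],
      description = paste0("synthetic term ", .data$ontology_id, " (",
                           .data$regulation_class, ")"),
      observed_gene_count = lengths(.data$matching_labels),
      background_gene_count = 2L * lengths(.data$matching_labels)
    ) |>
    dplyr::select("term_id", "source", "description",
                  "observed_gene_count", "background_gene_count",
                  "matching_labels")
}

#' Write a synthetic dataset to disk in the pipeline's file dialects
#'
#' Emits the protein-area CSV (first column the protein accession,
#' remaining columns one per sample), its sample-to-genotype sidecar TSV,
#' the long peptide fraction-new TSV, a StringDB-multiprotein-style
#' ontology TSV, and a ground-truth TSV for recovery scoring.
#'
#' @param truth Tibble from [generate_ground_truth()].
#' @param courses Combined time-course tibble (both cohorts).
#' @param lfq List from [simulate_lfq()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a named character vector of the paths written
#'   (`areas`, `sample_info`, `time_courses`, `ontology`, `ground_truth`).
#' @export
emit_fixture_files <- function(truth, courses, lfq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("Cannot create directory: ", dir, call. = FALSE)
  paths <- c(
    areas = file.path(dir, "protein_areas.csv"),
    sample_info = file.path(dir, "sample_info.tsv"),
    time_courses = file.path(dir, "peptide_time_courses.tsv"),
    ontology = file.path(dir, "ontology_terms.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  readr::write_csv(lfq$areas, paths[["areas"]], na = "")
  readr::write_tsv(lfq$sample_info, paths[["sample_info"]])
  readr::write_tsv(courses, paths[["time_courses"]])

  records <- .ontology_records_from_truth(truth)
  stringdb <- tibble::tibble(
    category = records$source,
    `term ID` = records$term_id,
    `term description` = records$description,
    `observed gene count` = records$observed_gene_count,
    `background gene count` = records$background_gene_count,
    `matching proteins in your network (labels)` =
      vapply(records$matching_labels, paste, character(1), collapse = ",")
  )
  readr::write_tsv(stringdb, paths[["ontology"]])

  gt <- truth |>
    dplyr::mutate(peptides = vapply(.data$peptides, paste, character(1),
                                    collapse = ";"))
  readr::write_tsv(gt, paths[["ground_truth"]])
  invisible(paths)
}
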