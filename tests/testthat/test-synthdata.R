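# The synthetic-data generator: determinism, generative arithmetic, and
# the file dialects it shares with the pipeline readers.

small_cfg <- function(seed = 7, ...) {
  synth_config(seed = seed, n_ontologies = 5, proteins_per_ontology = 4,
               peptides_per_protein = 3, ...)
}

test_that("ground truth honors counts, classes, and the seed contract", {
  cfg <- synth_config(seed = 7, n_proteins = 500)
  truth <- generate_ground_truth(cfg)
  expect_identical(nrow(truth), 500L)
  expect_identical(truth, generate_ground_truth(cfg))
  expect_setequal(unique(truth$regulation_class),
                  c("SynUp", "SynDown", "DegUp", "DegDown", "Null"))
  # one class per ontology
  per_ont <- dplyr::distinct(truth, ontology_id, regulation_class)
  expect_false(anyDuplicated(per_ont$ontology_id) > 0)
  expect_error(synth_config(n_proteins = 0), "positive count")
  expect_error(synth_config(missing_rate = 0.3), "missing_rate")
  expect_error(synth_config(timepoints = c(1, 4)), "first equal to 0")
})

test_that("experimental parameters implement the class sign patterns", {
  truth <- generate_ground_truth(small_cfg(effect_size_log2 = 0.5))
  ss_ratio <- log2((truth$ksyn_experimental / truth$kdeg_experimental) /
                     (truth$ksyn_control / truth$kdeg_control))
  kd_ratio <- log2(truth$kdeg_experimental / truth$kdeg_control)
  by_class <- split(tibble::tibble(ss_ratio, kd_ratio), truth$regulation_class)
  # DegUp: kdeg scales by 2^0.5, steady state falls by the same factor
  expect_equal(by_class$DegUp$kd_ratio, rep(0.5, nrow(by_class$DegUp)),
               tolerance = 1e-12)
  expect_equal(by_class$DegUp$ss_ratio, rep(-0.5, nrow(by_class$DegUp)),
               tolerance = 1e-12)
  expect_true(all(abs(by_class$DegDown$kd_ratio + 0.5) < 1e-9 &
                    abs(by_class$DegDown$ss_ratio - 0.5) < 1e-9))
  expect_true(all(by_class$SynUp$ss_ratio > 0 & by_class$SynUp$kd_ratio > 0))
  expect_true(all(by_class$SynDown$ss_ratio < 0 & by_class$SynDown$kd_ratio < 0))
  expect_true(all(abs(by_class$Null$ss_ratio) < 1e-12 &
                    abs(by_class$Null$kd_ratio) < 1e-12))
})

test_that("noise-free time courses follow the labeling closed form", {
  cfg <- small_cfg(fraction_new_noise_sd = 0)
  truth <- generate_ground_truth(cfg)
  tc <- simulate_time_courses(truth, cfg, "control")
  expect_true(all(tc$fraction_new[tc$time_days == 0] == 0))
  expected <- fraction_new(
    truth$kdeg_control[match(tc$protein_id, truth$protein_id)], tc$time_days
  )
  expect_equal(tc$fraction_new, expected, tolerance = 1e-12)
  expect_true(all(tc$fraction_new >= 0 & tc$fraction_new <= 1))
  # n-values come from the sequences
  expect_equal(tc$n_value, peptide_n_value(tc$peptide), tolerance = 1e-12)
})

test_that("with noise off, pool size is conserved over the labeling course", {
  cfg <- small_cfg(fraction_new_noise_sd = 0)
  truth <- generate_ground_truth(cfg)
  for (i in c(1, 7, 20)) {
    tr <- concentration_trajectory(truth$ksyn_control[i],
                                   truth$kdeg_control[i], cfg$timepoints)
    ss <- truth$ksyn_control[i] / truth$kdeg_control[i]
    expect_equal(tr$P + tr$P_D, rep(ss, length(cfg$timepoints)),
                 tolerance = 1e-12 * ss)
  }
})

test_that("LFQ simulation honors noise, effects, and missingness settings", {
  cfg <- small_cfg(lfq_noise_sd_log2 = 0, sample_effect_sd_log2 = 0,
                   missing_rate = 0, effect_size_log2 = 1)
  truth <- generate_ground_truth(cfg)
  lfq <- simulate_lfq(truth, cfg)
  m <- as.matrix(lfq$areas[-1])
  rownames(m) <- lfq$areas$protein_id
  expect_false(anyNA(m))
  ctrl <- lfq$sample_info$sample_id[lfq$sample_info$genotype == "control"]
  exp_ <- lfq$sample_info$sample_id[lfq$sample_info$genotype == "experimental"]
  # within-genotype areas identical and equal to the steady state
  expect_equal(unname(m[, ctrl[1]]), truth$ksyn_control / truth$kdeg_control,
               tolerance = 1e-12)
  expect_equal(unname(apply(m[, ctrl], 1, sd)), rep(0, nrow(m)))
  # a synthesis-up protein doubles (effect_size_log2 = 1)
  syn_up <- truth$protein_id[truth$regulation_class == "SynUp"]
  ratio <- m[syn_up, exp_[1]] / m[syn_up, ctrl[1]]
  expect_equal(unname(ratio), rep(2, length(syn_up)), tolerance = 1e-12)

  cfg2 <- small_cfg(missing_rate = 0.2)
  lfq2 <- simulate_lfq(generate_ground_truth(cfg2), cfg2)
  expect_gt(sum(is.na(as.matrix(lfq2$areas[-1]))), 0)
})

test_that("fixture files are deterministic and round-trip losslessly", {
  cfg <- small_cfg()
  truth <- generate_ground_truth(cfg)
  courses <- dplyr::bind_rows(
    simulate_time_courses(truth, cfg, "control"),
    simulate_time_courses(truth, cfg, "experimental")
  )
  lfq <- simulate_lfq(truth, cfg)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  p1 <- emit_fixture_files(truth, courses, lfq, dir1)
  p2 <- emit_fixture_files(truth, courses, lfq, dir2)
  expect_setequal(names(p1), c("areas", "sample_info", "time_courses",
                               "ontology", "ground_truth"))
  expect_true(all(file.exists(p1)))
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }

  records <- parse_stringdb_table(p1[["ontology"]])
  expect_identical(nrow(records), cfg$n_ontologies)
  expect_identical(records$observed_gene_count, lengths(records$matching_labels))
  # labels in the TSV match the generated memberships exactly
  for (i in seq_len(nrow(records))) {
    expect_setequal(
      records$matching_labels[[i]],
      truth$protein_id[truth$ontology_id == records$term_id[i]]
    )
  }
})

test_that("identical configs reproduce identical datasets end to end", {
  cfg_a <- small_cfg(seed = 99)
  cfg_b <- small_cfg(seed = 99)
  expect_identical(
    simulate_time_courses(generate_ground_truth(cfg_a), cfg_a, "experimental"),
    simulate_time_courses(generate_ground_truth(cfg_b), cfg_b, "experimental")
  )
  expect_identical(simulate_lfq(generate_ground_truth(cfg_a), cfg_a),
                   simulate_lfq(generate_ground_truth(cfg_b), cfg_b))
})

test_that("noise-free ontology means separate the regulation classes", {
  cfg <- synth_config(seed = 3, n_ontologies = 10, proteins_per_ontology = 5,
                      peptides_per_protein = 2, fraction_new_noise_sd = 0,
                      lfq_noise_sd_log2 = 0, sample_effect_sd_log2 = 0,
                      missing_rate = 0)
  truth <- generate_ground_truth(cfg)
  ab <- log2((truth$ksyn_experimental / truth$kdeg_experimental) /
               (truth$ksyn_control / truth$kdeg_control))
  tu <- log2(truth$kdeg_experimental / truth$kdeg_control)
  per_ont <- tibble::tibble(ont = truth$ontology_id,
                            class = truth$regulation_class, ab, tu) |>
    dplyr::group_by(ont, class) |>
    dplyr::summarise(ab = mean(ab), tu = mean(tu), .groups = "drop") |>
    dplyr::filter(class != "Null")
  called <- as.character(classify_quadrant(per_ont$ab, per_ont$tu))
  expect_identical(called, per_ont$class)
})
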