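# Label-free quantification (LFQ) abundance workflow.
#
# Fixed stage order: missingness filter -> log2 -> per-sample centering ->
# slope normalization -> 2-nearest-neighbor imputation -> variance-gated
# t-tests and fold changes -> cross-dataset averaging -> range scaling.
# Matrices travel as wide tibbles (protein_id + one column per sample)
# with a sample_info tibble mapping sample_id -> genotype.

.sample_cols <- function(mat) setdiff(names(mat), "protein_id")

.as_value_matrix <- function(mat) {
  m <- as.matrix(mat[, .sample_cols(mat), drop = FALSE])
  rownames(m) <- mat$protein_id
  m
}

.rebuild_wide <- function(mat, m) {
  dplyr::bind_cols(tibble::tibble(protein_id = mat$protein_id),
                   tibble::as_tibble(m))
}

#' Filter proteins by per-genotype missingness
#'
#' Retains proteins with at most `max_missing` missing area values in
#' every genotype group. When the matrix carries a logical
#' `is_top_protein` column (protein-group representative flag from the
#' upstream search), only flagged rows are kept first.
#'
#' @param mat Wide area tibble (`protein_id` + one column per sample).
#' @param sample_info Tibble with `sample_id`, `genotype` covering every
#'   sample column.
#' @param max_missing Maximum missing values tolerated per genotype
#'   (default 1).
#' @return The filtered wide tibble.
#' @export
filter_missingness <- function(mat, sample_info, max_missing = 1L) {
  stopifnot("protein_id" %in% names(mat),
            all(c("sample_id", "genotype") %in% names(sample_info)))
  if ("is_top_protein" %in% names(mat)) {
    mat <- dplyr::filter(mat, .data$is_top_protein)
    mat$is_top_protein <- NULL
  }
  samples <- .sample_cols(mat)
  if (!all(samples %in% sample_info$sample_id)) {
    stop("sample_info does not cover every sample column.", call. = FALSE)
  }
  if (dplyr::n_distinct(sample_info$genotype) < 2) {
    stop("Need at least two genotypes.", call. = FALSE)
  }
  m <- .as_value_matrix(mat)
  geno <- sample_info$genotype[match(samples, sample_info$sample_id)]
  keep <- rep(TRUE, nrow(m))
  for (g in unique(geno)) {
    keep <- keep & rowSums(is.na(m[, geno == g, drop = FALSE])) <= max_missing
  }
  mat[keep, , drop = FALSE]
}

#' Log2-transform areas and mean-center each sample
#'
#' Applies `log2` to every area, then subtracts from each value the mean
#' over proteins within its sample, so every sample's post-centering mean
#' is zero (missing values skipped).
#'
#' @param mat Wide tibble of raw (positive) areas.
#' @return Wide tibble of centered log2 areas.
#' @export
log2_and_center <- function(mat) {
  m <- .as_value_matrix(mat)
  if (any(m <= 0, na.rm = TRUE)) {
    stop("Areas must be strictly positive for log2 transformation.",
         call. = FALSE)
  }
  m <- log2(m)
  m <- sweep(m, 2, colMeans(m, na.rm = TRUE), "-")
  .rebuild_wide(mat, m)
}

#' Normalize sample distribution widths by their slope against the mean profile
#'
#' The reference profile is each protein's mean across samples. For every
#' sample, the ordinary least-squares slope (with intercept) of the
#' sample's values regressed on the reference over co-observed proteins is
#' computed, and the sample's values are divided by it. Slopes are
#' attached as the `"slopes"` attribute of the result.
#'
#' @param mat Wide tibble of centered log2 areas.
#' @return Wide tibble with width-normalized samples.
#' @export
slope_normalize <- function(mat) {
  m <- .as_value_matrix(mat)
  reference <- rowMeans(m, na.rm = TRUE)
  slopes <- vapply(seq_len(ncol(m)), function(j) {
    ok <- !is.na(m[, j]) & !is.na(reference)
    if (sum(ok) < 2) {
      stop("Sample ", colnames(m)[j], " has fewer than two observed proteins.",
           call. = FALSE)
    }
    stats::coef(stats::lm(m[ok, j] ~ reference[ok]))[[2]]
  }, numeric(1))
  names(slopes) <- colnames(m)
  degenerate <- abs(slopes) < 1e-6
  if (any(degenerate)) {
    stop("Degenerate sample(s) with near-zero slope: ",
         paste(names(slopes)[degenerate], collapse = ", "), call. = FALSE)
  }
  m <- sweep(m, 2, slopes, "/")
  out <- .rebuild_wide(mat, m)
  attr(out, "slopes") <- slopes
  out
}

# pairwise missing-aware Euclidean distances between rows, rescaled by
# the fraction of co-observed coordinates (nan-Euclidean convention)
.nan_euclidean <- function(m) {
  obs <- !is.na(m)
  x0 <- m; x0[!obs] <- 0
  sq <- x0^2
  cross <- tcrossprod(x0)
  d2 <- tcrossprod(sq, obs) + tcrossprod(obs, sq) - 2 * cross
  co <- tcrossprod(obs * 1)
  d2 <- ncol(m) * d2 / co       # Inf/NaN where no co-observation
  d2[d2 < 0] <- 0               # numerical fuzz
  sqrt(d2)
}

#' Impute missing values from the two closest protein neighbors
#'
#' Each missing cell is replaced by the mean, in that sample, of the `k`
#' proteins nearest to the target protein. Distances are missing-aware
#' Euclidean over co-observed samples, rescaled by the fraction observed;
#' eligible donors must have the target sample observed. If fewer than
#' `k` donors are eligible, all eligible donors are used with a warning.
#'
#' @param mat Wide tibble of normalized log2 areas; every protein must
#'   have at least one observed value.
#' @param k Number of neighbors (default 2).
#' @return Wide tibble with no missing cells.
#' @export
impute_knn <- function(mat, k = 2L) {
  m <- .as_value_matrix(mat)
  if (!anyNA(m)) return(mat)
  if (any(rowSums(!is.na(m)) == 0)) {
    stop("Every protein must have at least one observed value.", call. = FALSE)
  }
  d <- .nan_euclidean(m)
  diag(d) <- Inf
  short <- FALSE
  filled <- m
  for (i in which(rowSums(is.na(m)) > 0)) {
    for (j in which(is.na(m[i, ]))) {
      eligible <- which(!is.na(m[, j]) & is.finite(d[i, ]))
      if (length(eligible) == 0) {
        stop("No eligible imputation donor for protein ", rownames(m)[i],
             " in sample ", colnames(m)[j], ".", call. = FALSE)
      }
      if (length(eligible) < k) short <- TRUE
      donors <- eligible[order(d[i, eligible])][seq_len(min(k, length(eligible)))]
      filled[i, j] <- mean(m[donors, j])
    }
  }
  if (short) {
    warning("Fewer than k eligible neighbors for some cells; ",
            "used all eligible donors.", call. = FALSE)
  }
  .rebuild_wide(mat, filled)
}

#' Variance-gated two-sample test
#'
#' Assesses equality of variances with a two-tailed F-test at
#' `f_alpha`; a non-significant result routes to the pooled-variance
#' (homoscedastic) t-test, a significant one to Welch's
#' (heteroscedastic) t-test.
#'
#' @param exp_values,ctrl_values Numeric vectors of log2 areas, at least
#'   3 values each.
#' @param f_alpha Rejection level of the variance F-test (default 0.05).
#' @return One-row tibble: `p_value`, `variance_test_p`, `test_used`
#'   (`"homoscedastic"` or `"heteroscedastic"`).
#' @export
variance_gated_test <- function(exp_values, ctrl_values, f_alpha = 0.05) {
  exp_values <- exp_values[is.finite(exp_values)]
  ctrl_values <- ctrl_values[is.finite(ctrl_values)]
  if (length(exp_values) < 3 || length(ctrl_values) < 3) {
    stop("Insufficient replicates: need at least 3 values per group.",
         call. = FALSE)
  }
  if (stats::sd(exp_values) == 0 && stats::sd(ctrl_values) == 0) {
    # degenerate: no within-group variance to test against
    equal <- isTRUE(all.equal(mean(exp_values), mean(ctrl_values)))
    return(tibble::tibble(p_value = if (equal) 1 else 0,
                          variance_test_p = 1,
                          test_used = "homoscedastic"))
  }
  f_p <- stats::var.test(exp_values, ctrl_values)$p.value
  welch <- is.finite(f_p) && f_p < f_alpha
  t_p <- stats::t.test(exp_values, ctrl_values, var.equal = !welch)$p.value
  tibble::tibble(
    p_value = t_p,
    variance_test_p = f_p,
    test_used = if (welch) "heteroscedastic" else "homoscedastic"
  )
}

#' Per-protein abundance fold changes between genotypes
#'
#' For each protein, the log2 fold change is the mean normalized log2
#' area in the experimental genotype minus the control mean; p-values
#' come from [variance_gated_test()].
#'
#' @param mat Wide tibble of normalized, imputed log2 areas.
#' @param sample_info Tibble `sample_id`, `genotype`.
#' @param experimental,control Genotype labels to contrast.
#' @param f_alpha Forwarded to [variance_gated_test()].
#' @return Tibble: `protein_id`, `fc_log2`, `p_value`,
#'   `variance_test_p`, `test_used`.
#' @export
protein_fold_changes <- function(mat, sample_info, experimental, control,
                                 f_alpha = 0.05) {
  samples <- .sample_cols(mat)
  geno <- sample_info$genotype[match(samples, sample_info$sample_id)]
  if (!all(c(experimental, control) %in% geno)) {
    stop("Both genotypes must be present among the samples.", call. = FALSE)
  }
  m <- .as_value_matrix(mat)
  me <- m[, geno == experimental, drop = FALSE]
  mc <- m[, geno == control, drop = FALSE]
  tests <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    variance_gated_test(me[i, ], mc[i, ], f_alpha = f_alpha)
  })
  dplyr::bind_cols(
    tibble::tibble(
      protein_id = mat$protein_id,
      fc_log2 = unname(rowMeans(me, na.rm = TRUE) - rowMeans(mc, na.rm = TRUE))
    ),
    tests
  )
}

#' Average protein fold changes across datasets
#'
#' Unweighted mean of `fc_log2` per protein over the datasets in which
#' the protein has a fold change; the output covers the union of
#' proteins and records how many datasets contributed.
#'
#' @param fc_tables List of per-dataset fold-change tibbles
#'   (`protein_id`, `fc_log2`).
#' @return Tibble: `protein_id`, `fc_log2`, `n_datasets`.
#' @export
average_fc_across_datasets <- function(fc_tables) {
  if (length(fc_tables) == 0) stop("Need at least one dataset.", call. = FALSE)
  dplyr::bind_rows(fc_tables, .id = "dataset") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      fc_log2 = mean(.data$fc_log2),
      n_datasets = dplyr::n(),
      .groups = "drop"
    )
}
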