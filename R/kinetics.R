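# First-order turnover kinetics under proteostasis.
#
# The model: a protein pool at steady state [P] = ksyn / kdeg, with
# zero-order synthesis and first-order degradation. After deuterated water
# is introduced at t = 0, pre-existing (unlabeled) protein decays as
# P(t) = (ksyn/kdeg) e^(-kdeg t) while labeled protein accumulates as
# P_D(t) = (ksyn/kdeg) (1 - e^(-kdeg t)); the pool size is constant. The
# measurable "fraction new" P_D / (P + P_D) = 1 - e^(-kdeg t) identifies
# the turnover rate, which in homeostasis equals both the degradation rate
# constant and the per-molar synthesis rate ksyn/[P].

#' Fraction of newly synthesized protein at time t
#'
#' Under first-order turnover at steady state with full labeling of the
#' precursor pool, the labeled ("new") fraction of a protein pool follows a
#' saturating exponential with asymptote 1.
#'
#' @param kdeg Degradation rate constant (per day), `>= 0`.
#' @param t Time since label introduction (days), `>= 0`. Vectorized with
#'   the usual recycling rules.
#' @return Numeric vector of fractions in `[0, 1)`.
#' @examples
#' fraction_new(log(2), 1) # one half-life -> 0.5
#' fraction_new(0.1, c(0, 1, 4, 16, 32))
#' @export
fraction_new <- function(kdeg, t) {
  if (any(kdeg < 0, na.rm = TRUE)) {
    stop("`kdeg` must be non-negative.", call. = FALSE)
  }
  if (any(t < 0, na.rm = TRUE)) {
    stop("`t` must be non-negative.", call. = FALSE)
  }
  1 - exp(-kdeg * t)
}

#' Closed-form labeling trajectory of the unlabeled and labeled pools
#'
#' Solves the labeling kinetics at steady state: unlabeled protein decays
#' exponentially from the steady-state concentration `ksyn / kdeg` while
#' labeled protein accumulates toward it; their sum is constant in time, as
#' homeostasis requires.
#'
#' @param ksyn Zero-order synthesis rate (concentration per day), `>= 0`.
#' @param kdeg Degradation rate constant (per day), strictly positive.
#' @param t Time(s) since label introduction (days), `>= 0`.
#' @return A tibble with columns `t`, `P` (unlabeled), `P_D` (labeled),
#'   one row per time point.
#' @examples
#' concentration_trajectory(10, 0.1, c(0, 1, 4, 16))
#' @export
concentration_trajectory <- function(ksyn, kdeg, t) {
  if (any(ksyn < 0)) stop("`ksyn` must be non-negative.", call. = FALSE)
  if (any(kdeg <= 0)) {
    stop("`kdeg` must be strictly positive (no steady state at kdeg = 0).",
         call. = FALSE)
  }
  if (any(t < 0)) stop("`t` must be non-negative.", call. = FALSE)
  ss <- ksyn / kdeg
  tibble::tibble(
    t   = t,
    P   = ss * exp(-kdeg * t),
    P_D = ss * (1 - exp(-kdeg * t))
  )
}

#' Deuterium-accessible hydrogen counts per amino-acid residue
#'
#' Empirical per-residue numbers of hydrogen positions that exchange with
#' body water during synthesis in rodents, used to compute a peptide's
#' n-value as the sum over its sequence. Values are the literature-derived
#' in vivo accessibility table used by turnover-rate software.
#'
#' @format Named numeric vector over the 20 standard one-letter residue
#'   codes.
#' @export
deuterium_site_counts <- c(
  A = 4.00, R = 3.43, N = 1.89, D = 1.89, C = 1.62,
  E = 3.95, Q = 3.95, G = 2.06, H = 2.88, I = 1.00,
  L = 0.60, K = 0.54, M = 1.12, F = 0.32, P = 2.59,
  S = 2.61, T = 0.20, W = 0.08, Y = 0.42, V = 0.56
)

#' Peptide n-value from its sequence
#'
#' The n-value is the number of deuterium-accessible hydrogen positions on
#' a peptide, the sum of residue-specific counts over the sequence. It is
#' additive under concatenation.
#'
#' @param sequence Character vector of amino-acid sequences (one-letter
#'   codes).
#' @param residue_table Named numeric vector mapping residue to hydrogen
#'   count; defaults to [deuterium_site_counts].
#' @return Numeric vector of n-values (0 for the empty sequence).
#' @examples
#' peptide_n_value("ALAVSK")
#' @export
peptide_n_value <- function(sequence, residue_table = deuterium_site_counts) {
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) == 0) return(0)
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    unknown <- setdiff(res, names(residue_table))
    if (length(unknown) > 0) {
      stop("Unknown residue(s) in sequence: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    }
    sum(residue_table[res])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Maximal relative depletion of the monoisotopic peak at full labeling
#'
#' With each of the n accessible sites independently deuterated at the
#' body-water enrichment, the probability that a peptide carries no
#' deuterium — the M0 isotope peak — is `(1 - enrichment)^n`; the maximal
#' M0 change is its complement. Peptides whose theoretical M0 change falls
#' below a detection floor carry too little labeling signal to support a
#' rate fit.
#'
#' @param n_value Number of deuterium-accessible positions (`>= 0`).
#' @param enrichment Body-water deuterium enrichment as a fraction in
#'   `[0, 1)`; the labeling protocol this package models targets 0.05.
#' @return Numeric vector of maximal M0 changes in `[0, 1)`.
#' @examples
#' theoretical_m0_change(20, 0.05)
#' @export
theoretical_m0_change <- function(n_value, enrichment) {
  if (any(enrichment < 0 | enrichment >= 1)) {
    stop("`enrichment` must be in [0, 1).", call. = FALSE)
  }
  1 - (1 - enrichment)^n_value
}

#' Quality-filter peptide time courses before rate fitting
#'
#' Applies the three peptide-level admission rules: n-value strictly
#' greater than `min_n_value`, sequence length at least
#' `min_peptide_length`, and theoretical M0 change at least
#' `min_m0_change` at the given enrichment. Every rejected peptide carries
#' the full set of reasons it failed.
#'
#' @param courses Tibble of peptide observations with at least columns
#'   `peptide`, `n_value`; `sequence_length` is taken from a
#'   `sequence_length` column if present, else from `nchar(peptide)`.
#' @param enrichment Body-water deuterium enrichment (default 0.05).
#' @param min_n_value Exclusive lower bound on n-value (default 5).
#' @param min_peptide_length Inclusive lower bound on sequence length
#'   (default 6).
#' @param min_m0_change Inclusive lower bound on theoretical M0 change
#'   (default 0.04).
#' @return A list with tibbles `retained` (rows passing all rules) and
#'   `rejected` (one row per rejected peptide with a `reasons` list-column
#'   drawing on the vocabulary `"n_value"`, `"sequence_length"`,
#'   `"m0_change"`).
#' @export
filter_peptides <- function(courses, enrichment = 0.05, min_n_value = 5,
                            min_peptide_length = 6, min_m0_change = 0.04) {
  stopifnot(is.data.frame(courses), all(c("peptide", "n_value") %in% names(courses)))
  peptides <- dplyr::distinct(
    courses,
    .data$peptide,
    n_value = .data$n_value,
    sequence_length = if ("sequence_length" %in% names(courses)) {
      .data$sequence_length
    } else {
      nchar(.data$peptide)
    }
  )
  peptides$m0_change <- theoretical_m0_change(peptides$n_value, enrichment)
  reasons <- purrr::pmap(
    list(peptides$n_value, peptides$sequence_length, peptides$m0_change),
    function(n, len, m0) {
      r <- character(0)
      if (!(n > min_n_value)) r <- c(r, "n_value")
      if (len < min_peptide_length) r <- c(r, "sequence_length")
      if (m0 < min_m0_change) r <- c(r, "m0_change")
      r
    }
  )
  ok <- lengths(reasons) == 0
  rejected <- peptides[!ok, , drop = FALSE]
  rejected$reasons <- reasons[!ok]
  list(
    retained = dplyr::semi_join(courses, peptides[ok, "peptide"], by = "peptide"),
    rejected = tibble::as_tibble(rejected)
  )
}

# Grid-then-golden-section minimization of the pooled SSE over log10(k).
# The SSE of 1 - e^(-k t) against pooled points is smooth and in practice
# unimodal in log k; the coarse scan guards against flat tails.
.fit_rate_ls <- function(t, y, k_lower = 1e-6, k_upper = 20) {
  sse <- function(log10k) sum((y - (1 - exp(-10^log10k * t)))^2)
  grid <- seq(log10(k_lower), log10(k_upper), length.out = 121)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(sse, interval = c(lo, hi), tol = 1e-12)
  k <- 10^opt$minimum
  # a fit pinned in the first grid cell above the lower bound is a zero
  # rate in all but name
  at_floor <- opt$minimum <= grid[2]
  list(k = if (at_floor) 0 else k, sse = opt$objective)
}

#' Fit a pooled turnover rate for one protein and cohort
#'
#' Pools all (time, fraction-new) observations across the protein's
#' retained peptides and fits the single-rate labeling curve
#' `1 - exp(-k t)` (asymptote fixed at 1) by least squares over a bounded
#' positive rate. Fit diagnostics and the pass/fail gates are recorded:
#' the fit passes only if R-squared >= `rsq_min`, more than one unique
#' peptide contributed, the rate is positive, at least
#' `min_nonzero_timepoints` distinct times have a positive fraction-new,
#' and the root-mean-square residual is below `max_rms_deviation`.
#'
#' A nonpositive fitted rate makes the remaining diagnostics meaningless,
#' so it is reported as the sole rejection reason.
#'
#' @param courses Tibble with columns `peptide`, `time_days`,
#'   `fraction_new` for a single protein and cohort (extra columns are
#'   ignored).
#' @param rsq_min,min_unique_peptides,min_nonzero_timepoints,max_rms_deviation
#'   Pass/fail thresholds; defaults are the workflow's standard gates
#'   (0.6, 2, 3, 0.1).
#' @return One-row tibble: `k_turnover`, `r_squared`,
#'   `n_unique_peptides`, `n_nonzero_timepoints`, `rms_deviation`,
#'   `passed`, and a `reject_reasons` list-column over the vocabulary
#'   `"nonpositive_rate"`, `"unique_peptides"`, `"r_squared"`,
#'   `"nonzero_timepoints"`, `"rms_deviation"`.
#' @export
fit_turnover <- function(courses, rsq_min = 0.6, min_unique_peptides = 2,
                         min_nonzero_timepoints = 3,
                         max_rms_deviation = 0.1) {
  stopifnot(is.data.frame(courses),
            all(c("peptide", "time_days", "fraction_new") %in% names(courses)))
  if (nrow(courses) == 0) {
    stop("No retained peptide observations to fit.", call. = FALSE)
  }
  t <- courses$time_days
  y <- courses$fraction_new
  keep <- is.finite(t) & is.finite(y)
  t <- t[keep]; y <- y[keep]

  n_pep <- dplyr::n_distinct(courses$peptide)
  n_nonzero <- dplyr::n_distinct(t[y > 0])

  fit <- .fit_rate_ls(t, y)
  yhat <- 1 - exp(-fit$k * t)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  rsq <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  rms <- sqrt(mean((y - yhat)^2))

  if (fit$k <= 0) {
    reasons <- "nonpositive_rate"
  } else {
    reasons <- character(0)
    if (n_pep < min_unique_peptides) reasons <- c(reasons, "unique_peptides")
    if (!isTRUE(rsq >= rsq_min)) reasons <- c(reasons, "r_squared")
    if (n_nonzero < min_nonzero_timepoints) {
      reasons <- c(reasons, "nonzero_timepoints")
    }
    if (!isTRUE(rms < max_rms_deviation)) reasons <- c(reasons, "rms_deviation")
  }

  tibble::tibble(
    k_turnover = fit$k,
    r_squared = rsq,
    n_unique_peptides = n_pep,
    n_nonzero_timepoints = n_nonzero,
    rms_deviation = rms,
    passed = length(reasons) == 0,
    reject_reasons = list(reasons)
  )
}

#' Fit turnover rates for every protein and cohort in a time-course table
#'
#' Convenience wrapper applying [fit_turnover()] per `protein_id` x
#' `cohort` group of a long peptide time-course tibble.
#'
#' @param courses Tibble with columns `protein_id`, `cohort`, `peptide`,
#'   `time_days`, `fraction_new`.
#' @param ... Thresholds forwarded to [fit_turnover()].
#' @return Tibble with one row per protein and cohort, the columns of
#'   [fit_turnover()] plus `protein_id` and `cohort`.
#' @export
fit_turnover_all <- function(courses, ...) {
  stopifnot(all(c("protein_id", "cohort") %in% names(courses)))
  courses |>
    dplyr::group_by(.data$protein_id, .data$cohort) |>
    dplyr::group_modify(function(d, key) fit_turnover(d, ...)) |>
    dplyr::ungroup()
}

#' Turnover-rate fold changes between cohorts
#'
#' For proteins whose rate fit passed in both cohorts, the turnover fold
#' change is the difference of log2 fitted rates (experimental minus
#' control). Proteins lacking a passing fit in either cohort are omitted,
#' so the turnover set is typically smaller than the abundance set.
#'
#' @param fits Tibble from [fit_turnover_all()].
#' @param experimental,control Cohort labels to contrast.
#' @return Tibble with `protein_id` and `fc_log2`.
#' @export
turnover_fold_changes <- function(fits, experimental, control) {
  stopifnot(all(c("protein_id", "cohort", "k_turnover", "passed") %in% names(fits)))
  passing <- dplyr::filter(fits, .data$passed,
                           .data$cohort %in% c(experimental, control))
  if (any(passing$k_turnover <= 0)) {
    stop("Internal error: nonpositive rate among passing fits.", call. = FALSE)
  }
  wide <- passing |>
    dplyr::select("protein_id", "cohort", "k_turnover") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "k_turnover")
  if (!all(c(experimental, control) %in% names(wide))) {
    return(tibble::tibble(protein_id = character(0), fc_log2 = numeric(0)))
  }
  wide |>
    dplyr::filter(!is.na(.data[[experimental]]), !is.na(.data[[control]])) |>
    dplyr::transmute(
      protein_id = .data$protein_id,
      fc_log2 = log2(.data[[experimental]]) - log2(.data[[control]])
    )
}
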