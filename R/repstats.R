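#' Replication statistics: confidence intervals and half-widths
#'
#' Standard Student-t machinery for replication-averaged measures. For a
#' measure with across-replication mean `m`, sample SD `s` and `n`
#' replications, the 95% confidence interval is
#' `m -/+ t(n-1, 0.975) * s / sqrt(n)` and the half-width is the `+/-` term.
#'
#' @param mean Across-replication mean.
#' @param sd Sample standard deviation (n - 1 denominator).
#' @param n Number of replications (>= 2).
#' @param alpha Significance level (default 0.05 for 95% confidence).
#' @return `confidence_interval()`: numeric `c(low, high)`;
#'   `half_width()`: the half-width.
#' @examples
#' half_width(16.34, 30)   # ~6.1
#' @export
confidence_interval <- function(mean, sd, n, alpha = 0.05) {
  h <- half_width(sd, n, alpha)
  c(low = mean - h, high = mean + h)
}

#' @rdname confidence_interval
#' @export
half_width <- function(sd, n, alpha = 0.05) {
  check_number(n, "n", min = 2)
  check_number(sd, "sd", min = 0)
  check_number(alpha, "alpha", positive = TRUE)
  qt(1 - alpha / 2, df = n - 1) * sd / sqrt(n)
}

#' Required replication count for a target half-width
#'
#' Sequential replication sizing: from a pilot of `n0` replications with
#' observed half-width `h0`, the number of replications needed to reach a
#' target half-width `h` is approximately `n0 * h0^2 / h^2`, rounded up.
#' In the case study the pilot (30 replications, half-width 6.1 around an
#' outpatient mean of 351.7) requires more than 89 replications to bring the
#' coefficient of variation below 0.01; the experiments then over-provision
#' to 110.
#'
#' @param n0 Pilot replication count.
#' @param h0 Pilot half-width.
#' @param h_target Desired half-width (> 0).
#' @return Integer replication count (ceiling).
#' @examples
#' required_replications(30, 6.1, 0.01 * 351.7)  # 91
#' @export
required_replications <- function(n0, h0, h_target) {
  check_number(n0, "n0", positive = TRUE)
  check_number(h0, "h0", positive = TRUE)
  check_number(h_target, "h_target", positive = TRUE)
  as.integer(ceiling(n0 * h0^2 / h_target^2))
}

#' Coefficient of variation of a replication estimate
#'
#' The precision criterion used for replication sizing: the confidence
#' half-width divided by the mean (e.g. 6.1 / 351.7 = 1.73%).
#'
#' @param half_width Confidence half-width (>= 0).
#' @param mean Measure mean (> 0).
#' @return `half_width / mean`.
#' @export
cv <- function(half_width, mean) {
  check_number(half_width, "half_width", min = 0)
  check_number(mean, "mean", positive = TRUE)
  half_width / mean
}

#' Across-room workload mean and spread
#'
#' Summarizes the balance of technologist workload: the arithmetic mean and
#' sample standard deviation (n - 1 denominator) of the six per-room
#' utilization percentages, reported to two decimals as in the comparison
#' tables.
#'
#' @param utilizations Numeric vector of exactly six utilization
#'   percentages.
#' @return List with `mean` and `sd`, each rounded to 2 decimals.
#' @examples
#' workload_sd(c(71.39, 69.97, 69.44, 68.02, 68.93, 67.49))
#' @export
workload_sd <- function(utilizations) {
  if (length(utilizations) != 6L) {
    stop_input("`utilizations` must contain exactly six values (got %d).",
               length(utilizations))
  }
  list(mean = round(mean(utilizations), 2), sd = round(sd(utilizations), 2))
}

#' Validate an experiment against reference counts
#'
#' The validation-by-confidence-interval procedure: a reference value (e.g.
#' the hospital's observed 5-day patient volume) passes when it falls inside
#' the simulated measure's 95% confidence interval. Reference measures the
#' experiment did not record are reported as not evaluated, never as a
#' silent pass.
#'
#' @param experiment A `uf_experiment`.
#' @param reference Named numeric vector; names must match measure names in
#'   the experiment summary (e.g. `n_outpatient`, `n_inpatient`).
#' @return Tibble with one row per reference measure: `measure`,
#'   `reference`, `mean`, `ci_low`, `ci_high`, `pass` (NA when the measure
#'   was not evaluated).
#' @export
validate_against_reference <- function(experiment, reference) {
  if (!inherits(experiment, "uf_experiment")) {
    stop_input("`experiment` must come from run_experiment().")
  }
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    stop_input("`reference` must be a fully named numeric vector.")
  }
  s <- experiment$summary
  purrr::map_dfr(names(reference), function(m) {
    ref <- reference[[m]]
    row <- s[s$measure == m, ]
    if (nrow(row) == 0L) {
      tibble::tibble(measure = m, reference = ref,
                     mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                     pass = NA)
    } else {
      tibble::tibble(measure = m, reference = ref,
                     mean = row$mean, ci_low = row$ci_low, ci_high = row$ci_high,
                     pass = ref >= row$ci_low & ref <= row$ci_high)
    }
  })
}
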