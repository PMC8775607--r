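#' Tidy an experiment
#'
#' @param x A `uf_experiment`.
#' @param ... Unused.
#' @return The per-measure summary tibble: `measure`, `mean`, `sd`, `n`,
#'   `half_width`, `ci_low`, `ci_high`, `cv`.
#' @export
tidy.uf_experiment <- function(x, ...) {
  x$summary
}

#' One-row summary of an experiment
#'
#' @param x A `uf_experiment`.
#' @param ... Unused.
#' @return One-row tibble: policy, replication count, mean total examined,
#'   overall mean wait, mean workload and workload SD (percent).
#' @export
glance.uf_experiment <- function(x, ...) {
  s <- x$summary
  g <- function(m) {
    row <- s[s$measure == m, ]
    if (nrow(row)) row$mean else NA_real_
  }
  tibble::tibble(policy = x$policy, n_reps = x$n_reps,
                 total_examined = g("n_all"), mean_wait = g("wait_all"),
                 workload_mean = x$workload$mean, workload_sd = x$workload$sd)
}

#' Tidy an optimization scan
#'
#' @param x A `uf_optimization`.
#' @param ... Unused.
#' @return The candidate results tibble.
#' @export
tidy.uf_optimization <- function(x, ...) {
  x$results
}

#' One-row summary of an optimization scan
#'
#' @param x A `uf_optimization`.
#' @param ... Unused.
#' @return One-row tibble with candidate/feasible counts and the best
#'   candidate's settings and objective (NA when infeasible throughout).
#' @export
glance.uf_optimization <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$results), n_feasible = nrow(x$feasible),
    best_interval = if (is.null(x$best)) NA_real_ else x$best$interval,
    best_batch = if (is.null(x$best)) NA_real_ else x$best$batch,
    best_policy = if (is.null(x$best)) NA_character_ else x$best$policy,
    best_objective = if (is.null(x$best)) NA_real_ else x$best$objective)
}

#' Plot per-room utilization of an experiment
#'
#' @param object A `uf_experiment`.
#' @param ... Unused.
#' @return A ggplot: per-room mean utilization with 95% confidence
#'   half-width error bars.
#' @export
autoplot.uf_experiment <- function(object, ...) {
  d <- object$room_summary
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$room), y = .data$mean * 100)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = (.data$mean - .data$half_width) * 100,
                                        ymax = (.data$mean + .data$half_width) * 100),
                           width = 0.2) +
    ggplot2::labs(x = "Examination room", y = "Utilization (%)",
                  title = sprintf("Room workload (%s policy, %d replications)",
                                  object$policy, object$n_reps)) +
    ggplot2::theme_minimal()
}

#' Plot the warm-up diagnostic
#'
#' @param object A `uf_warmup` tibble from [warmup_scan()].
#' @param ... Unused.
#' @return A ggplot of running utilization over simulated time, one line
#'   per room.
#' @export
autoplot.uf_warmup <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$utilization,
                                       colour = factor(.data$room))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Simulated time (min)", y = "Running utilization",
                  colour = "Room") +
    ggplot2::theme_minimal()
}

#' Plot an optimization scan
#'
#' @param object A `uf_optimization`.
#' @param ... Unused.
#' @return A ggplot of the objective against the appointment interval,
#'   feasible candidates highlighted.
#' @export
autoplot.uf_optimization <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$interval, y = .data$objective,
                               colour = .data$feasible, shape = factor(.data$batch))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Appointment interval (min)",
                  y = "Class-weighted mean wait (min)",
                  colour = "Feasible", shape = "Batch") +
    ggplot2::theme_minimal()
}
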