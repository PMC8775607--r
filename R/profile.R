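#' Hospital profiles
#'
#' A `uf_profile` bundles everything the simulator needs to know about a
#' department: the patient classes and their arrival processes, the
#' examination catalogue (slot rules, service-time laws, sex constraints),
#' the room layout with its fixed technologist sexes, the setup-phase
#' distribution, and the calendar.
#'
#' @param classes Named list of patient-class configurations
#'   (see [patient_class()]).
#' @param exams Named list of exam types (see [exam_type()]).
#' @param rooms A tibble with columns `id` (integer) and `tech_sex`
#'   (`"M"`/`"F"`).
#' @param priority Named list giving the priority room id for `inpatient`
#'   and/or `emergency` patients (a spacious room that takes the patient
#'   directly whenever nobody is waiting there), or `NULL`.
#' @param setup_spec [uf_dist] for the setup phase (entry to first image).
#' @param calendar A [calendar_config()].
#' @return A validated `uf_profile`.
#' @seealso [default_profile()] for the shipped synthetic case hospital.
#' @export
hospital_profile <- function(classes, exams, rooms,
                             priority = NULL,
                             setup_spec = dist_triangular(1, 5, 9),
                             calendar = calendar_config()) {
  prof <- structure(
    list(classes = classes, exams = exams, rooms = tibble::as_tibble(rooms),
         priority = priority, setup_spec = setup_spec, calendar = calendar),
    class = "uf_profile")
  validate_profile(prof)
}

validate_profile <- function(prof) {
  if (!all(c("id", "tech_sex") %in% names(prof$rooms))) {
    stop_input("`rooms` needs columns id and tech_sex.")
  }
  if (anyDuplicated(prof$rooms$id)) stop_input("room ids must be unique.")
  if (!all(prof$rooms$tech_sex %in% c("M", "F"))) {
    stop_input("`tech_sex` must be \"M\" or \"F\".")
  }
  for (nm in names(prof$priority %||% list())) {
    if (!prof$priority[[nm]] %in% prof$rooms$id) {
      stop_input("priority room for %s (%d) is not in the layout.", nm, prof$priority[[nm]])
    }
  }
  mix <- vapply(prof$exams, function(e) e$share, 0)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop_input("exam shares must sum to 1 within 1e-9 (sum is %.12g).", sum(mix))
  }
  for (cl in prof$classes) {
    if (!cl$class %in% c("outpatient", "inpatient", "emergency")) {
      stop_input("unknown patient class '%s'.", cl$class)
    }
  }
  validate_dist(prof$setup_spec)
  shr <- vapply(prof$classes, function(cl) cl$share, 0)
  if (abs(sum(shr) - 1) > 1e-6) {
    stop_input("class shares must sum to 1 (sum is %.12g).", sum(shr))
  }
  prof
}

#' Examination types
#'
#' Describes one body-part examination: the scheduling slot rule
#' (`"fixed20"`, `"fixed40"`, or `"dvt_split"` — 20 min with probability 0.7,
#' 40 min otherwise), the service-time law for the actual scanning phase
#' (setup excluded), the technologist sex constraint (`"none"`,
#' `"male_tech_only"` for intimate male exams, `"same_sex_tech"` for deep
#' vein thrombosis), and the exam's share of the case mix. Weighted
#' examination points are derived from the mean scanning time via
#' [weighted_points()] with the 5-minute mean setup phase.
#'
#' @param name Exam label.
#' @param share Probability of this exam in the case mix.
#' @param slot_rule One of `"fixed20"`, `"fixed40"`, `"dvt_split"`.
#' @param service_spec [uf_dist] for the scanning time, minutes.
#' @param sex_constraint One of `"none"`, `"male_tech_only"`,
#'   `"same_sex_tech"`.
#' @return A `uf_exam` list.
#' @export
exam_type <- function(name, share, slot_rule, service_spec,
                      sex_constraint = "none") {
  slot_rule <- match.arg(slot_rule, c("fixed20", "fixed40", "dvt_split"))
  sex_constraint <- match.arg(sex_constraint, c("none", "male_tech_only", "same_sex_tech"))
  check_number(share, "share", positive = TRUE)
  validate_dist(service_spec)
  structure(list(
    name = name, share = share, slot_rule = slot_rule,
    service_spec = service_spec, sex_constraint = sex_constraint,
    mean_minutes = dist_mean(service_spec),
    weighted_points = weighted_points(dist_mean(service_spec))
  ), class = "uf_exam")
}

#' Patient-class configurations
#'
#' One entry per class of patient (outpatient, inpatient, emergency): how
#' they arrive (a renewal process with a given inter-arrival law, or a
#' scheduled appointment stream of `batch` patients every `interval`
#' minutes), their share of the overall case mix, and the probability that a
#' patient of this class is male (overall and conditional on a DVT exam,
#' where the case hospital sees a 3:4 male-to-female ratio).
#'
#' @param class `"outpatient"`, `"inpatient"`, or `"emergency"`.
#' @param share Share of the total case mix (reporting only).
#' @param arrival_model `"renewal"` or `"scheduled"`.
#' @param arrival_spec [uf_dist] of inter-arrival times (renewal model).
#' @param interval,batch Appointment interval (minutes) and batch size
#'   (scheduled model).
#' @param p_male Probability a patient is male.
#' @param p_male_dvt Probability a DVT patient is male (default 3/7).
#' @return A `uf_class` list.
#' @export
patient_class <- function(class, share, arrival_model = c("renewal", "scheduled"),
                          arrival_spec = NULL, interval = NULL, batch = 1L,
                          p_male = 0.5, p_male_dvt = 3 / 7) {
  arrival_model <- match.arg(arrival_model)
  if (arrival_model == "renewal") {
    validate_dist(arrival_spec)
    if (dist_mean(arrival_spec) <= 0) stop_input("arrival_spec needs a positive mean.")
  } else {
    check_number(interval, "interval", positive = TRUE)
    check_number(batch, "batch", min = 1)
  }
  if (p_male < 0 || p_male > 1 || p_male_dvt < 0 || p_male_dvt > 1) {
    stop_input("sex-mix probabilities must lie in [0, 1].")
  }
  structure(list(class = class, share = share, arrival_model = arrival_model,
                 arrival_spec = arrival_spec, interval = interval,
                 batch = as.integer(batch), p_male = p_male,
                 p_male_dvt = p_male_dvt),
            class = "uf_class")
}

#' Simulation calendar
#'
#' The simulated clock is continuous and compressed: one effective day is
#' 447.36 minutes (480 minutes of schedule times the 93.2% share spent on
#' the body parts in scope), a replication observes 5 effective days
#' (2236.8 min), and statistics start after a 5600-minute warm-up, giving
#' the default replication length 7836.8 min. Day boundaries exist only for
#' reporting; there is no explicit lunch break or overnight gap.
#'
#' @param effective_day_minutes Effective minutes per day (default 447.36).
#' @param days_per_replication Days measured per replication (default 5).
#' @param warmup_minutes Warm-up excluded from statistics (default 5600).
#' @return A `uf_calendar` list with derived `measured_minutes` and
#'   `replication_minutes`.
#' @export
calendar_config <- function(effective_day_minutes = 447.36,
                            days_per_replication = 5,
                            warmup_minutes = 5600) {
  check_number(effective_day_minutes, "effective_day_minutes", positive = TRUE)
  check_number(days_per_replication, "days_per_replication", positive = TRUE)
  check_number(warmup_minutes, "warmup_minutes", min = 0)
  measured <- effective_day_minutes * days_per_replication
  structure(list(
    effective_day_minutes = effective_day_minutes,
    days_per_replication = days_per_replication,
    warmup_minutes = warmup_minutes,
    measured_minutes = measured,
    replication_minutes = warmup_minutes + measured
  ), class = "uf_calendar")
}

#' The synthetic case-hospital profile
#'
#' Builds the stand-in for the studied department: six examination rooms
#' (ids 5-10; female technologists in 5, 7, 9 and male in 6, 8, 10, with
#' inpatients prioritized into room 5 and emergency patients into room 6),
#' three patient classes with the reported case-mix shares
#' 72.46 / 19.98 / 7.57%, and arrival processes calibrated so a 5-day
#' measured window expects 355.3 outpatients, 93.0 inpatients, and 37.9
#' emergency patients. Inter-arrival stand-ins are exponential because the
#' hospital's empirical inter-arrival data are unpublished; users with data
#' can substitute [dist_empirical()] specs.
#'
#' The exam catalogue carries the fitted prostate scanning-time mixture
#' (the only published service distribution) plus documented synthetic
#' stand-ins for the rest: means within 15-25 min for 20-minute-slot exams
#' and 30-45 min for 40-minute-slot exams, with the shoulder mean pinned at
#' the reported 16.35 min. The inpatient and emergency body-part mix reuses
#' the outpatient mix (not separately published).
#'
#' @param calendar A [calendar_config()].
#' @return A `uf_profile`.
#' @examples
#' prof <- default_profile()
#' class_shares(prof)
#' @export
default_profile <- function(calendar = calendar_config()) {
  # weekly volumes fixed by the validation data; shares from the case-mix
  # table. Rates are absolute (per reference 5-day week of effective time),
  # not rescaled by the calendar in use.
  week_minutes <- 447.36 * 5
  vol <- c(outpatient = 355.3, inpatient = 93.0, emergency = 37.9)
  shares <- c(outpatient = 72.46, inpatient = 19.98, emergency = 7.57)
  shares <- shares / sum(shares)

  classes <- list(
    outpatient = patient_class("outpatient", shares[["outpatient"]],
      arrival_spec = dist_exponential(week_minutes / vol[["outpatient"]])),
    inpatient = patient_class("inpatient", shares[["inpatient"]],
      arrival_spec = dist_exponential(week_minutes / vol[["inpatient"]])),
    emergency = patient_class("emergency", shares[["emergency"]],
      arrival_spec = dist_exponential(week_minutes / vol[["emergency"]]))
  )

  exams <- list(
    abdomen = exam_type("abdomen", 0.38, "fixed20",
      dist_weibull_scaled(offset = 8, scale = 8, shape = 1.6)),
    liver = exam_type("liver", 0.12, "fixed40",
      dist_weibull_scaled(offset = 20, scale = 13.5, shape = 1.8)),
    dvt = exam_type("dvt", 0.07, "dvt_split",
      dist_mixture(c(0.7, 0.3), list(
        dist_weibull_scaled(offset = 8, scale = 8, shape = 1.6),
        dist_weibull_scaled(offset = 18, scale = 13.5, shape = 1.8))),
      sex_constraint = "same_sex_tech"),
    prostate = exam_type("prostate", 0.04, "fixed20",
      prostate_service_spec(), sex_constraint = "male_tech_only"),
    scrotum = exam_type("scrotum", 0.02, "fixed20",
      dist_triangular(8, 14, 23), sex_constraint = "male_tech_only"),
    shoulder = exam_type("shoulder", 0.10, "fixed20",
      dist_triangular(9, 15, 25.05)),
    other = exam_type("other", 0.27, "fixed20",
      dist_empirical(c(5, 10, 15, 20, 30), c(0, 0.25, 0.55, 0.80, 1)))
  )

  rooms <- tibble::tibble(id = 5:10,
                          tech_sex = c("F", "M", "F", "M", "F", "M"))

  hospital_profile(classes, exams, rooms,
                   priority = list(inpatient = 5L, emergency = 6L),
                   setup_spec = dist_triangular(1, 5, 9),
                   calendar = calendar)
}

#' The fitted prostate scanning-time mixture
#'
#' The published hybrid distribution for outpatient prostate scanning times:
#' `0.485 (3 + 7 Beta(1.9, 1.16)) + 0.424 (10 + Weib(3.46, 1.23)) +
#' 0.091 (20 + Weib(6.99, 1.29))` minutes, Weibull written (scale, shape).
#' Its support starts at 3 minutes.
#'
#' @return A [uf_dist] mixture.
#' @export
prostate_service_spec <- function() {
  dist_mixture(c(0.485, 0.424, 0.091), list(
    dist_beta_scaled(offset = 3, scale = 7, shape1 = 1.9, shape2 = 1.16),
    dist_weibull_scaled(offset = 10, scale = 3.46, shape = 1.23),
    dist_weibull_scaled(offset = 20, scale = 6.99, shape = 1.29)
  ))
}

#' Class shares of a profile
#'
#' @param profile A `uf_profile`.
#' @return Named numeric vector of normalized class shares.
#' @export
class_shares <- function(profile) {
  vapply(profile$classes, function(cl) cl$share, 0)
}

#' Deterministic scheduled appointment arrivals
#'
#' Appointment epochs at `0, interval, 2*interval, ...` strictly below
#' `horizon`, each repeated `batch` times (batch members share a timestamp
#' and are registered in generation order).
#'
#' @param interval Minutes between appointment epochs (> 0).
#' @param batch Patients per epoch (>= 1).
#' @param horizon Minutes of schedule to generate.
#' @return Sorted numeric vector of arrival times.
#' @examples
#' length(gen_scheduled_arrivals(18, 3, 447.36))  # 75
#' @export
gen_scheduled_arrivals <- function(interval, batch, horizon) {
  check_number(interval, "interval", positive = TRUE)
  check_number(batch, "batch", min = 1)
  check_number(horizon, "horizon", min = 0)
  if (horizon <= 0) return(numeric(0))
  # exact multiples, strictly below the horizon (seq() fuzz would admit it)
  epochs <- (seq_len(ceiling(horizon / interval)) - 1) * interval
  epochs <- epochs[epochs < horizon]
  rep(epochs, each = as.integer(batch))
}

#' Renewal-process arrivals
#'
#' Cumulative sums of inter-arrival draws from `spec`, truncated at
#' `horizon`; reproducible per stream.
#'
#' @param spec [uf_dist] of inter-arrival times with positive mean.
#' @param horizon Minutes to generate.
#' @param stream A [rand_stream()].
#' @return Sorted numeric vector of arrival times in (0, horizon].
#' @export
gen_renewal_arrivals <- function(spec, horizon, stream) {
  validate_dist(spec)
  m <- dist_mean(spec)
  if (m <= 0) stop_input("inter-arrival spec must have positive mean.")
  if (dist_quantile(spec, 0) < 0) stop_input("inter-arrival spec must be non-negative.")
  check_number(horizon, "horizon", min = 0)
  if (horizon == 0) return(numeric(0))
  times <- numeric(0)
  last <- 0
  repeat {
    n_block <- max(16L, ceiling((horizon - last) / m * 1.25) + 8L)
    gaps <- sample_dist(spec, n_block, stream)
    block <- last + cumsum(gaps)
    times <- c(times, block)
    last <- block[length(block)]
    if (last >= horizon) break
    if (all(gaps == 0)) stop_input("inter-arrival spec generates zero gaps.")
  }
  times[times <= horizon]
}

#' Slot allocation for one examination
#'
#' Applies the scheduler's slot rule: liver-style `fixed40` exams get the
#' 40-minute double slot (2 points), `dvt_split` exams get 20 minutes with
#' probability 0.7 and 40 minutes otherwise, and everything else gets the
#' standard 20-minute slot (1 point).
#'
#' @param exam A [exam_type()] object.
#' @param stream A [rand_stream()] (used only for `dvt_split`).
#' @return List with `slot_minutes` (20 or 40) and `base_points` (1 or 2).
#' @export
allocate_slots <- function(exam, stream = rand_stream(0, "dvt_slot")) {
  if (!inherits(exam, "uf_exam")) stop_input("`exam` must be a uf_exam.")
  slot <- switch(exam$slot_rule,
    fixed20 = 20,
    fixed40 = 40,
    dvt_split = if (draw_stream(stream, function() runif(1)) < 0.7) 20 else 40,
    stop_input("unknown slot_rule '%s'.", exam$slot_rule))
  list(slot_minutes = slot, base_points = slot / 20)
}

#' Weighted examination points
#'
#' The fairness-oriented workload currency: the exam's mean scanning time
#' and the mean setup time are each divided by the 20-minute baseline slot,
#' rounded half-up to one decimal, and summed. The reported example — a
#' 16.35-minute mean shoulder scan with the 5-minute setup — yields
#' 0.8 + 0.3 = 1.1 points.
#'
#' @param mean_exam_minutes Mean scanning time of the exam, minutes.
#' @param setup_minutes Mean setup time (default 5).
#' @param base Baseline slot length (default 20).
#' @return Weighted points (one-decimal resolution).
#' @examples
#' weighted_points(16.35)  # 1.1
#' @export
weighted_points <- function(mean_exam_minutes, setup_minutes = 5, base = 20) {
  check_number(mean_exam_minutes, "mean_exam_minutes", positive = TRUE)
  check_number(setup_minutes, "setup_minutes", positive = TRUE)
  check_number(base, "base", positive = TRUE)
  round_half_up(mean_exam_minutes / base, 1) + round_half_up(setup_minutes / base, 1)
}

#' @export
print.uf_profile <- function(x, ...) {
  cat(sprintf("<uf_profile: %d classes, %d exam types, %d rooms>\n",
              length(x$classes), length(x$exams), nrow(x$rooms)))
  cat("  classes:", paste(sprintf("%s (%.4f)", names(x$classes),
                                  class_shares(x)), collapse = ", "), "\n")
  cat("  exams:  ", paste(names(x$exams), collapse = ", "), "\n")
  cat(sprintf("  calendar: %.2f min/day x %g days + %g min warm-up\n",
              x$calendar$effective_day_minutes, x$calendar$days_per_replication,
              x$calendar$warmup_minutes))
  invisible(x)
}

#' Exam catalogue as a tibble
#'
#' @param profile A `uf_profile`.
#' @return Tibble with one row per exam type.
#' @export
exam_catalogue <- function(profile) {
  purrr::map_dfr(profile$exams, function(e) tibble::tibble(
    exam = e$name, share = e$share, slot_rule = e$slot_rule,
    sex_constraint = e$sex_constraint, mean_minutes = e$mean_minutes,
    weighted_points = e$weighted_points,
    service = format_dist(e$service_spec)))
}
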