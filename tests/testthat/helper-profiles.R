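# Shared fixture profiles, built in code.

# Single room, Poisson arrivals, exponential scanning, no setup phase:
# the textbook M/M/1 queue (Wq = rho / (mu - lambda)).
mm1_profile <- function(arrival_mean = 30, service_mean = 20) {
  hospital_profile(
    classes = list(outpatient = patient_class(
      "outpatient", 1, arrival_spec = dist_exponential(arrival_mean))),
    exams = list(generic = exam_type(
      "generic", 1, "fixed20", dist_exponential(service_mean))),
    rooms = tibble::tibble(id = 1L, tech_sex = "F"),
    priority = NULL,
    setup_spec = dist_deterministic(0))
}

# The case-hospital stand-in on a reduced calendar for fast unit tests:
# one measured day after a short warm-up.
tiny_calendar <- function() calendar_config(447.36, 1, 500)

tiny_profile <- function() default_profile(tiny_calendar())

# Lighter-loaded variant (arrival rates scaled down ~25%) so short windows
# leave the rooms unsaturated and policy differences remain visible.
light_profile <- function(factor = 1.35) {
  prof <- tiny_profile()
  for (nm in names(prof$classes)) {
    cl <- prof$classes[[nm]]
    prof$classes[[nm]] <- patient_class(
      cl$class, cl$share,
      arrival_spec = dist_exponential(dist_mean(cl$arrival_spec) * factor),
      p_male = cl$p_male, p_male_dvt = cl$p_male_dvt)
  }
  prof
}

# Event-log invariants that must hold on every run: chronology along each
# patient's path, non-negative waits, and the technologist sex constraint.
expect_valid_event_log <- function(patients, profile) {
  expect_true(all(patients$arrival <= patients$room_entry))
  expect_true(all(patients$room_entry <= patients$first_image))
  expect_true(all(patients$first_image <= patients$completion + 1e-9))
  expect_true(all(patients$wait >= 0))
  tech <- setNames(profile$rooms$tech_sex, profile$rooms$id)
  male_only <- patients$sex_constraint == "male_tech_only"
  same_sex <- patients$sex_constraint == "same_sex_tech"
  expect_true(all(tech[as.character(patients$room[male_only])] == "M"))
  expect_true(all(tech[as.character(patients$room[same_sex])] ==
                    patients$sex[same_sex]))
  invisible(TRUE)
}

# Conservation over the measured window: every measured arrival either
# completed by the horizon or was still in the system at the end.
expect_conservation <- function(rep_result) {
  p <- rep_result$patients
  horizon <- rep_result$calendar$replication_minutes
  m <- p[p$measured, ]
  expect_identical(nrow(m),
                   sum(m$completion <= horizon) + sum(m$completion > horizon))
  expect_equal(sum(rep_result$rooms$n_assigned), nrow(m))
  expect_equal(sum(rep_result$rooms$points), sum(m$base_points))
}
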