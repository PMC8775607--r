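rooms_with <- function(points = 0, minutes = 0, weighted = 0, queue = 0L) {
  tibble::tibble(id = 5:10, tech_sex = c("F", "M", "F", "M", "F", "M"),
                 queue_len = rep_len(queue, 6), points = rep_len(points, 6),
                 minutes = rep_len(minutes, 6),
                 weighted_points = rep_len(weighted, 6))
}

test_that("eligibility respects technologist sex constraints", {
  rooms <- default_profile()$rooms
  expect_setequal(eligible_rooms(list(sex = "M", sex_constraint = "male_tech_only"), rooms),
                  c(6L, 8L, 10L))
  expect_setequal(eligible_rooms(list(sex = "M", sex_constraint = "same_sex_tech"), rooms),
                  c(6L, 8L, 10L))
  expect_setequal(eligible_rooms(list(sex = "F", sex_constraint = "same_sex_tech"), rooms),
                  c(5L, 7L, 9L))
  expect_setequal(eligible_rooms(list(sex = "M", sex_constraint = "none"), rooms), 5:10)
  expect_error(eligible_rooms(list(sex = "F", sex_constraint = "male_tech_only"), rooms),
               "female")
})

test_that("the dispatcher picks the criterion-minimal eligible room", {
  rooms <- rooms_with()
  rooms$points <- c(1, 5, 1, 3, 1, 7)  # rooms 6/8/10 hold 5/3/7
  pat <- list(class = "outpatient", sex = "M", sex_constraint = "male_tech_only")
  expect_identical(assign_room(pat, rooms, "points"), 8L)
  # all counters equal: lowest eligible room id
  expect_identical(assign_room(pat, rooms_with(points = 2), "points"), 6L)
  expect_identical(assign_room(list(class = "outpatient", sex = "F",
                                    sex_constraint = "none"),
                               rooms_with(), "points"), 5L)
})

test_that("inpatients and emergency patients take their idle priority room", {
  pat_in <- list(class = "inpatient", sex = "F", sex_constraint = "none")
  # queue empty: room 5 even when its counter is the worst
  rooms <- rooms_with()
  rooms$points <- c(99, 0, 0, 0, 0, 0)
  expect_identical(assign_room(pat_in, rooms, "points"), 5L)
  # someone waiting in room 5: fall back to the minimal room over all
  rooms$queue_len <- c(1L, 0L, 0L, 0L, 0L, 0L)
  expect_identical(assign_room(pat_in, rooms, "points"), 6L)
  pat_em <- list(class = "emergency", sex = "M", sex_constraint = "none")
  rooms2 <- rooms_with()
  rooms2$points <- c(0, 99, 0, 0, 0, 0)
  expect_identical(assign_room(pat_em, rooms2, "points"), 6L)
  # a constrained inpatient goes through the sex branch first
  pat_con <- list(class = "inpatient", sex = "M", sex_constraint = "same_sex_tech")
  expect_identical(assign_room(pat_con, rooms_with(), "points"), 6L)
})

test_that("the random policy is reproducible, in-bounds, and branch-preserving", {
  pat <- list(class = "outpatient", sex = "M", sex_constraint = "male_tech_only")
  picks <- vapply(1:50, function(i) {
    assign_room(pat, rooms_with(), "random", stream = rand_stream(i, "pol"))
  }, 0L)
  expect_true(all(picks %in% c(6L, 8L, 10L)))
  expect_gt(length(unique(picks)), 1)
  expect_identical(picks,
                   vapply(1:50, function(i) {
                     assign_room(pat, rooms_with(), "random", stream = rand_stream(i, "pol"))
                   }, 0L))
  # priority branch still short-circuits under the random policy
  pat_in <- list(class = "inpatient", sex = "F", sex_constraint = "none")
  expect_identical(assign_room(pat_in, rooms_with(), "random",
                               stream = rand_stream(1, "pol")), 5L)
  expect_error(assign_room(pat, rooms_with(), "random"), "stream")
})

test_that("all three balance counters are updated at assignment", {
  rooms <- rooms_with()
  dvt40 <- list(base_points = 2, service_minutes = 36.5, weighted_points = 1.3)
  rooms <- update_criterion(rooms, 8L, dvt40)
  expect_equal(rooms$points[rooms$id == 8], 2)
  expect_equal(rooms$minutes[rooms$id == 8], 36.5)
  expect_equal(rooms$weighted_points[rooms$id == 8], 1.3)
  shoulder <- list(base_points = 1, service_minutes = 21, weighted_points = 1.1)
  rooms <- update_criterion(rooms, 8L, shoulder)
  expect_equal(rooms$weighted_points[rooms$id == 8], 2.4)
  expect_true(all(rooms$points[rooms$id != 8] == 0))
  expect_error(update_criterion(rooms, 99L, shoulder), "not in the layout")
})

test_that("greedy minute-balancing keeps room loads within one service draw", {
  # single class, one exam type, no constraints: the minutes criterion never
  # lets max - min of the room counters exceed the largest single service
  prof <- hospital_profile(
    classes = list(outpatient = patient_class(
      "outpatient", 1, arrival_spec = dist_exponential(4))),
    exams = list(generic = exam_type("generic", 1, "fixed20",
                                     dist_weibull_scaled(8, 8, 1.6))),
    rooms = default_profile()$rooms,
    priority = NULL, setup_spec = dist_triangular(1, 5, 9))
  r <- run_replication(prof, "minutes", calendar_config(400, 1, 0), seed = 2)
  spread <- max(r$rooms$cum_minutes) - min(r$rooms$cum_minutes)
  expect_lte(spread, max(r$patients$service_minutes))
})

test_that("every assignment stays within the eligible room set", {
  prof <- tiny_profile()
  for (pol in uf_policies) {
    r <- run_replication(prof, pol, seed = 31)
    expect_valid_event_log(r$patients, prof)
  }
})
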