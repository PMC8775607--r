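test_that("an idle system serves a lone patient with zero wait", {
  prof <- mm1_profile()
  prof$classes$outpatient <- patient_class("outpatient", 1, "scheduled",
                                           interval = 1000, batch = 1)
  r <- run_replication(prof, "points", calendar_config(500, 1, 0), seed = 1)
  expect_identical(nrow(r$patients), 1L)
  expect_equal(r$patients$wait, 0)
  expect_equal(r$patients$room_entry, r$patients$arrival)
})

test_that("replications are deterministic in their seed", {
  prof <- tiny_profile()
  r1 <- run_replication(prof, "points", seed = 9)
  r2 <- run_replication(prof, "points", seed = 9)
  expect_equal(r1$patients, r2$patients)
  expect_equal(r1$rooms, r2$rooms)
  r3 <- run_replication(prof, "points", seed = 10)
  expect_false(isTRUE(all.equal(r1$patients$arrival, r3$patients$arrival)))
})

test_that("measured-window conservation holds across policies", {
  prof <- tiny_profile()
  for (pol in c("points", "minutes", "random")) {
    r <- run_replication(prof, pol, seed = 13)
    expect_conservation(r)
  }
})

test_that("the queue mechanics match an independent Lindley recursion", {
  # single FIFO server: W(k) = max(0, W(k-1) + S(k-1) - gap(k))
  prof <- mm1_profile(arrival_mean = 25, service_mean = 20)
  r <- run_replication(prof, "points", calendar_config(500, 1, 0), seed = 6)
  p <- r$patients
  expect_gt(nrow(p), 5)
  w <- numeric(nrow(p))
  for (k in 2:nrow(p)) {
    w[k] <- max(0, w[k - 1] + p$service_minutes[k - 1] -
                  (p$arrival[k] - p$arrival[k - 1]))
  }
  expect_equal(p$wait, w)
})

test_that("warm-up clearing excludes early patients but keeps residual busy time", {
  # deterministic overload: arrivals every 10 min, service 30 min, 1 room.
  prof <- hospital_profile(
    classes = list(outpatient = patient_class("outpatient", 1, "scheduled",
                                              interval = 10, batch = 1)),
    exams = list(generic = exam_type("generic", 1, "fixed20",
                                     dist_deterministic(30))),
    rooms = tibble::tibble(id = 1L, tech_sex = "F"),
    priority = NULL, setup_spec = dist_deterministic(0))
  cal <- calendar_config(100, 1, 50)  # horizon 150, measured window [50, 150)
  r <- run_replication(prof, "points", cal, seed = 1)
  # patients arriving before minute 50 are excluded from the measured counts
  expect_identical(sum(r$patients$measured), sum(r$patients$arrival >= 50))
  expect_equal(r$summary$n[r$summary$class == "all"], 10L)
  # the server never idles after start-up, so measured utilization is 1
  expect_equal(r$rooms$utilization, 1)
  # waits grow by 20 per arrival in an overloaded deterministic queue
  expect_equal(diff(r$patients$wait), rep(20, nrow(r$patients) - 1))
})

test_that("experiments aggregate replications with t-based half-widths", {
  prof <- mm1_profile()
  cal <- calendar_config(400, 1, 100)
  ex <- run_experiment(prof, "points", cal, n_reps = 12, base_seed = 5)
  expect_identical(nrow(ex$replications), 12L)
  s <- ex$summary
  n_all <- s[s$measure == "n_all", ]
  expect_equal(n_all$half_width,
               qt(0.975, 11) * n_all$sd / sqrt(12))
  expect_true(all(s$ci_low[!is.na(s$ci_low)] <= s$mean[!is.na(s$ci_low)]))
  expect_error(run_experiment(prof, "points", cal, n_reps = 1), "at least 2")
  # duplicated seeds give identical replication rows
  ex2 <- run_experiment(prof, "points", cal, seeds = c(42, 42))
  rows <- ex2$replications
  expect_equal(rows[1, setdiff(names(rows), "rep")],
               rows[2, setdiff(names(rows), "rep")])
})

test_that("experiment half-widths shrink roughly like 1/sqrt(n)", {
  prof <- mm1_profile()
  cal <- calendar_config(400, 1, 100)
  h30 <- run_experiment(prof, "points", cal, n_reps = 30, base_seed = 2)
  h120 <- run_experiment(prof, "points", cal, n_reps = 120, base_seed = 2)
  g <- function(ex) ex$summary$half_width[ex$summary$measure == "n_outpatient"]
  ratio <- g(h30) / g(h120)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.2)
})

test_that("the warm-up scan flags steady state and handles empty arrivals", {
  mm1 <- mm1_profile()
  tails <- vapply(1:6, function(s) {
    ws <- warmup_scan(mm1, "points", probe_interval = 200, seed = s)
    mean(ws$utilization[ws$time > 5760])
  }, 0)
  expect_lt(abs(mean(tails) - 2 / 3), 0.05)

  silent <- mm1_profile()
  silent$classes$outpatient <- patient_class(
    "outpatient", 1, arrival_spec = dist_deterministic(1e7))
  ws <- warmup_scan(silent, "points", probe_interval = 500, seed = 1)
  expect_true(all(ws$utilization == 0))
})

test_that("the default profile's running utilization is flat by the warm-up cut", {
  ws <- warmup_scan(default_profile(), "points", probe_interval = 100, seed = 8)
  overall <- dplyr::summarise(dplyr::group_by(ws, time),
                              u = mean(utilization))
  late <- overall$u[overall$time > 0.8 * max(overall$time)]
  expect_lt(max(late) - min(late), 0.01 + 1e-9)
})

test_that("tidy, glance and autoplot work on experiments", {
  ex <- run_experiment(tiny_profile(), "points", n_reps = 3, base_seed = 1)
  td <- tidy(ex)
  expect_true(all(c("measure", "mean", "half_width") %in% names(td)))
  gl <- glance(ex)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$policy, "points")
  p <- autoplot(ex)
  expect_s3_class(p, "ggplot")
  ws <- warmup_scan(tiny_profile(), "points", probe_interval = 200,
                    seed = 1, horizon = 1000)
  expect_s3_class(autoplot(ws), "ggplot")
})
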