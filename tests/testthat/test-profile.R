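test_that("the default profile reproduces the case mix and weekly volumes", {
  prof <- default_profile()
  sh <- class_shares(prof)
  expect_equal(sum(sh), 1, tolerance = 1e-9)
  expect_equal(unname(sh), c(72.46, 19.98, 7.57) / 100.01, tolerance = 1e-4)

  cal <- prof$calendar
  expect_equal(cal$measured_minutes, 2236.8)
  # arrival rates calibrated to the validated 5-day volumes
  vols <- vapply(prof$classes,
                 function(cl) cal$measured_minutes / dist_mean(cl$arrival_spec), 0)
  expect_equal(unname(vols), c(355.3, 93.0, 37.9), tolerance = 1e-9)
})

test_that("the exam catalogue satisfies its structural rules", {
  prof <- default_profile()
  cat_tbl <- exam_catalogue(prof)
  expect_equal(sum(cat_tbl$share), 1, tolerance = 1e-9)
  expect_true(all(cat_tbl$weighted_points > 0))
  # stand-in service means sit in the documented bands
  twenty <- cat_tbl$exam %in% c("abdomen", "scrotum", "shoulder", "other")
  expect_true(all(cat_tbl$mean_minutes[twenty] >= 15 &
                    cat_tbl$mean_minutes[twenty] <= 25))
  expect_true(cat_tbl$mean_minutes[cat_tbl$exam == "liver"] >= 30 &&
                cat_tbl$mean_minutes[cat_tbl$exam == "liver"] <= 45)
  expect_identical(cat_tbl$sex_constraint[cat_tbl$exam == "prostate"], "male_tech_only")
  expect_identical(cat_tbl$sex_constraint[cat_tbl$exam == "dvt"], "same_sex_tech")
  # six rooms, fixed sex mapping
  expect_identical(prof$rooms$id, 5:10)
  expect_identical(prof$rooms$tech_sex, c("F", "M", "F", "M", "F", "M"))
})

test_that("scheduled arrivals are deterministic and batch-replicated", {
  a <- gen_scheduled_arrivals(18, 1, 447.36)
  expect_length(a, 25)
  expect_equal(a, seq(0, 432, by = 18))
  b <- gen_scheduled_arrivals(18, 3, 447.36)
  expect_length(b, 75)
  expect_equal(unname(table(b)), rep(3L, 25), ignore_attr = TRUE)
  expect_length(gen_scheduled_arrivals(10, 1, 0), 0)
  expect_error(gen_scheduled_arrivals(0, 1, 100), "positive")
})

test_that("renewal arrivals follow the inter-arrival law", {
  # deterministic gaps give a lattice
  a <- gen_renewal_arrivals(dist_deterministic(7), 30, rand_stream(1, "r"))
  expect_equal(a, c(7, 14, 21, 28))
  expect_length(gen_renewal_arrivals(dist_exponential(5), 0, rand_stream(1, "r")), 0)
  # Poisson count law: mean T/m within 3 SDs over seeded runs
  m <- 5; T <- 400
  counts <- vapply(1:300, function(s) {
    length(gen_renewal_arrivals(dist_exponential(m), T, rand_stream(s, "cnt")))
  }, 0L)
  expect_lt(abs(mean(counts) - T / m), 3 * sqrt(T / m / 300))
  # reproducible per stream
  expect_identical(gen_renewal_arrivals(dist_exponential(5), 100, rand_stream(2, "z")),
                   gen_renewal_arrivals(dist_exponential(5), 100, rand_stream(2, "z")))
})

test_that("slot allocation follows the scheduler's rules", {
  prof <- default_profile()
  expect_identical(allocate_slots(prof$exams$liver)$slot_minutes, 40)
  expect_identical(allocate_slots(prof$exams$liver)$base_points, 2)
  expect_identical(allocate_slots(prof$exams$abdomen),
                   list(slot_minutes = 20, base_points = 1))
  s <- rand_stream(1, "dvt")
  slots <- vapply(1:1e4, function(i) allocate_slots(prof$exams$dvt, s)$slot_minutes, 0)
  expect_lt(abs(mean(slots == 40) - 0.30), 0.015)
})

test_that("weighted points round each addend half-up to one decimal", {
  expect_equal(weighted_points(16.35), 1.1)
  expect_equal(weighted_points(20), 1.3)
  expect_equal(weighted_points(40), 2.3)
  expect_equal(weighted_points(16.35, setup_minutes = 5, base = 20), 1.1)
  expect_error(weighted_points(-1), "positive")
  expect_error(weighted_points(10, setup_minutes = 0), "positive")
})

test_that("the generated patient mix matches the configured probabilities", {
  prof <- default_profile()
  pats <- ultraflow:::generate_patients(prof, 50000, seed = 21, policy = "points")
  n <- nrow(pats)
  expect_gt(n, 8000)
  for (e in c("abdomen", "liver", "dvt")) {
    p <- prof$exams[[e]]$share
    expect_lt(abs(mean(pats$exam == e) - p), 3 * sqrt(p * (1 - p) / n))
  }
  # DVT male share 3:4
  dvt <- pats[pats$exam == "dvt", ]
  p <- 3 / 7
  expect_lt(abs(mean(dvt$sex == "M") - p), 3 * sqrt(p * (1 - p) / nrow(dvt)))
  # intimate male exams are always male patients
  expect_true(all(pats$sex[pats$exam %in% c("prostate", "scrotum")] == "M"))
})

test_that("profiles round-trip through YAML without loss", {
  prof <- default_profile()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(class_shares(back), class_shares(prof))
  expect_identical(exam_catalogue(back), exam_catalogue(prof))
  expect_equal(back$calendar, prof$calendar)
  expect_identical(back$rooms, prof$rooms)
  # and a replication run from the re-read profile is identical
  r1 <- run_replication(prof, "points", tiny_calendar(), seed = 4)
  r2 <- run_replication(back, "points", tiny_calendar(), seed = 4)
  expect_equal(r1$patients, r2$patients)
})

test_that("the shipped case-hospital configuration equals the built-in profile", {
  path <- system.file("extdata", "case_hospital.yaml", package = "ultraflow")
  expect_true(nzchar(path))
  shipped <- read_profile(path)
  expect_identical(exam_catalogue(shipped), exam_catalogue(default_profile()))
  expect_equal(class_shares(shipped), class_shares(default_profile()))
})
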