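#' Run one simulation replication
#'
#' Simulates one replication of the department: patients arrive (per class,
#' from a scheduled appointment stream or a renewal process), are assigned
#' an examination room at registration by the active policy, wait in their
#' room's FIFO queue, go through a random setup phase followed by the
#' scanning phase, and depart. Rooms never exchange patients after
#' assignment, so each room is an independent single server and the
#' replication can be computed in a single chronological pass.
#'
#' Exams still in progress at the end of the horizon run to completion and
#' are counted; their busy time contributes to utilization only up to the
#' horizon. Statistics cover the measured window after the warm-up: patients
#' arriving during warm-up are excluded from counts and waiting-time
#' averages, but residual service they occupy contributes to busy time.
#' Balance counters used by the dispatcher accumulate continuously over the
#' whole replication; the per-room report sums only measured-window
#' patients.
#'
#' All stochastic processes draw from independent substreams derived from
#' `seed`, so the same seed reproduces the replication exactly and different
#' policies sharing a seed see identical arrivals and service demands
#' (common random numbers).
#'
#' @param profile A `uf_profile`.
#' @param policy One of [uf_policies].
#' @param calendar A [calendar_config()]; defaults to the profile's.
#' @param seed Integer replication seed.
#' @return A `uf_replication`: list with `patients` (the per-patient event
#'   log tibble), `rooms` (per-room busy time, utilization, counters),
#'   `summary` (per-class counts and mean waits over the measured window),
#'   and run metadata.
#' @examples
#' rep <- run_replication(default_profile(), "points",
#'                        calendar_config(100, 1, 0), seed = 1)
#' rep$summary
#' @export
run_replication <- function(profile, policy = uf_policies,
                            calendar = NULL, seed = 1) {
  policy <- match.arg(policy, uf_policies)
  validate_profile(profile)
  calendar <- calendar %||% profile$calendar
  check_number(seed, "seed")
  horizon <- calendar$replication_minutes
  warm <- calendar$warmup_minutes

  pats <- generate_patients(profile, horizon, seed, policy)
  n <- nrow(pats)

  rooms <- profile$rooms
  nr <- nrow(rooms)
  room_ids <- as.integer(rooms$id)
  male_idx <- which(rooms$tech_sex == "M")
  female_idx <- which(rooms$tech_sex == "F")
  all_idx <- seq_len(nr)

  prio_idx_by_class <- c(outpatient = 0L, inpatient = 0L, emergency = 0L)
  for (nm in names(profile$priority %||% list())) {
    m <- match(profile$priority[[nm]], room_ids)
    prio_idx_by_class[nm] <- if (is.na(m)) 0L else m
  }
  prio_room_set <- prio_idx_by_class[prio_idx_by_class > 0L]

  room_free <- numeric(nr)
  pts <- numeric(nr); mins <- numeric(nr); wpts <- numeric(nr)
  pending <- vector("list", nr)  # future queue-entry times, priority rooms only
  for (k in seq_len(nr)) pending[[k]] <- numeric(0)

  entry <- numeric(n); comp <- numeric(n); room_of <- integer(n)

  arr <- pats$arrival
  svc <- pats$service_minutes
  bpt <- pats$base_points
  wpt <- pats$weighted_points
  cls <- pats$class
  sexes <- pats$sex
  cons <- pats$sex_constraint
  u_rand <- pats$u_policy

  for (i in seq_len(n)) {
    t <- arr[i]
    con <- cons[i]
    elig <- if (con == "none") all_idx
            else if (sexes[i] == "M") male_idx else female_idx
    if (con == "male_tech_only" && sexes[i] == "F") {
      stop_input("patient %d: female patient with a male-only exam.", i)
    }
    if (length(elig) == 0L) {
      stop_input("patient %d (%s, %s exam): no eligible room in the layout.",
                 i, sexes[i], pats$exam[i])
    }
    p_idx <- prio_idx_by_class[[cls[i]]]
    waiting <- 0L
    if (p_idx > 0L && con == "none") {
      q <- pending[[p_idx]]
      if (length(q)) {
        q <- q[q > t]
        pending[[p_idx]] <- q
      }
      waiting <- length(q)
    }
    crit <- switch(policy, points = pts, minutes = mins,
                   weighted_points = wpts, random = room_free)  # unused for random
    r <- choose_room_idx(room_ids, crit, elig, con != "none", cls[i],
                         p_idx, waiting, policy, u_rand[i])
    e <- max(t, room_free[r])
    c_ <- e + svc[i]
    room_free[r] <- c_
    pts[r] <- pts[r] + bpt[i]
    mins[r] <- mins[r] + svc[i]
    wpts[r] <- wpts[r] + wpt[i]
    # queue bookkeeping is only consulted for priority rooms
    if (e > t && r %in% prio_room_set) {
      pending[[r]] <- c(pending[[r]], e)
    }
    entry[i] <- e; comp[i] <- c_; room_of[i] <- r
  }

  pats$room <- if (n) room_ids[room_of] else integer(0)
  pats$room_entry <- entry
  pats$first_image <- entry + pats$setup_minutes
  pats$completion <- comp
  pats$wait <- entry - arr
  pats$measured <- arr >= warm & arr < horizon
  pats$u_policy <- NULL

  measured_len <- horizon - warm
  lo <- pmax(entry, warm); hi <- pmin(comp, horizon)
  contrib <- pmax(hi - lo, 0)
  busy <- vapply(seq_len(nr), function(k) sum(contrib[room_of == k]), 0)

  sel <- pats$measured
  room_tbl <- tibble::tibble(
    room = room_ids, tech_sex = rooms$tech_sex,
    n_assigned = vapply(seq_len(nr), function(k) sum(sel & room_of == k), 0L),
    busy_minutes = busy,
    utilization = if (measured_len > 0) busy / measured_len else 0,
    points = vapply(seq_len(nr), function(k) sum(bpt[sel & room_of == k]), 0),
    minutes = vapply(seq_len(nr), function(k) sum(svc[sel & room_of == k]), 0),
    weighted_points = vapply(seq_len(nr), function(k) sum(wpt[sel & room_of == k]), 0),
    cum_points = pts, cum_minutes = mins, cum_weighted_points = wpts
  )

  class_names <- names(profile$classes)
  summary <- purrr::map_dfr(class_names, function(cn) {
    s <- sel & cls == cn
    tibble::tibble(class = cn, n = sum(s),
                   mean_wait = if (any(s)) mean(pats$wait[s]) else NA_real_)
  })
  summary <- dplyr::bind_rows(summary, tibble::tibble(
    class = "all", n = sum(sel),
    mean_wait = if (any(sel)) mean(pats$wait[sel]) else NA_real_))

  structure(list(patients = pats, rooms = room_tbl, summary = summary,
                 policy = policy, seed = seed, calendar = calendar),
            class = "uf_replication")
}

# Build the patient table for one replication: arrivals, exam types, sexes,
# slots, service and setup draws — everything knowable at registration.
generate_patients <- function(profile, horizon, seed, policy) {
  cls_names <- names(profile$classes)
  arr <- numeric(0); cls <- character(0)
  for (cn in cls_names) {
    cc <- profile$classes[[cn]]
    a <- if (cc$arrival_model == "scheduled") {
      gen_scheduled_arrivals(cc$interval, cc$batch, horizon)
    } else {
      gen_renewal_arrivals(cc$arrival_spec, horizon,
                           rand_stream(seed, paste0("arrivals_", cn)))
    }
    arr <- c(arr, a)
    cls <- c(cls, rep(cn, length(a)))
  }
  n <- length(arr)

  exams <- profile$exams
  ke <- length(exams)
  shares <- vapply(exams, function(e) e$share, 0)
  exam_names <- vapply(exams, function(e) e$name, "")
  slot_rules <- vapply(exams, function(e) e$slot_rule, "")
  sex_cons <- vapply(exams, function(e) e$sex_constraint, "")
  wp_exam <- vapply(exams, function(e) e$weighted_points, 0)

  u_exam <- if (n) draw_stream(rand_stream(seed, "exam_mix"), function() runif(n)) else numeric(0)
  exam_idx <- findInterval(u_exam, cumsum(shares)[-ke]) + 1L

  p_male <- vapply(profile$classes, function(cc) cc$p_male, 0)[cls]
  p_male_dvt <- vapply(profile$classes, function(cc) cc$p_male_dvt, 0)[cls]
  con_i <- sex_cons[exam_idx]
  p <- ifelse(con_i == "male_tech_only", 1,
              ifelse(con_i == "same_sex_tech", p_male_dvt, p_male))
  u_sex <- if (n) draw_stream(rand_stream(seed, "sex"), function() runif(n)) else numeric(0)
  sex <- ifelse(u_sex < p, "M", "F")

  u_slot <- if (n) draw_stream(rand_stream(seed, "dvt_slot"), function() runif(n)) else numeric(0)
  slot <- ifelse(slot_rules[exam_idx] == "fixed40", 40,
                 ifelse(slot_rules[exam_idx] == "dvt_split",
                        ifelse(u_slot < 0.7, 20, 40), 20))

  scan <- numeric(n)
  svc_stream <- rand_stream(seed, "service")
  for (j in seq_len(ke)) {
    who <- which(exam_idx == j)
    if (length(who)) {
      scan[who] <- sample_dist(exams[[j]]$service_spec, length(who), svc_stream)
    }
  }
  setup <- if (n) sample_dist(profile$setup_spec, n, rand_stream(seed, "setup")) else numeric(0)

  u_policy <- rep(NA_real_, n)
  if (policy == "random" && n) {
    u_policy <- draw_stream(rand_stream(seed, "policy_random"), function() runif(n))
  }

  ord <- order(arr, seq_len(n))
  tibble::tibble(
    id = seq_len(n),
    class = cls[ord], sex = sex[ord],
    exam = exam_names[exam_idx][ord],
    sex_constraint = con_i[ord],
    slot_minutes = slot[ord],
    base_points = slot[ord] / 20,
    weighted_points = wp_exam[exam_idx][ord],
    arrival = arr[ord],
    setup_minutes = setup[ord],
    scan_minutes = scan[ord],
    service_minutes = setup[ord] + scan[ord],
    u_policy = u_policy[ord]
  )
}

#' Run a replicated experiment
#'
#' Runs `n_reps` independent replications (seeds `base_seed`,
#' `base_seed + 1`, ...) and aggregates the performance measures: per-class
#' arrival counts and mean waits, total examined, overall mean wait, and
#' per-room utilization, each with its across-replication mean, standard
#' deviation, and 95% confidence half-width; plus the across-room workload
#' mean and sample SD on the percentage scale.
#'
#' @param profile A `uf_profile`.
#' @param policy One of [uf_policies].
#' @param calendar Optional [calendar_config()] override.
#' @param n_reps Number of replications (>= 2).
#' @param base_seed Master seed. Per-replication seeds are drawn from a
#'   dedicated substream of this seed (not consecutive integers, whose
#'   arithmetic structure can leak correlation into the generator
#'   initialization), so experiments sharing `base_seed` still share
#'   replication seeds across policies.
#' @param seeds Optional explicit seed vector overriding `base_seed`.
#' @return A `uf_experiment`: `replications` (one row per replication),
#'   `summary` (per-measure mean/sd/half-width/CI), `room_summary`,
#'   `workload` (list with `mean` and `sd`, percent), and metadata. Supports
#'   [tidy()], [glance()], and [autoplot()].
#' @export
run_experiment <- function(profile, policy = uf_policies, calendar = NULL,
                           n_reps = 110, base_seed = 1, seeds = NULL) {
  policy <- match.arg(policy, uf_policies)
  seeds <- seeds %||% draw_stream(rand_stream(base_seed, "replication_seeds"),
                                  function() sample.int(2147483646L, n_reps))
  if (length(seeds) < 2L) stop_input("an experiment needs at least 2 replications.")
  calendar <- calendar %||% profile$calendar

  rows <- purrr::map(seq_along(seeds), function(i) {
    r <- run_replication(profile, policy, calendar, seeds[i])
    s <- r$summary
    out <- tibble::tibble(rep = i, seed = seeds[i])
    for (j in seq_len(nrow(s))) {
      out[[paste0("n_", s$class[j])]] <- s$n[j]
      out[[paste0("wait_", s$class[j])]] <- s$mean_wait[j]
    }
    for (j in seq_len(nrow(r$rooms))) {
      out[[paste0("util_", r$rooms$room[j])]] <- r$rooms$utilization[j]
    }
    out$workload_sd_pct <- sd(r$rooms$utilization) * 100
    out
  })
  reps <- dplyr::bind_rows(rows)

  measures <- setdiff(names(reps), c("rep", "seed"))
  summary <- purrr::map_dfr(measures, function(m) {
    x <- reps[[m]]
    x <- x[!is.na(x)]
    if (length(x) < 2L) {
      return(tibble::tibble(measure = m,
                            mean = if (length(x)) mean(x) else NA_real_,
                            sd = NA_real_, n = length(x), half_width = NA_real_,
                            ci_low = NA_real_, ci_high = NA_real_, cv = NA_real_))
    }
    mu <- mean(x); s <- sd(x)
    h <- half_width(s, length(x), 0.05)
    tibble::tibble(measure = m, mean = mu, sd = s, n = length(x),
                   half_width = h, ci_low = mu - h, ci_high = mu + h,
                   cv = if (mu > 0) h / mu else NA_real_)
  })

  util_cols <- grep("^util_", measures, value = TRUE)
  room_summary <- summary |>
    dplyr::filter(.data$measure %in% util_cols) |>
    dplyr::mutate(room = as.integer(sub("^util_", "", .data$measure)))
  wl <- if (nrow(room_summary) == 6L) {
    workload_sd(room_summary$mean * 100)
  } else {
    list(mean = round(mean(room_summary$mean) * 100, 2),
         sd = if (nrow(room_summary) > 1L) round(sd(room_summary$mean) * 100, 2) else NA_real_)
  }

  structure(list(replications = reps, summary = summary,
                 room_summary = room_summary, workload = wl,
                 policy = policy, n_reps = length(seeds), seeds = seeds,
                 calendar = calendar),
            class = "uf_experiment")
}

#' @export
print.uf_experiment <- function(x, ...) {
  cat(sprintf("<uf_experiment: policy=%s, %d replications>\n", x$policy, x$n_reps))
  tot <- x$summary[x$summary$measure == "n_all", ]
  wt <- x$summary[x$summary$measure == "wait_all", ]
  if (nrow(tot)) cat(sprintf("  total examined: %.2f (+/- %.2f)\n", tot$mean, tot$half_width))
  if (nrow(wt)) cat(sprintf("  mean wait:      %.2f min (+/- %.2f)\n", wt$mean, wt$half_width))
  cat(sprintf("  workload:       %.2f%% (SD %.2f)\n", x$workload$mean, x$workload$sd))
  invisible(x)
}

#' Running-utilization warm-up diagnostic
#'
#' Runs a single long replication (default 7200 minutes, statistics from
#' time zero) and reports, for every room, the running mean utilization
#' `busy(0, t) / t` sampled every `probe_interval` minutes. A flat tail
#' indicates the process has reached steady state; the default calendar's
#' 5600-minute warm-up was chosen by exactly this kind of scan.
#'
#' @param profile A `uf_profile`.
#' @param policy One of [uf_policies].
#' @param probe_interval Minutes between probes.
#' @param seed Replication seed.
#' @param horizon Total scan length in minutes.
#' @return A `uf_warmup` tibble with columns `time`, `room`, `utilization`.
#'   Supports [autoplot()].
#' @export
warmup_scan <- function(profile, policy = uf_policies, probe_interval = 100,
                        seed = 1, horizon = 7200) {
  policy <- match.arg(policy, uf_policies)
  check_number(probe_interval, "probe_interval", positive = TRUE)
  cal <- calendar_config(effective_day_minutes = horizon,
                         days_per_replication = 1, warmup_minutes = 0)
  r <- run_replication(profile, policy, cal, seed)
  probes <- seq(probe_interval, horizon, by = probe_interval)
  p <- r$patients
  out <- purrr::map_dfr(sort(unique(profile$rooms$id)), function(rm) {
    sel <- p$room == rm
    en <- p$room_entry[sel]; cp <- p$completion[sel]
    util <- vapply(probes, function(t) {
      sum(pmax(pmin(cp, t) - pmin(en, t), 0)) / t
    }, 0)
    tibble::tibble(time = probes, room = rm, utilization = util)
  })
  class(out) <- c("uf_warmup", class(out))
  out
}
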