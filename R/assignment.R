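#' Room-assignment policies
#'
#' Four interchangeable balance criteria drive the dispatch decision tree:
#'
#' * `"points"` — cumulative examination points (1 point per 20-minute slot,
#'   2 per 40-minute slot): the department's current practice.
#' * `"minutes"` — cumulative examination time: the realized service
#'   duration (setup + scanning) drawn at patient creation, a finer-grained
#'   balance currency.
#' * `"random"` — uniform draw over the candidate rooms.
#' * `"weighted_points"` — weighted cumulative examination points
#'   ([weighted_points()] per exam), trading some balance for fairness in
#'   patient counts.
#'
#' @format NULL
#' @name policies
#' @export
uf_policies <- c("points", "minutes", "random", "weighted_points")

#' Rooms a patient may be assigned to
#'
#' Sex-constrained examinations restrict the candidate set: male patients
#' needing a prostate, scrotal, or DVT scan may only use rooms staffed by a
#' male technologist; female DVT patients only rooms staffed by a female
#' technologist. Everyone else may use any room. A female patient with a
#' male-only exam type is a contradiction and raises an error.
#'
#' @param patient List or one-row data frame with at least `sex`
#'   (`"M"`/`"F"`) and `sex_constraint` (`"none"`, `"male_tech_only"`,
#'   `"same_sex_tech"`).
#' @param rooms Tibble with columns `id`, `tech_sex`.
#' @return Integer vector of eligible room ids.
#' @examples
#' rooms <- default_profile()$rooms
#' eligible_rooms(list(sex = "M", sex_constraint = "male_tech_only"), rooms)
#' @export
eligible_rooms <- function(patient, rooms) {
  sex <- patient$sex
  con <- patient$sex_constraint
  if (!sex %in% c("M", "F")) stop_input("patient sex must be \"M\" or \"F\".")
  if (con == "male_tech_only" && sex == "F") {
    stop_input("a female patient cannot carry a male-only examination type.")
  }
  if (con == "none") return(rooms$id)
  rooms$id[rooms$tech_sex == sex]
}

# Core decision tree, shared by the exported assign_room() and the engine.
# Arguments are plain vectors indexed by room position:
#   room_ids      integer ids
#   crit          criterion value per room (ignored for random)
#   elig_idx      positions of eligible rooms
#   constrained   TRUE when the patient's exam is sex-constrained
#   class         patient class string
#   prio_idx      position of this class's priority room, or 0
#   prio_waiting  queue length at the priority room (excluding in service)
#   rand_u        uniform draw in [0,1) when policy == "random"
choose_room_idx <- function(room_ids, crit, elig_idx, constrained, class,
                            prio_idx, prio_waiting, policy, rand_u = NA_real_) {
  if (length(elig_idx) == 0L) stop_input("no eligible room for this patient.")
  if (!constrained && prio_idx > 0L && prio_waiting == 0L &&
      class %in% c("inpatient", "emergency")) {
    return(prio_idx)
  }
  cand <- elig_idx
  if (policy == "random") {
    return(cand[floor(rand_u * length(cand)) + 1L])
  }
  v <- crit[cand]
  # ties broken by lowest room id
  cand <- cand[v == min(v)]
  cand[which.min(room_ids[cand])]
}

#' Assign a patient to a room
#'
#' Implements the registration-counter decision tree: (1) patients with a
#' sex-constrained examination go to the room with the lowest criterion
#' value among their eligible rooms; (2) an inpatient goes straight to the
#' inpatient priority room when nobody is waiting there (even if it is
#' busy), otherwise to the criterion-minimal room over all rooms; (3) the
#' same for emergency patients and their priority room; (4) everyone else
#' goes to the criterion-minimal room over all rooms. Under the random
#' policy the criterion step is a uniform draw but the branch structure is
#' preserved. Ties break toward the lowest room id.
#'
#' @param patient List with `class`, `sex`, `sex_constraint`.
#' @param rooms Tibble with columns `id`, `tech_sex`, `queue_len`, and the
#'   balance counters `points`, `minutes`, `weighted_points`.
#' @param policy One of [uf_policies].
#' @param priority Named list of priority room ids (as in a `uf_profile`).
#' @param stream [rand_stream()] consumed only by the random policy.
#' @return The chosen room id (integer).
#' @examples
#' prof <- default_profile()
#' rooms <- dplyr::mutate(prof$rooms, queue_len = 0L,
#'                        points = c(4, 5, 2, 3, 6, 7), minutes = 0,
#'                        weighted_points = 0)
#' assign_room(list(class = "outpatient", sex = "M",
#'                  sex_constraint = "male_tech_only"),
#'             rooms, "points", prof$priority)
#' @export
assign_room <- function(patient, rooms, policy = uf_policies,
                        priority = list(inpatient = 5L, emergency = 6L),
                        stream = NULL) {
  policy <- match.arg(policy, uf_policies)
  elig <- eligible_rooms(patient, rooms)
  elig_idx <- match(elig, rooms$id)
  constrained <- patient$sex_constraint != "none"
  prio_id <- priority[[patient$class]] %||% 0L
  prio_idx <- if (prio_id > 0L) match(prio_id, rooms$id) else 0L
  if (is.na(prio_idx)) prio_idx <- 0L
  crit <- switch(policy,
    points = rooms$points,
    minutes = rooms$minutes,
    weighted_points = rooms$weighted_points,
    random = rep(0, nrow(rooms)))
  u <- if (policy == "random") {
    if (is.null(stream)) stop_input("the random policy needs a `stream`.")
    draw_stream(stream, function() runif(1))
  } else NA_real_
  idx <- choose_room_idx(rooms$id, crit, elig_idx, constrained, patient$class,
                         prio_idx,
                         if (prio_idx > 0L) rooms$queue_len[prio_idx] else 0L,
                         policy, u)
  rooms$id[idx]
}

#' Update a room's balance counters after an assignment
#'
#' All three counters are maintained regardless of the active policy so any
#' of them can be reported: `points` grows by the slot's base points,
#' `minutes` by the patient's realized service duration, and
#' `weighted_points` by the exam's weighted points. Counters are updated at
#' assignment time — the dispatcher must see load it has already committed,
#' not only completed work.
#'
#' @param rooms Tibble with counter columns and an `id` column.
#' @param room_id Room that received the patient.
#' @param patient List with `base_points`, `service_minutes`,
#'   `weighted_points`.
#' @return `rooms` with the counters of `room_id` incremented.
#' @export
update_criterion <- function(rooms, room_id, patient) {
  i <- match(room_id, rooms$id)
  if (is.na(i)) stop_input("room %s is not in the layout.", room_id)
  rooms$points[i] <- rooms$points[i] + patient$base_points
  rooms$minutes[i] <- rooms$minutes[i] + patient$service_minutes
  rooms$weighted_points[i] <- rooms$weighted_points[i] + patient$weighted_points
  rooms
}
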