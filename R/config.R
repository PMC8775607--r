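#' Read and write profiles as YAML
#'
#' Profiles round-trip through a plain YAML document so a run configuration
#' can live beside its outputs. The shipped `case_hospital.yaml` (under
#' `inst/extdata/`) is the serialized [default_profile()].
#'
#' @param profile A `uf_profile`.
#' @param path File path.
#' @return `read_profile()` returns a `uf_profile`; `write_profile()`
#'   returns `path` invisibly.
#' @examples
#' path <- system.file("extdata", "case_hospital.yaml", package = "ultraflow")
#' prof <- read_profile(path)
#' @export
write_profile <- function(profile, path) {
  validate_profile(profile)
  yaml::write_yaml(profile_to_list(profile), path, precision = 12)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  profile_from_list(yaml::read_yaml(path))
}

dist_to_list <- function(d) {
  if (d$kind == "mixture") {
    list(kind = "mixture", weights = as.list(d$weights),
         components = lapply(d$components, dist_to_list))
  } else {
    out <- unclass(d)
    out[c("values", "probs")] <- lapply(out[c("values", "probs")], as.list)
    out[lengths(out) > 0]
  }
}

dist_from_list <- function(x) {
  switch(x$kind,
    triangular = dist_triangular(x$min, x$mode, x$max),
    beta_scaled = dist_beta_scaled(x$offset, x$scale, x$shape1, x$shape2),
    weibull_scaled = dist_weibull_scaled(x$offset, x$scale, x$shape),
    exponential = dist_exponential(x$mean),
    deterministic = dist_deterministic(x$value),
    empirical = dist_empirical(unlist(x$values), unlist(x$probs)),
    mixture = dist_mixture(unlist(x$weights), lapply(x$components, dist_from_list)),
    stop_input("unknown distribution kind '%s'.", x$kind)
  )
}

profile_to_list <- function(p) {
  list(
    classes = lapply(p$classes, function(cl) {
      out <- list(class = cl$class, share = cl$share,
                  arrival_model = cl$arrival_model,
                  p_male = cl$p_male, p_male_dvt = cl$p_male_dvt)
      if (cl$arrival_model == "renewal") {
        out$arrival_spec <- dist_to_list(cl$arrival_spec)
      } else {
        out$interval <- cl$interval
        out$batch <- cl$batch
      }
      out
    }),
    exams = lapply(p$exams, function(e) list(
      name = e$name, share = e$share, slot_rule = e$slot_rule,
      sex_constraint = e$sex_constraint,
      service_spec = dist_to_list(e$service_spec))),
    rooms = list(id = as.list(p$rooms$id), tech_sex = as.list(p$rooms$tech_sex)),
    priority = p$priority,
    setup_spec = dist_to_list(p$setup_spec),
    calendar = list(effective_day_minutes = p$calendar$effective_day_minutes,
                    days_per_replication = p$calendar$days_per_replication,
                    warmup_minutes = p$calendar$warmup_minutes)
  )
}

profile_from_list <- function(x) {
  classes <- lapply(x$classes, function(cl) {
    if (cl$arrival_model == "renewal") {
      patient_class(cl$class, cl$share, "renewal",
                    arrival_spec = dist_from_list(cl$arrival_spec),
                    p_male = cl$p_male, p_male_dvt = cl$p_male_dvt)
    } else {
      patient_class(cl$class, cl$share, "scheduled",
                    interval = cl$interval, batch = cl$batch,
                    p_male = cl$p_male, p_male_dvt = cl$p_male_dvt)
    }
  })
  names(classes) <- vapply(classes, function(cl) cl$class, "")
  exams <- lapply(x$exams, function(e) {
    exam_type(e$name, e$share, e$slot_rule, dist_from_list(e$service_spec),
              e$sex_constraint)
  })
  names(exams) <- vapply(exams, function(e) e$name, "")
  rooms <- tibble::tibble(id = as.integer(unlist(x$rooms$id)),
                          tech_sex = unlist(x$rooms$tech_sex))
  priority <- x$priority
  if (!is.null(priority)) priority <- lapply(priority, as.integer)
  hospital_profile(classes, exams, rooms, priority = priority,
                   setup_spec = dist_from_list(x$setup_spec),
                   calendar = calendar_config(x$calendar$effective_day_minutes,
                                              x$calendar$days_per_replication,
                                              x$calendar$warmup_minutes))
}
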