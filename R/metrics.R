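# Shift metrics. Everything here is a pure function of the event log, so the
# metrics of a finished run and the metrics replayed from its written log are
# the same computation on the same rows.

#' Success label of a completed task
#'
#' A task succeeds when the actual execution time does not exceed the duration
#' the doctor requested (non-strict). Because the requested duration follows
#' the doctor's — possibly biased — level estimate, an overestimating doctor
#' imposes a stricter threshold and an underestimating doctor a laxer one.
#'
#' @param actual_s Actual execution time, seconds.
#' @param requested_duration_s Doctor-requested duration, seconds.
#' @return Logical.
#' @examples
#' classify_success(30, 20) # FALSE: overestimated request, stricter threshold
#' classify_success(30, 40) # TRUE: relaxed threshold
#' @export
classify_success <- function(actual_s, requested_duration_s) {
  stopifnot(all(actual_s > 0), all(requested_duration_s > 0))
  actual_s <= requested_duration_s
}

#' Time damage of a completed task
#'
#' The positive part of (actual - expected) where the expected duration is the
#' doctor-requested one, consistent with the success labeling.
#'
#' @inheritParams classify_success
#' @return Non-negative seconds.
#' @export
time_damage <- function(actual_s, requested_duration_s) {
  pmax(0, actual_s - requested_duration_s)
}

#' Compute shift metrics from an event log
#'
#' Accumulates the five per-shift metric families at total, per-doctor and
#' per-nurse granularity:
#' \describe{
#'   \item{patients served}{discharges, total and per doctor;}
#'   \item{time damage}{sum of positive (actual - requested) deviations over
#'     completed tasks, total, per executing nurse and per requesting doctor;}
#'   \item{total delay}{time patients wait with an issued but unattended
#'     request, total and per doctor — a request never attended accrues delay
#'     until shift end;}
#'   \item{success/failure counts and utility}{per nurse; utility grows by
#'     the requested level of each successful task;}
#'   \item{doctor evaluation accuracy}{fraction of issued requests whose
#'     requested level equals the true level.}
#' }
#'
#' @param events Event-log data.table as produced by [run_shift()] (or read
#'   back by [read_event_log()]). Must contain a `shift_end` row and the
#'   `on_duty` roster rows.
#' @param count_travel_as_delay If `TRUE` a patient counts as waiting until
#'   the nurse arrives at the bed; by default waiting ends when a nurse
#'   commits to the request (claims it).
#' @return An object of class `ed_metrics`: list of data.tables `totals`
#'   (one row), `per_doctor`, `per_nurse`.
#' @export
compute_shift_metrics <- function(events, count_travel_as_delay = FALSE) {
  stopifnot(is.data.frame(events))
  ev <- data.table::as.data.table(events)
  shift_end <- ev[event == "shift_end", time_s]
  if (length(shift_end) != 1L) {
    stop("event log must contain exactly one shift_end row", call. = FALSE)
  }
  doctors <- ev[event == "on_duty" & actor_type == "doctor",
                .(doctor_id = actor_id, style = detail)]
  nurses <- ev[event == "on_duty" & actor_type == "nurse",
               .(nurse_id = actor_id, quality = detail)]
  spawned_nurses <- ev[event == "nurse_spawned",
                       .(nurse_id = actor_id, quality = detail)]
  nurses <- data.table::rbindlist(list(nurses, spawned_nurses))

  issued <- ev[event == "request_issued",
               .(request_id, doctor_id = actor_id, bed_id, patient_id,
                 true_level, requested_level, requested_duration_s = value_s,
                 issue_time_s = time_s)]
  claims <- ev[event == "request_claimed",
               .(request_id, nurse_id = actor_id, claim_time_s = time_s)]
  starts <- ev[event == "task_started", .(request_id, start_time_s = time_s)]
  done <- ev[event == "task_completed",
             .(request_id, nurse_id = actor_id, complete_time_s = time_s,
               actual_s = value_s)]
  served <- ev[event == "patient_discharged",
               .(request_id, doctor_id = actor_id, patient_id)]

  ## per-request table
  # a request may be claimed, aborted, then re-claimed in principle; keep the
  # attendance-start of the claim that leads anywhere (first claim)
  first_claim <- if (nrow(claims)) claims[, .SD[1L], by = request_id] else claims
  req <- data.table::copy(issued)
  if (nrow(req)) {
    req[, `:=`(claim_time_s = NA_real_, start_time_s = NA_real_,
               exec_nurse = NA_integer_, actual_s = NA_real_,
               complete_time_s = NA_real_)]
    if (nrow(first_claim)) {
      req[first_claim, on = "request_id", claim_time_s := i.claim_time_s]
    }
    if (nrow(starts)) {
      req[starts, on = "request_id", start_time_s := i.start_time_s]
    }
    if (nrow(done)) {
      req[done, on = "request_id",
          `:=`(exec_nurse = i.nurse_id, actual_s = i.actual_s,
               complete_time_s = i.complete_time_s)]
    }
    attended <- if (count_travel_as_delay) req$start_time_s else req$claim_time_s
    req[, delay_s := pmin(data.table::fifelse(is.na(attended), shift_end, attended),
                          shift_end) - issue_time_s]
    req[, delay_s := pmax(delay_s, 0)]
    req[, completed := !is.na(actual_s)]
    req[, `:=`(success = NA, damage_s = NA_real_)]
    req[completed == TRUE,
        `:=`(success = classify_success(actual_s, requested_duration_s),
             damage_s = time_damage(actual_s, requested_duration_s))]
  } else {
    req <- data.table::data.table(
      request_id = integer(), doctor_id = integer(), bed_id = integer(),
      patient_id = integer(), true_level = integer(), requested_level = integer(),
      requested_duration_s = numeric(), issue_time_s = numeric(),
      claim_time_s = numeric(), start_time_s = numeric(),
      exec_nurse = integer(), actual_s = numeric(), complete_time_s = numeric(),
      delay_s = numeric(), completed = logical(), success = logical(),
      damage_s = numeric())
  }

  ## per-doctor
  per_doctor <- doctors[, .(doctor_id, style)]
  srv_d <- served[, .(patients_served = .N), by = doctor_id]
  dmg_d <- req[completed == TRUE, .(time_damage_s = sum(damage_s)), by = doctor_id]
  dly_d <- req[, .(total_delay_s = sum(delay_s)), by = doctor_id]
  acc_d <- req[, .(n_requests = .N,
                   eval_accuracy = mean(requested_level == true_level)),
               by = doctor_id]
  for (tb in list(srv_d, dmg_d, dly_d, acc_d)) {
    per_doctor <- merge(per_doctor, tb, by = "doctor_id", all.x = TRUE)
  }
  fill0 <- function(dt, cols) {
    for (cc in cols) data.table::set(dt, which(is.na(dt[[cc]])), cc, 0)
    dt
  }
  per_doctor <- fill0(per_doctor, c("patients_served", "time_damage_s",
                                    "total_delay_s", "n_requests"))
  per_doctor[, patients_served := as.integer(patients_served)]
  per_doctor[, n_requests := as.integer(n_requests)]
  data.table::setorder(per_doctor, doctor_id)

  ## per-nurse
  per_nurse <- nurses[, .(nurse_id, quality)]
  cmp <- req[completed == TRUE]
  nur_stats <- if (nrow(cmp)) {
    cmp[, .(tasks_completed = .N,
            successes = sum(success),
            failures = sum(!success),
            utility = sum(requested_level * success),
            time_damage_s = sum(damage_s)),
        by = .(nurse_id = exec_nurse)]
  } else {
    data.table::data.table(nurse_id = integer(), tasks_completed = integer(),
                           successes = integer(), failures = integer(),
                           utility = integer(), time_damage_s = numeric())
  }
  per_nurse <- merge(per_nurse, nur_stats, by = "nurse_id", all.x = TRUE)
  per_nurse <- fill0(per_nurse, c("tasks_completed", "successes", "failures",
                                  "utility", "time_damage_s"))
  for (cc in c("tasks_completed", "successes", "failures", "utility")) {
    per_nurse[[cc]] <- as.integer(per_nurse[[cc]])
  }
  data.table::setorder(per_nurse, nurse_id)

  totals <- data.table::data.table(
    patients_spawned = nrow(ev[event == "patient_spawned"]),
    patients_served = nrow(served),
    tasks_completed = nrow(cmp),
    successes = sum(per_nurse$successes),
    failures = sum(per_nurse$failures),
    time_damage_s = sum(req[completed == TRUE, damage_s]),
    total_delay_s = sum(req$delay_s),
    utility_total = sum(per_nurse$utility),
    shift_length_s = shift_end
  )
  structure(list(totals = totals, per_doctor = per_doctor,
                 per_nurse = per_nurse),
            class = "ed_metrics")
}

#' @export
print.ed_metrics <- function(x, ...) {
  cat("<ed_metrics>\n totals:\n")
  print(x$totals)
  cat(" per doctor:\n")
  print(x$per_doctor)
  cat(" per nurse:\n")
  print(x$per_nurse)
  invisible(x)
}

#' Write the metric tables and event log of a run
#'
#' Produces `runs.csv` (one wide row), `doctors.csv` and `nurses.csv` (long
#' format, keyed by `run_id`) and `events.csv` in `dir`. Numeric columns are
#' written at full precision so a replay from disk is bit-identical.
#'
#' @param run An `ed_run` from [run_shift()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "ed_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- run$metrics
  wide <- data.table::data.table(run_id = run$run_id,
                                 scenario = run$config$scenario,
                                 policy = run$config$policy,
                                 seed = run$config$seed)
  wide <- cbind(wide, m$totals)
  paths <- file.path(dir, c("runs.csv", "doctors.csv", "nurses.csv", "events.csv"))
  data.table::fwrite(wide, paths[1])
  data.table::fwrite(cbind(run_id = run$run_id, m$per_doctor), paths[2])
  data.table::fwrite(cbind(run_id = run$run_id, m$per_nurse), paths[3])
  write_event_log(run$events, paths[4])
  invisible(dir)
}

#' Write / read an event log
#'
#' @param events Event-log data.table.
#' @param path CSV path.
#' @return `read_event_log()` returns the data.table with the column types
#'   used by [run_shift()].
#' @export
write_event_log <- function(events, path) {
  out <- data.table::copy(data.table::as.data.table(events))
  # doubles as shortest-exact decimal strings so the log round-trips bitwise
  for (cc in c("time_s", "value_s")) {
    out[[cc]] <- ifelse(is.na(out[[cc]]), NA_character_,
                        sprintf("%.17g", out[[cc]]))
  }
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("event log not found: ", path, call. = FALSE)
  ev <- data.table::fread(path)
  needed <- c("seq", "time_s", "event", "actor_type", "actor_id", "bed_id",
              "patient_id", "request_id", "true_level", "requested_level",
              "value_s", "detail")
  missing <- setdiff(needed, names(ev))
  if (length(missing)) {
    stop("malformed event log, missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (cc in c("seq", "actor_id", "bed_id", "patient_id", "request_id",
               "true_level", "requested_level")) {
    ev[[cc]] <- as.integer(ev[[cc]])
  }
  for (cc in c("time_s", "value_s")) ev[[cc]] <- as.numeric(ev[[cc]])
  for (cc in c("event", "actor_type", "detail")) ev[[cc]] <- as.character(ev[[cc]])
  data.table::setcolorder(ev, needed)
  ev
}
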