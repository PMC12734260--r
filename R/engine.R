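# Discrete-event shift engine.
#
# Determinism contract: a run is a pure function of (config, seed). Ties in
# event time are broken by event-kind priority (task completion, exam
# completion, nurse arrival, nurse return), then actor index, then scheduling
# order. Every doctor and nurse draws from its own RNG substream derived from
# the master seed, so adding an agent in one scenario does not perturb the
# draws of the others (common random numbers across scenario arms).

EV_TASK_DONE <- 1L
EV_EXAM_DONE <- 2L
EV_ARRIVE <- 3L
EV_RETURN <- 4L

#' Simulate one shift
#'
#' Runs the event-driven simulation from t = 0 to the shift length under the
#' configured scenario and policy: patients spawn into beds along the fixed
#' fill sequence (and immediately re-fill freed beds — saturated demand),
#' doctors examine and broadcast one IV-catheter task request per patient,
#' nurses claim requests under the active policy, travel, execute, and return
#' to the waiting room. Trust weights, self-assessment and the scenario hooks
#' (difficulty capping, replacement spawning, mentored training) run inside
#' the loop.
#'
#' The returned metrics are computed from the event log alone, so replaying a
#' written log through [compute_shift_metrics()] reproduces them exactly.
#'
#' @param config An [sim_config()].
#' @return An object of class `ed_run`: a list with `events` (the ordered
#'   event log as a data.table), `metrics` (an `ed_metrics`), and `config`.
#' @examples
#' run <- run_shift(default_config(shift_length_s = 1200, seed = 42))
#' run$metrics$totals$patients_served
#' @export
run_shift <- function(config) {
  stopifnot(inherits(config, "ed_config"))
  cfg <- config
  D <- length(cfg$doctors)
  map <- cfg$level_durations

  ## ---- RNG substreams -------------------------------------------------
  # stream k is an independent generator state; doctors use 1..D, roster
  # nurses D+1..D+N, a spawned replacement nurse D+N+1.
  n_streams <- D + length(cfg$nurses) + 1L
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, n_streams)
  streams <- vector("list", n_streams)
  for (k in seq_len(n_streams)) {
    set.seed(stream_seeds[k])
    streams[[k]] <- get(".Random.seed", globalenv())
  }
  draw <- function(k, fn) {
    assign(".Random.seed", streams[[k]], envir = globalenv())
    x <- fn()
    streams[[k]] <<- get(".Random.seed", globalenv())
    x
  }

  ## ---- mutable state --------------------------------------------------
  doc_busy <- rep(FALSE, D)

  nurses <- cfg$nurses
  n_roster <- length(nurses)
  nur_status <- rep("idle", n_roster) # idle | travel | exec | return
  nur_req <- rep(NA_integer_, n_roster)
  nur_stream <- D + seq_len(n_roster)
  nur_trust <- replicate(n_roster, trust_state(cfg$trust$w0), simplify = FALSE)
  nur_training <- replicate(n_roster,
    training_state(decrement = cfg$training$decrement,
                   completion_threshold = cfg$training$completion_threshold,
                   noise_floor = cfg$training$noise_floor),
    simplify = FALSE)
  nur_hook_fired <- rep(FALSE, n_roster)

  bed_patient <- rep(NA_integer_, cfg$n_beds)
  fill_pos <- 1L
  freed_queue <- integer() # beds freed, oldest first (used once fill is done)
  n_spawned <- 0L
  pat_bed <- integer()
  pat_spawn_t <- numeric()
  pat_waiting_exam <- logical()

  # requests: parallel vectors indexed by request id
  req_cap <- 256L
  req_patient <- integer(req_cap); req_bed <- integer(req_cap)
  req_doctor <- integer(req_cap); req_true <- integer(req_cap)
  req_level <- integer(req_cap); req_dur <- numeric(req_cap)
  req_issue <- numeric(req_cap); req_status <- integer(req_cap) # 0 pend 1 claim 2 done
  req_start <- numeric(req_cap)
  n_req <- 0L
  pending <- integer() # pending request ids, in issue order
  grow_req <- function() {
    req_cap <<- req_cap * 2L
    for (v in c("req_patient", "req_bed", "req_doctor", "req_true",
                "req_level", "req_status", "req_dur", "req_issue", "req_start")) {
      assign(v, `length<-`(get(v), req_cap), inherits = TRUE)
    }
  }

  # event queue (small; linear-scan pop)
  eq_time <- numeric(); eq_kind <- integer(); eq_actor <- integer()
  eq_aux <- integer(); eq_seq <- integer(); eq_counter <- 0L
  push <- function(time, kind, actor, aux = NA_integer_) {
    eq_counter <<- eq_counter + 1L
    n <- length(eq_time) + 1L
    eq_time[n] <<- time; eq_kind[n] <<- kind
    eq_actor[n] <<- actor; eq_aux[n] <<- aux; eq_seq[n] <<- eq_counter
  }
  pop <- function() {
    if (!length(eq_time)) return(NULL)
    o <- order(eq_time, eq_kind, eq_actor, eq_seq)[1L]
    ev <- list(time = eq_time[o], kind = eq_kind[o], actor = eq_actor[o],
               aux = eq_aux[o])
    eq_time <<- eq_time[-o]; eq_kind <<- eq_kind[-o]; eq_actor <<- eq_actor[-o]
    eq_aux <<- eq_aux[-o]; eq_seq <<- eq_seq[-o]
    ev
  }

  ## ---- event log ------------------------------------------------------
  log_cap <- 4096L
  lg_time <- numeric(log_cap); lg_event <- character(log_cap)
  lg_atype <- character(log_cap); lg_aid <- integer(log_cap)
  lg_bed <- integer(log_cap); lg_pat <- integer(log_cap)
  lg_req <- integer(log_cap); lg_true <- integer(log_cap)
  lg_lvl <- integer(log_cap); lg_val <- numeric(log_cap)
  lg_detail <- character(log_cap)
  n_log <- 0L
  log_ev <- function(time, event, atype = NA_character_, aid = NA_integer_,
                     bed = NA_integer_, pat = NA_integer_, req = NA_integer_,
                     true_level = NA_integer_, level = NA_integer_,
                     value = NA_real_, detail = NA_character_) {
    if (n_log == log_cap) {
      log_cap <<- log_cap * 2L
      for (v in c("lg_time", "lg_val", "lg_event", "lg_atype", "lg_detail",
                  "lg_aid", "lg_bed", "lg_pat", "lg_req", "lg_true", "lg_lvl")) {
        assign(v, `length<-`(get(v), log_cap), inherits = TRUE)
      }
    }
    n_log <<- n_log + 1L
    lg_time[n_log] <<- time; lg_event[n_log] <<- event
    lg_atype[n_log] <<- atype; lg_aid[n_log] <<- aid
    lg_bed[n_log] <<- bed; lg_pat[n_log] <<- pat; lg_req[n_log] <<- req
    lg_true[n_log] <<- true_level; lg_lvl[n_log] <<- level
    lg_val[n_log] <<- value; lg_detail[n_log] <<- detail
  }

  ## ---- helpers --------------------------------------------------------
  next_bed <- function() {
    if (fill_pos <= length(cfg$fill_sequence)) {
      b <- cfg$fill_sequence[fill_pos]
      fill_pos <<- fill_pos + 1L
      return(b)
    }
    if (!length(freed_queue)) return(NA_integer_)
    b <- freed_queue[1L]
    freed_queue <<- freed_queue[-1L]
    b
  }

  spawn_patient <- function(t) {
    b <- next_bed()
    if (is.na(b)) return(invisible(NULL))
    n_spawned <<- n_spawned + 1L
    pid <- n_spawned
    pat_bed[pid] <<- b; pat_spawn_t[pid] <<- t; pat_waiting_exam[pid] <<- TRUE
    bed_patient[b] <<- pid
    log_ev(t, "patient_spawned", "patient", pid, bed = b, pat = pid)
    invisible(pid)
  }

  dispatch_doctors <- function(t) {
    for (i in seq_len(D)) {
      if (doc_busy[i]) next
      d <- cfg$doctors[[i]]
      cand <- bed_patient[d$beds]
      cand <- cand[!is.na(cand)]
      cand <- cand[pat_waiting_exam[cand]]
      if (!length(cand)) next
      ord <- order(pat_spawn_t[cand], pat_bed[cand])
      pid <- cand[ord[1L]]
      pat_waiting_exam[pid] <<- FALSE
      doc_busy[i] <<- TRUE
      log_ev(t, "exam_started", "doctor", d$id, bed = pat_bed[pid], pat = pid)
      push(t + cfg$exam_duration_s, EV_EXAM_DONE, i, pid)
    }
  }

  dispatch_nurses <- function(t) {
    for (i in seq_along(nurses)) {
      if (nur_status[i] != "idle" || nurses[[i]]$role == "trainer") next
      if (!length(pending)) next
      store <- request_store(pending, req_issue[pending])
      rid <- if (cfg$policy == "fifo") {
        select_request_fifo(store, req_level)
      } else {
        select_request_ca(nur_trust[[i]], store, req_level)
      }
      if (is.na(rid)) next
      pending <<- pending[pending != rid]
      req_status[rid] <<- 1L
      nur_req[i] <<- rid
      nur_status[i] <<- "travel"
      log_ev(t, "request_claimed", "nurse", nurses[[i]]$id,
             bed = req_bed[rid], pat = req_patient[rid], req = rid,
             level = req_level[rid])
      push(t + cfg$travel_time_s, EV_ARRIVE, i)
    }
  }

  spawn_replacement <- function(t) {
    id <- max(vapply(nurses, `[[`, integer(1), "id")) + 1L
    prof <- nurse_profile(id, cfg$replacement_quality, role = "replacement")
    nurses[[length(nurses) + 1L]] <<- prof
    i <- length(nurses)
    nur_status[i] <<- "idle"; nur_req[i] <<- NA_integer_
    nur_stream[i] <<- D + n_roster + 1L
    nur_trust[[i]] <<- trust_state(cfg$trust$w0)
    nur_training[[i]] <<- training_state(
      decrement = cfg$training$decrement,
      completion_threshold = cfg$training$completion_threshold,
      noise_floor = cfg$training$noise_floor)
    nur_hook_fired[i] <<- TRUE # spawned staff get no further scenario hook
    log_ev(t, "nurse_spawned", "nurse", id, detail = prof$quality)
  }

  scenario_on_unreliable <- function(i, t) {
    if (cfg$policy == "fifo") {
      stop("self-assessment fired under FIFO; contract violation", call. = FALSE)
    }
    nid <- nurses[[i]]$id
    log_ev(t, "self_assessed_unreliable", "nurse", nid,
           detail = sprintf("cap=%d", nur_trust[[i]]$restricted_max_level))
    if (cfg$scenario == "replacement") {
      spawn_replacement(t)
    } else if (cfg$scenario == "training") {
      # the trainee keeps all levels while supervised
      nur_training[[i]]$active <<- TRUE
      nur_training[[i]]$start_speed_factor <<- nurses[[i]]$speed_factor
      nur_training[[i]]$start_noise_sd <<- nurses[[i]]$noise_sd
      nur_trust[[i]]$restricted_max_level <<- NA_integer_
      log_ev(t, "trainer_spawned", "nurse", nid)
    }
    nur_hook_fired[i] <<- TRUE
  }

  ## ---- event handlers -------------------------------------------------
  on_exam_done <- function(i, pid, t) {
    d <- cfg$doctors[[i]]
    true_lv <- draw(i, function() sample.int(5L, 1L, prob = cfg$difficulty_probs))
    lv <- evaluate_performance_level(true_lv, d)
    if (n_req == req_cap) grow_req()
    n_req <<- n_req + 1L
    rid <- n_req
    req_patient[rid] <<- pid; req_bed[rid] <<- pat_bed[pid]
    req_doctor[rid] <<- d$id; req_true[rid] <<- true_lv
    req_level[rid] <<- lv; req_dur[rid] <<- gold_duration(lv, map)
    req_issue[rid] <<- t; req_status[rid] <<- 0L
    pending[length(pending) + 1L] <<- rid
    doc_busy[i] <<- FALSE
    log_ev(t, "request_issued", "doctor", d$id, bed = pat_bed[pid], pat = pid,
           req = rid, true_level = true_lv, level = lv, value = req_dur[rid])
  }

  on_arrive <- function(i, t) {
    rid <- nur_req[i]
    if (req_status[rid] == 2L) { # already completed by someone else
      log_ev(t, "task_aborted", "nurse", nurses[[i]]$id, req = rid)
      nur_req[i] <<- NA_integer_
      nur_status[i] <<- "return"
      push(t + cfg$travel_time_s, EV_RETURN, i)
      return(invisible(NULL))
    }
    u <- if (cfg$noise) draw(nur_stream[i], function() stats::runif(1)) else 0.5
    dur <- task_duration(req_true[rid], nurses[[i]], u = u, map = map,
                         noise = cfg$noise)
    req_start[rid] <<- t
    log_ev(t, "task_started", "nurse", nurses[[i]]$id, bed = req_bed[rid],
           pat = req_patient[rid], req = rid, level = req_level[rid],
           value = dur)
    nur_status[i] <<- "exec"
    push(t + dur, EV_TASK_DONE, i)
  }

  on_task_done <- function(i, t) {
    rid <- nur_req[i]
    nid <- nurses[[i]]$id
    actual <- t - req_start[rid]
    success <- classify_success(actual, req_dur[rid])
    req_status[rid] <<- 2L
    log_ev(t, "task_completed", "nurse", nid, bed = req_bed[rid],
           pat = req_patient[rid], req = rid, true_level = req_true[rid],
           level = req_level[rid], value = actual,
           detail = if (success) "success" else "failure")

    if (cfg$policy == "ca") {
      nur_trust[[i]] <<- record_outcome(nur_trust[[i]], req_level[rid],
                                        success, cfg$trust$alpha)
      if (nur_training[[i]]$active) {
        upd <- apply_training_increment(nur_training[[i]], nurses[[i]])
        nur_training[[i]] <<- upd$training
        nurses[[i]] <<- upd$nurse
        if (!upd$training$active) {
          log_ev(t, "trainer_left", "nurse", nid,
                 detail = sprintf("observed=%d", upd$training$observed_count))
          # full responsibilities restored: fresh optimistic weights
          nur_trust[[i]] <<- trust_state(cfg$trust$w0)
        }
      } else {
        was_reliable <- nur_trust[[i]]$reliable
        nur_trust[[i]] <<- self_assess(nur_trust[[i]], cfg$trust$threshold,
                                       cfg$trust$min_attempts,
                                       cfg$trust$baseline_cap)
        if (was_reliable && !nur_trust[[i]]$reliable && !nur_hook_fired[i]) {
          scenario_on_unreliable(i, t)
        }
      }
    }

    # patient served; bed frees; saturated demand refills it immediately
    pid <- req_patient[rid]
    b <- req_bed[rid]
    log_ev(t, "patient_discharged", "doctor", req_doctor[rid], bed = b,
           pat = pid, req = rid)
    bed_patient[b] <<- NA_integer_
    freed_queue[length(freed_queue) + 1L] <<- b
    spawn_patient(t)

    nur_req[i] <<- NA_integer_
    nur_status[i] <<- "return"
    push(t + cfg$travel_time_s, EV_RETURN, i)
  }

  ## ---- main loop ------------------------------------------------------
  for (k in seq_len(min(cfg$n_beds, length(cfg$fill_sequence)))) spawn_patient(0)
  dispatch_doctors(0); dispatch_nurses(0)
  repeat {
    ev <- pop()
    if (is.null(ev) || ev$time > cfg$shift_length_s) break
    t <- ev$time
    if (ev$kind == EV_TASK_DONE) on_task_done(ev$actor, t)
    else if (ev$kind == EV_EXAM_DONE) on_exam_done(ev$actor, ev$aux, t)
    else if (ev$kind == EV_ARRIVE) on_arrive(ev$actor, t)
    else if (ev$kind == EV_RETURN) nur_status[ev$actor] <- "idle"
    dispatch_doctors(t); dispatch_nurses(t)
  }
  log_ev(cfg$shift_length_s, "shift_end")

  idx <- seq_len(n_log)
  events <- data.table::data.table(
    seq = idx, time_s = lg_time[idx], event = lg_event[idx],
    actor_type = lg_atype[idx], actor_id = lg_aid[idx], bed_id = lg_bed[idx],
    patient_id = lg_pat[idx], request_id = lg_req[idx],
    true_level = lg_true[idx], requested_level = lg_lvl[idx],
    value_s = lg_val[idx], detail = lg_detail[idx]
  )
  # prepend roster rows so the log alone determines the metrics
  roster_rows <- data.table::data.table(
    seq = 0L, time_s = 0, event = "on_duty",
    actor_type = c(rep("doctor", D), rep("nurse", n_roster)),
    actor_id = c(vapply(cfg$doctors, `[[`, integer(1), "id"),
                 vapply(cfg$nurses, `[[`, integer(1), "id")),
    bed_id = NA_integer_, patient_id = NA_integer_, request_id = NA_integer_,
    true_level = NA_integer_, requested_level = NA_integer_, value_s = NA_real_,
    detail = c(vapply(cfg$doctors, `[[`, character(1), "style"),
               vapply(cfg$nurses, `[[`, character(1), "quality"))
  )
  events <- data.table::rbindlist(list(roster_rows, events))
  events[, seq := seq_len(.N)]

  metrics <- compute_shift_metrics(
    events, count_travel_as_delay = cfg$count_travel_as_delay)
  structure(list(events = events, metrics = metrics, config = cfg,
                 run_id = cfg$run_id),
            class = "ed_run")
}

#' @export
print.ed_run <- function(x, ...) {
  tot <- x$metrics$totals
  cat(sprintf(
    "<ed_run> %s: %d patients served, damage %.1f s, delay %.1f s (%d events)\n",
    x$run_id, tot$patients_served, tot$time_damage_s, tot$total_delay_s,
    nrow(x$events)))
  invisible(x)
}
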