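# Independent 1-second time-stepping simulator used as an oracle for the
# event-queue engine. Supports noise-off configs with integer exam, travel
# and execution durations, baseline scenario, both policies. State advances
# second by second with the same tie-break discipline the engine documents
# (completions, then exam ends, then arrivals, then returns; actors in id
# order; dispatch after every handled action).

step_sim <- function(cfg) {
  stopifnot(!cfg$noise, cfg$scenario == "baseline")
  D <- length(cfg$doctors)
  N <- length(cfg$nurses)
  shift <- cfg$shift_length_s
  map <- cfg$level_durations

  # replicate the engine's substream seeding recipe so the doctors' difficulty
  # draws coincide; the oracle is independent in its *scheduling*, which is
  # what it checks
  set.seed(cfg$seed)
  stream_seeds <- sample.int(.Machine$integer.max - 1L, D + N + 1L)
  streams <- vector("list", D)
  for (k in seq_len(D)) {
    set.seed(stream_seeds[k])
    streams[[k]] <- get(".Random.seed", envir = globalenv())
  }
  draw_level <- function(k) {
    assign(".Random.seed", streams[[k]], envir = globalenv())
    x <- sample.int(5L, 1L, prob = cfg$difficulty_probs)
    streams[[k]] <<- get(".Random.seed", envir = globalenv())
    x
  }

  bed_owner <- integer(cfg$n_beds)
  for (d in cfg$doctors) bed_owner[d$beds] <- d$id
  bed_patient <- rep(NA_integer_, cfg$n_beds)
  fill_pos <- 1L; freed <- integer()
  n_spawned <- 0L
  pat_bed <- integer(); pat_spawn <- numeric(); pat_wait <- logical()
  spawns <- list()

  nr <- 0L
  r_pat <- integer(); r_bed <- integer(); r_doc <- integer()
  r_true <- integer(); r_lvl <- integer(); r_dur <- numeric()
  r_issue <- numeric(); r_done <- logical()
  pending <- integer()

  doc_exam_end <- rep(NA_real_, D); doc_exam_pat <- rep(NA_integer_, D)
  nur_state <- rep("idle", N)
  nur_t <- rep(NA_real_, N) # time of next transition
  nur_rid <- rep(NA_integer_, N)
  trust <- replicate(N, trust_state(cfg$trust$w0), simplify = FALSE)

  claims <- list(); completions <- list(); served <- 0L

  spawn <- function(t) {
    b <- if (fill_pos <= length(cfg$fill_sequence)) {
      x <- cfg$fill_sequence[fill_pos]; fill_pos <<- fill_pos + 1L; x
    } else if (length(freed)) {
      x <- freed[1L]; freed <<- freed[-1L]; x
    } else NA_integer_
    if (is.na(b)) return()
    n_spawned <<- n_spawned + 1L
    pid <- n_spawned
    pat_bed[pid] <<- b; pat_spawn[pid] <<- t; pat_wait[pid] <<- TRUE
    bed_patient[b] <<- pid
    spawns[[length(spawns) + 1L]] <<- list(t = t, pid = pid, bed = b)
  }

  dispatch <- function(t) {
    for (i in seq_len(D)) {
      if (!is.na(doc_exam_end[i])) next
      d <- cfg$doctors[[i]]
      cand <- bed_patient[d$beds]
      cand <- cand[!is.na(cand)]
      cand <- cand[pat_wait[cand]]
      if (!length(cand)) next
      pid <- cand[order(pat_spawn[cand], pat_bed[cand])][1L]
      pat_wait[pid] <<- FALSE
      doc_exam_end[i] <<- t + cfg$exam_duration_s
      doc_exam_pat[i] <<- pid
    }
    for (i in seq_len(N)) {
      if (nur_state[i] != "idle" || !length(pending)) next
      store <- request_store(pending, r_issue[pending])
      rid <- if (cfg$policy == "fifo") select_request_fifo(store, r_lvl)
             else select_request_ca(trust[[i]], store, r_lvl)
      if (is.na(rid)) next
      pending <<- pending[pending != rid]
      nur_rid[i] <<- rid
      nur_state[i] <<- "travel"
      nur_t[i] <<- t + cfg$travel_time_s
      claims[[length(claims) + 1L]] <<-
        list(t = t, nurse = cfg$nurses[[i]]$id, rid = rid)
    }
  }

  spawn_n <- min(cfg$n_beds, length(cfg$fill_sequence))
  for (k in seq_len(spawn_n)) spawn(0)
  dispatch(0)

  for (t in 0:shift) {
    # 1. execution completions
    for (i in seq_len(N)) {
      if (nur_state[i] == "exec" && nur_t[i] == t) {
        rid <- nur_rid[i]
        r_done[rid] <- TRUE
        actual <- gold_duration(r_true[rid], map) * cfg$nurses[[i]]$speed_factor
        completions[[length(completions) + 1L]] <-
          list(t = t, rid = rid, nurse = cfg$nurses[[i]]$id)
        if (cfg$policy == "ca") {
          ok <- actual <= r_dur[rid]
          trust[[i]] <- record_outcome(trust[[i]], r_lvl[rid], ok, cfg$trust$alpha)
          trust[[i]] <- self_assess(trust[[i]], cfg$trust$threshold,
                                    cfg$trust$min_attempts, cfg$trust$baseline_cap)
        }
        served <- served + 1L
        b <- r_bed[rid]
        bed_patient[b] <- NA_integer_
        freed[length(freed) + 1L] <- b
        spawn(t)
        nur_rid[i] <- NA_integer_
        nur_state[i] <- "return"
        nur_t[i] <- t + cfg$travel_time_s
        dispatch(t)
      }
    }
    # 2. exam completions
    for (i in seq_len(D)) {
      if (!is.na(doc_exam_end[i]) && doc_exam_end[i] == t) {
        pid <- doc_exam_pat[i]
        true_lv <- draw_level(i)
        lv <- evaluate_performance_level(true_lv, cfg$doctors[[i]])
        nr <- nr + 1L
        r_pat[nr] <- pid; r_bed[nr] <- pat_bed[pid]
        r_doc[nr] <- cfg$doctors[[i]]$id
        r_true[nr] <- true_lv; r_lvl[nr] <- lv
        r_dur[nr] <- gold_duration(lv, map)
        r_issue[nr] <- t; r_done[nr] <- FALSE
        pending[length(pending) + 1L] <- nr
        doc_exam_end[i] <- NA_real_; doc_exam_pat[i] <- NA_integer_
        dispatch(t)
      }
    }
    # 3. arrivals
    for (i in seq_len(N)) {
      if (nur_state[i] == "travel" && nur_t[i] == t) {
        rid <- nur_rid[i]
        dur <- gold_duration(r_true[rid], map) * cfg$nurses[[i]]$speed_factor
        nur_state[i] <- "exec"
        nur_t[i] <- t + dur
        dispatch(t)
      }
    }
    # 4. returns
    for (i in seq_len(N)) {
      if (nur_state[i] == "return" && nur_t[i] == t) {
        nur_state[i] <- "idle"
        nur_t[i] <- NA_real_
        dispatch(t)
      }
    }
  }

  list(
    served = served,
    claims = data.table::rbindlist(lapply(claims, data.table::as.data.table)),
    completions = data.table::rbindlist(lapply(completions, data.table::as.data.table)),
    spawns = data.table::rbindlist(lapply(spawns, data.table::as.data.table))
  )
}

# extract the same sequences from an engine run for comparison
engine_sequences <- function(run) {
  ev <- run$events
  list(
    served = run$metrics$totals$patients_served,
    claims = ev[event == "request_claimed",
                .(t = time_s, nurse = actor_id, rid = request_id)],
    completions = ev[event == "task_completed",
                     .(t = time_s, rid = request_id, nurse = actor_id)],
    spawns = ev[event == "patient_spawned",
                .(t = time_s, pid = patient_id, bed = bed_id)]
  )
}
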