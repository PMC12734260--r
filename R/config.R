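#' Trust-policy parameters
#'
#' @param alpha Learning rate of the outcome-feedback weight update.
#' @param w0 Optimistic initial weight per level.
#' @param threshold Self-assessment reliability threshold.
#' @param min_attempts Minimum attempts per level before it is judged.
#' @param baseline_cap Maximum level an unreliable nurse still accepts.
#' @return A named list.
#' @export
trust_params <- function(alpha = 0.2, w0 = 0.8, threshold = 0.5,
                         min_attempts = 3L, baseline_cap = 2L) {
  stopifnot(alpha > 0, alpha <= 1, w0 >= 0, w0 <= 1,
            threshold > 0, threshold < 1, min_attempts >= 1)
  list(alpha = alpha, w0 = w0, threshold = threshold,
       min_attempts = as.integer(min_attempts),
       baseline_cap = assert_level(baseline_cap))
}

#' Mentored-training parameters
#'
#' The trainee's speed factor falls by `decrement` per mentored completion
#' until it reaches `completion_threshold` (the high-quality default), at
#' which point the trainer leaves. The default decrement spreads the learning
#' curve over roughly a full shift of supervised work.
#'
#' @param decrement Speed-factor reduction per mentored completion.
#' @param completion_threshold Target speed factor ending the training.
#' @param noise_floor Duration-noise sigma of a fully trained nurse.
#' @return A named list.
#' @export
training_params <- function(decrement = 0.0025, completion_threshold = 0.9,
                            noise_floor = 0.05) {
  stopifnot(decrement > 0, completion_threshold > 0, noise_floor >= 0)
  list(decrement = as.numeric(decrement),
       completion_threshold = as.numeric(completion_threshold),
       noise_floor = as.numeric(noise_floor))
}

#' Simulation configuration for one shift
#'
#' Fully parameterizes a run: the roster, the physical layout (beds and their
#' owning doctors), the scenario and allocation policy, durations, trust and
#' training parameters, and the master seed. The FIFO policy carries no
#' self-assessment, so it is only valid in the baseline scenario.
#'
#' Beds are assigned to doctors in contiguous blocks (doctor 1 gets the first
#' block, and so on) unless profiles carry explicit `beds`. The initial
#' bed-fill sequence interleaves the doctors' blocks position by position so
#' every doctor is engaged as early as possible; with 9 beds and 3 doctors
#' this is 1, 4, 7, 2, 5, 8, 3, 6, 9.
#'
#' @param doctors List of [doctor_profile()]s.
#' @param nurses List of [nurse_profile()]s (roles must be `"regular"`;
#'   replacement nurses and trainers are spawned by scenario hooks).
#' @param scenario `"baseline"`, `"replacement"` or `"training"`.
#' @param policy `"ca"` (trust model) or `"fifo"`.
#' @param n_beds Number of beds.
#' @param shift_length_s Shift length in seconds.
#' @param travel_time_s Travel time per leg (waiting room to bed and back).
#' @param exam_duration_s Fixed doctor examination delay.
#' @param level_durations A [level_duration_map()].
#' @param difficulty_probs Probabilities of true levels 1..5 at examination.
#' @param noise Logical; multiplicative duration noise on/off.
#' @param trust [trust_params()].
#' @param training [training_params()].
#' @param replacement_quality Quality of a spawned replacement nurse.
#' @param count_travel_as_delay If `TRUE`, patient delay ends when the nurse
#'   arrives at the bed; by default it ends when a nurse commits (claims).
#' @param seed Master seed; every doctor and nurse draws from its own
#'   substream derived from it.
#' @param run_id Optional run identifier (defaults to a seed-derived string).
#' @return A list of class `ed_config`.
#' @export
sim_config <- function(doctors, nurses,
                       scenario = c("baseline", "replacement", "training"),
                       policy = c("ca", "fifo"),
                       n_beds = 9L,
                       shift_length_s = 28800,
                       travel_time_s = 5,
                       exam_duration_s = 10,
                       level_durations = level_duration_map(),
                       difficulty_probs = rep(0.2, 5),
                       noise = TRUE,
                       trust = trust_params(),
                       training = training_params(),
                       replacement_quality = "high",
                       count_travel_as_delay = FALSE,
                       seed = 1L,
                       run_id = NULL) {
  scenario <- match.arg(scenario)
  policy <- match.arg(policy)
  if (policy == "fifo" && scenario != "baseline") {
    stop("the FIFO policy has no self-assessment and is only valid in the ",
         "baseline scenario (got scenario = '", scenario, "')", call. = FALSE)
  }
  stopifnot(length(doctors) >= 1, n_beds >= 1,
            shift_length_s > 0, travel_time_s >= 0, exam_duration_s >= 0,
            length(difficulty_probs) == 5, all(difficulty_probs >= 0),
            abs(sum(difficulty_probs) - 1) < 1e-8)
  doctors <- lapply(doctors, function(d) {
    stopifnot(inherits(d, "ed_doctor")); d
  })
  nurses <- lapply(nurses, function(n) {
    stopifnot(inherits(n, "ed_nurse"))
    if (n$role != "regular") {
      stop("roster nurses must have role 'regular'; replacement nurses and ",
           "trainers are spawned by scenario hooks", call. = FALSE)
    }
    n
  })
  ids_d <- vapply(doctors, `[[`, integer(1), "id")
  ids_n <- vapply(nurses, `[[`, integer(1), "id")
  if (anyDuplicated(ids_d) || anyDuplicated(ids_n)) {
    stop("duplicated doctor or nurse ids", call. = FALSE)
  }

  # bed ownership: contiguous blocks unless given explicitly
  n_beds <- as.integer(n_beds)
  if (all(vapply(doctors, function(d) length(d$beds) == 0L, logical(1)))) {
    blocks <- split(seq_len(n_beds),
                    rep(seq_along(doctors), length.out = n_beds) |> sort())
    for (i in seq_along(doctors)) doctors[[i]]$beds <- as.integer(blocks[[i]])
  }
  owned <- sort(unlist(lapply(doctors, `[[`, "beds")))
  if (!identical(owned, seq_len(n_beds))) {
    stop("doctor bed sets must be disjoint and cover beds 1..n_beds", call. = FALSE)
  }
  # initial fill sequence: interleave doctor blocks position by position
  bed_lists <- lapply(doctors, `[[`, "beds")
  maxlen <- max(lengths(bed_lists))
  fill_sequence <- unlist(lapply(seq_len(maxlen), function(j) {
    vapply(bed_lists, function(b) if (j <= length(b)) b[j] else NA_integer_,
           integer(1))
  }))
  fill_sequence <- fill_sequence[!is.na(fill_sequence)]

  seed <- as.integer(seed)
  if (is.null(run_id)) {
    run_id <- sprintf("%s-%s-seed%d", scenario, policy, seed)
  }
  structure(list(
    doctors = doctors, nurses = nurses,
    scenario = scenario, policy = policy,
    n_beds = n_beds, fill_sequence = as.integer(fill_sequence),
    shift_length_s = as.numeric(shift_length_s),
    travel_time_s = as.numeric(travel_time_s),
    exam_duration_s = as.numeric(exam_duration_s),
    level_durations = level_durations,
    difficulty_probs = as.numeric(difficulty_probs),
    noise = isTRUE(noise),
    trust = trust, training = training,
    replacement_quality = replacement_quality,
    count_travel_as_delay = isTRUE(count_travel_as_delay),
    seed = seed, run_id = run_id
  ), class = "ed_config")
}

#' Default configuration: the small-emergency-room case study
#'
#' Three doctors who estimate correctly, two nurses (one high-performing, one
#' low-performing), nine beds, an 8-hour shift.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return An `ed_config`.
#' @export
default_config <- function(...) {
  args <- list(
    doctors = list(doctor_profile(1), doctor_profile(2), doctor_profile(3)),
    nurses = list(nurse_profile(1, "high"), nurse_profile(2, "low"))
  )
  utils::modifyList(args, list(...)) |> do.call(what = sim_config)
}

#' @export
print.ed_config <- function(x, ...) {
  cat(sprintf("<ed_config> %s | scenario=%s policy=%s seed=%d\n",
              x$run_id, x$scenario, x$policy, x$seed))
  cat(sprintf("  %d doctors, %d nurses, %d beds, shift %.0f s\n",
              length(x$doctors), length(x$nurses), x$n_beds, x$shift_length_s))
  for (d in x$doctors) {
    cat(sprintf("  doctor %d: %s (beds %s)\n", d$id, d$style,
                paste(d$beds, collapse = ",")))
  }
  for (n in x$nurses) {
    cat(sprintf("  nurse %d: %s (speed %.2f, sd %.2f)\n", n$id, n$quality,
                n$speed_factor, n$noise_sd))
  }
  invisible(x)
}

config_to_list <- function(cfg) {
  list(
    doctors = lapply(cfg$doctors, function(d)
      list(id = d$id, style = d$style, bias_magnitude = d$bias_magnitude,
           beds = d$beds)),
    nurses = lapply(cfg$nurses, function(n)
      list(id = n$id, quality = n$quality, speed_factor = n$speed_factor,
           noise_sd = n$noise_sd, role = n$role)),
    scenario = cfg$scenario, policy = cfg$policy, n_beds = cfg$n_beds,
    shift_length_s = cfg$shift_length_s, travel_time_s = cfg$travel_time_s,
    exam_duration_s = cfg$exam_duration_s,
    level_durations = as.numeric(cfg$level_durations),
    difficulty_probs = cfg$difficulty_probs, noise = cfg$noise,
    trust = cfg$trust, training = cfg$training,
    replacement_quality = cfg$replacement_quality,
    count_travel_as_delay = cfg$count_travel_as_delay,
    seed = cfg$seed, run_id = cfg$run_id
  )
}

#' Write a configuration to a YAML file
#'
#' @param cfg An `ed_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ed_config"))
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' Read a configuration from a YAML file
#'
#' @param path YAML file written by [write_config()] (or hand-authored with
#'   the same keys; missing keys fall back to defaults).
#' @return An `ed_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  doctors <- lapply(raw$doctors, function(d)
    doctor_profile(d$id, d$style, d$bias_magnitude %||% 2L,
                   as.integer(unlist(d$beds %||% integer()))))
  nurses <- lapply(raw$nurses, function(n)
    nurse_profile(n$id, n$quality, n$speed_factor, n$noise_sd,
                  n$role %||% "regular"))
  args <- list(doctors = doctors, nurses = nurses)
  scalar_keys <- c("scenario", "policy", "n_beds", "shift_length_s",
                   "travel_time_s", "exam_duration_s", "difficulty_probs",
                   "noise", "replacement_quality", "count_travel_as_delay",
                   "seed", "run_id")
  for (k in scalar_keys) if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  if (!is.null(raw$level_durations)) {
    args$level_durations <- level_duration_map(as.numeric(unlist(raw$level_durations)))
  }
  if (!is.null(raw$trust)) args$trust <- do.call(trust_params, raw$trust)
  if (!is.null(raw$training)) args$training <- do.call(training_params, raw$training)
  do.call(sim_config, args)
}

#' Stable hash of a configuration
#'
#' Key order does not affect the hash.
#'
#' @param cfg An `ed_config`.
#' @return A hash string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      nm <- names(x)
      if (!is.null(nm) && any(nzchar(nm))) x <- x[order(nm)]
      lapply(x, canon)
    } else x
  }
  rlang::hash(canon(config_to_list(cfg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
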