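#' Task difficulty levels
#'
#' Nursing tasks carry an integer difficulty/performance level from 1 (easiest)
#' to 5 (most difficult). Harder tasks demand faster execution, so the
#' gold-standard duration is strictly decreasing in the level.
#'
#' @format Integer vector `1:5`.
#' @export
PERFORMANCE_LEVELS <- 1:5

#' Gold-standard duration map
#'
#' Maps each difficulty level to the gold-standard execution time in seconds.
#' The default is linear, `70 - 10 * level`, anchored at level 3 = 40 s and
#' level 5 = 20 s.
#'
#' @param durations_s Numeric vector of length 5, seconds for levels 1..5.
#'   Must be strictly positive and strictly decreasing.
#' @return A named numeric vector of class `ed_level_map`.
#' @examples
#' level_duration_map()
#' @export
level_duration_map <- function(durations_s = 70 - 10 * PERFORMANCE_LEVELS) {
  stopifnot(is.numeric(durations_s), length(durations_s) == 5L,
            all(durations_s > 0))
  if (any(diff(durations_s) >= 0)) {
    stop("gold durations must be strictly decreasing in level ",
         "(harder tasks demand faster execution)", call. = FALSE)
  }
  structure(stats::setNames(as.numeric(durations_s), PERFORMANCE_LEVELS),
            class = "ed_level_map")
}

assert_level <- function(level) {
  if (!all(level %in% PERFORMANCE_LEVELS)) {
    stop("difficulty level must be an integer in 1..5, got: ",
         paste(level, collapse = ", "), call. = FALSE)
  }
  as.integer(level)
}

#' Gold-standard duration of a task
#'
#' @param level Difficulty level(s) in 1..5.
#' @param map A [level_duration_map()].
#' @return Duration(s) in seconds.
#' @examples
#' gold_duration(3) # 40
#' gold_duration(5) # 20
#' @export
gold_duration <- function(level, map = level_duration_map()) {
  level <- assert_level(level)
  unname(map[level])
}

#' Doctor profile
#'
#' A doctor has an evaluation style that governs how the true task difficulty
#' is mapped to the requested level: `correct` reproduces it, `overestimate`
#' adds `bias_magnitude` levels (clamped at 5), `underestimate` subtracts it
#' (clamped at 1).
#'
#' @param id Integer doctor identifier.
#' @param style One of `"correct"`, `"overestimate"`, `"underestimate"`.
#' @param bias_magnitude Integer bias in levels (1..4); ignored for `correct`.
#' @param beds Integer vector of bed identifiers this doctor owns (filled in by
#'   [sim_config()] when left empty).
#' @return A list of class `ed_doctor`.
#' @export
doctor_profile <- function(id, style = c("correct", "overestimate", "underestimate"),
                           bias_magnitude = 2L, beds = integer()) {
  style <- match.arg(style)
  bias_magnitude <- as.integer(bias_magnitude)
  if (style != "correct" && (bias_magnitude < 1L || bias_magnitude > 4L)) {
    stop("bias_magnitude must be in 1..4 for a biased style", call. = FALSE)
  }
  structure(list(id = as.integer(id), style = style,
                 bias_magnitude = bias_magnitude, beds = as.integer(beds)),
            class = "ed_doctor")
}

#' Nurse profile
#'
#' Nurse quality drives task execution speed: the task duration is the
#' gold-standard duration times `speed_factor` times multiplicative lognormal
#' noise with log-scale standard deviation `noise_sd`. High performers are
#' faster and more consistent than the gold standard (default factor 0.9,
#' sd 0.05); low performers are slower and more variable (default factor 1.5,
#' sd 0.25). The high-quality noise scale is calibrated so that a high
#' performer rarely exceeds a correctly requested duration within one shift
#' and therefore remains a reliable provider.
#'
#' @param id Integer nurse identifier.
#' @param quality `"high"` or `"low"`.
#' @param speed_factor Positive multiplier on the gold duration; defaults by
#'   quality.
#' @param noise_sd Lognormal sigma of the duration noise; defaults by quality.
#' @param role `"regular"`, `"replacement"` or `"trainer"`. Trainer nurses
#'   supervise but never execute tasks.
#' @return A list of class `ed_nurse`.
#' @export
nurse_profile <- function(id, quality = c("high", "low"), speed_factor = NULL,
                          noise_sd = NULL, role = c("regular", "replacement", "trainer")) {
  quality <- match.arg(quality)
  role <- match.arg(role)
  if (is.null(speed_factor)) speed_factor <- if (quality == "high") 0.9 else 1.5
  if (is.null(noise_sd)) noise_sd <- if (quality == "high") 0.05 else 0.25
  stopifnot(speed_factor > 0, noise_sd >= 0)
  structure(list(id = as.integer(id), quality = quality,
                 speed_factor = as.numeric(speed_factor),
                 noise_sd = as.numeric(noise_sd), role = role),
            class = "ed_nurse")
}

#' Mentored-training state
#'
#' Tracks a low performer's progress while supervised by a trainer. Each
#' completed task under mentoring decrements the nurse's `speed_factor` by
#' `decrement`, floored at `completion_threshold` (the high-quality default
#' speed factor). Training ends once the factor reaches the threshold.
#'
#' Skill gain covers consistency as well as speed: while the speed factor
#' falls from its starting value to the threshold, the duration-noise sigma is
#' interpolated linearly from its starting value down to `noise_floor` (the
#' high-quality default), so a fully trained nurse performs like a high one
#' in both mean and variability.
#'
#' @param active Logical; is a trainer currently mentoring this nurse?
#' @param observed_count Number of tasks completed under mentoring.
#' @param decrement Speed-factor reduction per mentored completion.
#' @param completion_threshold Speed factor at which training completes (also
#'   the floor).
#' @param noise_floor Duration-noise sigma of a fully trained nurse.
#' @param start_speed_factor,start_noise_sd The trainee's attributes at the
#'   moment training starts (set by the scenario hook; `NA` until then).
#' @return A list of class `ed_training`.
#' @export
training_state <- function(active = FALSE, observed_count = 0L,
                           decrement = 0.0025, completion_threshold = 0.9,
                           noise_floor = 0.05,
                           start_speed_factor = NA_real_,
                           start_noise_sd = NA_real_) {
  stopifnot(decrement > 0, completion_threshold > 0, observed_count >= 0,
            noise_floor >= 0)
  structure(list(active = active, observed_count = as.integer(observed_count),
                 decrement = as.numeric(decrement),
                 completion_threshold = as.numeric(completion_threshold),
                 noise_floor = as.numeric(noise_floor),
                 start_speed_factor = as.numeric(start_speed_factor),
                 start_noise_sd = as.numeric(start_noise_sd)),
            class = "ed_training")
}

#' Map true difficulty to the doctor's requested level
#'
#' Applies the doctor's evaluation style: identity for `correct`, a clamped
#' upward shift of `bias_magnitude` for `overestimate`, a clamped downward
#' shift for `underestimate`. Deterministic given the profile.
#'
#' @param true_level True difficulty level(s) in 1..5.
#' @param doctor An [doctor_profile()].
#' @return Requested level(s), integer in 1..5.
#' @examples
#' d <- doctor_profile(1, "overestimate", bias_magnitude = 2)
#' evaluate_performance_level(3, d) # 5
#' @export
evaluate_performance_level <- function(true_level, doctor) {
  true_level <- assert_level(true_level)
  switch(doctor$style,
    correct = true_level,
    overestimate = pmin(5L, true_level + doctor$bias_magnitude),
    underestimate = pmax(1L, true_level - doctor$bias_magnitude)
  )
}

#' Task execution duration for a nurse
#'
#' Duration = gold duration of the *true* level x the nurse's current speed
#' factor x multiplicative lognormal noise `exp(noise_sd * qnorm(u))`. With
#' `u = 0.5` (or `noise_sd = 0`) the noise term is 1 and the duration is
#' deterministic.
#'
#' @param true_level True difficulty level of the task.
#' @param nurse A [nurse_profile()] (role must not be `"trainer"`).
#' @param u Uniform(0,1) draw driving the noise; 0.5 disables it.
#' @param map A [level_duration_map()].
#' @param noise Logical; if `FALSE` the noise term is forced to 1.
#' @return Duration in seconds, strictly positive.
#' @examples
#' n <- nurse_profile(1, "high") # factor 0.9
#' task_duration(3, n, noise = FALSE) # 36
#' @export
task_duration <- function(true_level, nurse, u = 0.5, map = level_duration_map(),
                          noise = TRUE) {
  if (nurse$role == "trainer") {
    stop("trainer nurses supervise but never execute tasks", call. = FALSE)
  }
  base <- gold_duration(true_level, map) * nurse$speed_factor
  if (!noise || nurse$noise_sd == 0) return(base)
  base * exp(nurse$noise_sd * stats::qnorm(u))
}

#' Apply one mentored-training increment
#'
#' Called after the trainee completes a task under a trainer's supervision:
#' increments the observation count and lowers the trainee's speed factor by
#' the configured decrement, floored at the completion threshold. Training
#' deactivates once the factor reaches the threshold. Calling it while
#' training is inactive is a no-op (flagged with a warning).
#'
#' @param training A [training_state()] with `active = TRUE`.
#' @param nurse The trainee's [nurse_profile()].
#' @return `list(training = , nurse = )` with updated state.
#' @export
apply_training_increment <- function(training, nurse) {
  if (!isTRUE(training$active)) {
    warning("apply_training_increment called while training inactive; no-op",
            call. = FALSE)
    return(list(training = training, nurse = nurse))
  }
  training$observed_count <- training$observed_count + 1L
  nurse$speed_factor <- max(training$completion_threshold,
                            nurse$speed_factor - training$decrement)
  # consistency improves in step with speed
  if (!is.na(training$start_speed_factor) &&
      training$start_speed_factor > training$completion_threshold &&
      !is.na(training$start_noise_sd)) {
    progress <- (training$start_speed_factor - nurse$speed_factor) /
      (training$start_speed_factor - training$completion_threshold)
    nurse$noise_sd <- max(training$noise_floor,
                          training$start_noise_sd -
                            progress * (training$start_noise_sd - training$noise_floor))
  }
  if (nurse$speed_factor <= training$completion_threshold) {
    training$active <- FALSE
  }
  list(training = training, nurse = nurse)
}
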