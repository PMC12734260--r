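# Small deterministic configurations used across tests.

# 1 doctor, 1 bed, 1 high nurse, noise off, all tasks true level 3:
# cycle time = exam 10 + travel 5 + execution 36 = 51 s per patient.
tiny_config <- function(shift_length_s = 510,
                        difficulty_probs = c(0, 0, 1, 0, 0), ...) {
  sim_config(
    doctors = list(doctor_profile(1)),
    nurses = list(nurse_profile(1, "high")),
    n_beds = 1, shift_length_s = shift_length_s,
    difficulty_probs = difficulty_probs, noise = FALSE, seed = 1,
    ...
  )
}

# 2 doctors, 3 beds, high + low nurse, noise off, mixed levels
mini_config <- function(policy = "fifo", shift_length_s = 600, seed = 5, ...) {
  sim_config(
    doctors = list(doctor_profile(1), doctor_profile(2)),
    nurses = list(nurse_profile(1, "high"), nurse_profile(2, "low")),
    n_beds = 3, policy = policy, shift_length_s = shift_length_s,
    noise = FALSE, seed = seed, ...
  )
}

library(data.table)
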