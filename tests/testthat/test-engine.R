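test_that("saturated shifts fill beds in the fixed interleaved order", {
  run <- run_shift(default_config(shift_length_s = 120, seed = 1))
  first_beds <- run$events[event == "patient_spawned", bed_id][1:9]
  expect_identical(first_beds, c(1L, 4L, 7L, 2L, 5L, 8L, 3L, 6L, 9L))
  # beds 1-3 belong to doctor 1, 4-6 to doctor 2, 7-9 to doctor 3
  cfg <- default_config()
  expect_identical(cfg$doctors[[1]]$beds, 1:3)
  expect_identical(cfg$doctors[[2]]$beds, 4:6)
  expect_identical(cfg$doctors[[3]]$beds, 7:9)
})

test_that("freed beds refill oldest-freed-first after the initial sequence", {
  run <- run_shift(mini_config(shift_length_s = 900))
  ev <- run$events
  discharges <- ev[event == "patient_discharged", .(time_s, bed_id)]
  respawns <- ev[event == "patient_spawned"][-(1:3), .(time_s, bed_id)]
  skip_if(nrow(discharges) < 2, "not enough turnover in this window")
  # every respawn reuses the bed freed longest ago
  expect_identical(respawns$bed_id, discharges$bed_id[seq_len(nrow(respawns))])
})

test_that("examination takes 10 s and the request is broadcast once", {
  run <- run_shift(tiny_config())
  ev <- run$events
  expect_equal(ev[event == "exam_started", time_s][1], 0)
  expect_equal(ev[event == "request_issued", time_s][1], 10)
  # requested duration equals the gold duration of the requested level
  issued <- ev[event == "request_issued"]
  expect_equal(issued$value_s, gold_duration(issued$requested_level))
  # correct-style doctor: requested = true
  expect_identical(issued$requested_level, issued$true_level)
})

test_that("the nurse cycle is claim, travel, execute, complete, return", {
  run <- run_shift(tiny_config())
  ev <- run$events
  expect_equal(ev[event == "request_claimed", time_s][1], 10)
  expect_equal(ev[event == "task_started", time_s][1], 15) # + travel 5
  expect_equal(ev[event == "task_completed", time_s][1], 51) # + 40 * 0.9
  expect_equal(ev[event == "task_completed", value_s][1], 36)
  # completion time = claim + travel + execution for every task
  claims <- ev[event == "request_claimed", .(request_id, claim = time_s)]
  comps <- ev[event == "task_completed",
              .(request_id, done = time_s, dur = value_s)]
  j <- merge(claims, comps, by = "request_id")
  expect_equal(j$done, j$claim + 5 + j$dur)
})

test_that("degenerate closed form: served = floor(shift / cycle time)", {
  # cycle = exam 10 + travel 5 + 36 s execution; the return leg overlaps the
  # next examination
  for (shift in c(510, 500, 1020, 2000)) {
    run <- run_shift(tiny_config(shift_length_s = shift))
    expect_identical(run$metrics$totals$patients_served,
                     as.integer(floor(shift / 51)))
  }
})

test_that("identical configuration and seed give bit-identical outputs", {
  a <- run_shift(default_config(shift_length_s = 2000, seed = 17))
  b <- run_shift(default_config(shift_length_s = 2000, seed = 17))
  expect_identical(a$events, b$events)
  expect_identical(a$metrics, b$metrics)
  c <- run_shift(default_config(shift_length_s = 2000, seed = 18))
  expect_false(identical(a$events, c$events))
})

test_that("with no nurses nothing is served and every request waits out the shift", {
  cfg <- sim_config(doctors = list(doctor_profile(1)), nurses = list(),
                    n_beds = 2, shift_length_s = 400, noise = FALSE, seed = 1)
  run <- run_shift(cfg)
  expect_identical(run$metrics$totals$patients_served, 0L)
  issued <- run$events[event == "request_issued"]
  expect_gt(nrow(issued), 0)
  expect_equal(run$metrics$totals$total_delay_s, sum(400 - issued$time_s))
})

test_that("event logs satisfy conservation and exclusivity invariants", {
  for (cfgfn in list(
    function() default_config(shift_length_s = 3000, seed = 21),
    function() default_config(shift_length_s = 3000, seed = 22, policy = "fifo"),
    function() default_config(shift_length_s = 3000, seed = 23, scenario = "replacement"),
    function() default_config(shift_length_s = 3000, seed = 24, scenario = "training")
  )) {
    run <- run_shift(cfgfn())
    ev <- run$events
    spawned <- ev[event == "patient_spawned"]
    discharged <- ev[event == "patient_discharged"]
    # conservation: everyone spawned is served or still in a bed
    expect_identical(nrow(spawned) - nrow(discharged) <= run$config$n_beds, TRUE)
    expect_identical(run$metrics$totals$patients_spawned -
                       run$metrics$totals$patients_served,
                     nrow(spawned) - nrow(discharged))
    # no request completed twice
    expect_false(anyDuplicated(ev[event == "task_completed", request_id]) > 0)
    # no bed holds two patients: occupancy intervals per bed do not overlap
    occ <- merge(spawned[, .(patient_id, bed_id, t0 = time_s)],
                 discharged[, .(patient_id, t1 = time_s)],
                 by = "patient_id", all.x = TRUE)
    occ[is.na(t1), t1 := run$config$shift_length_s]
    setkey(occ, bed_id, t0)
    overlaps <- occ[, any(t0[-1] < t1[-.N]), by = bed_id]$V1
    expect_false(any(overlaps))
    # no nurse executes two tasks concurrently
    ex <- merge(ev[event == "task_started", .(request_id, nurse = actor_id, s = time_s)],
                ev[event == "task_completed", .(request_id, e = time_s)],
                by = "request_id")
    setkey(ex, nurse, s)
    nover <- ex[, if (.N > 1) any(s[-1] < e[-.N]) else FALSE, by = nurse]$V1
    expect_false(any(nover))
    # monotone non-decreasing times
    expect_true(all(diff(ev$time_s) >= 0))
  }
})

test_that("all-correct, all-high, noise-off shifts have zero damage and failures", {
  cfg <- sim_config(
    doctors = list(doctor_profile(1), doctor_profile(2), doctor_profile(3)),
    nurses = list(nurse_profile(1, "high"), nurse_profile(2, "high")),
    shift_length_s = 3000, noise = FALSE, seed = 9)
  run <- run_shift(cfg)
  expect_identical(run$metrics$totals$failures, 0L)
  expect_equal(run$metrics$totals$time_damage_s, 0)
  expect_gt(run$metrics$totals$patients_served, 0)
})

test_that("the event engine matches the 1-second time-stepping oracle", {
  cases <- list(
    mini_config(policy = "fifo", shift_length_s = 600, seed = 5),
    mini_config(policy = "ca", shift_length_s = 600, seed = 5),
    mini_config(policy = "ca", shift_length_s = 600, seed = 31),
    sim_config(doctors = list(doctor_profile(1)),
               nurses = list(nurse_profile(1, "low")),
               n_beds = 2, shift_length_s = 500, noise = FALSE, seed = 8)
  )
  for (cfg in cases) {
    eng <- engine_sequences(run_shift(cfg))
    orc <- step_sim(cfg)
    expect_identical(eng$served, orc$served)
    expect_equal(as.data.frame(eng$spawns), as.data.frame(orc$spawns))
    expect_equal(as.data.frame(eng$claims[, .(t, nurse, rid)]),
                 as.data.frame(orc$claims))
    expect_equal(as.data.frame(eng$completions[, .(t, rid, nurse)]),
                 as.data.frame(orc$completions))
  }
})

test_that("FIFO is rejected outside the baseline scenario", {
  expect_error(default_config(policy = "fifo", scenario = "training"),
               "baseline")
  expect_error(default_config(policy = "fifo", scenario = "replacement"),
               "baseline")
})

test_that("an unreliable nurse never claims above her cap", {
  run <- run_shift(default_config(seed = 4, shift_length_s = 10000))
  ev <- run$events
  sa <- ev[event == "self_assessed_unreliable"]
  skip_if(nrow(sa) == 0, "no self-assessment in this window")
  nid <- sa$actor_id[1]
  t_sa <- sa$time_s[1]
  later_claims <- ev[event == "request_claimed" & actor_id == nid & time_s > t_sa]
  expect_true(all(later_claims$requested_level <= 2))
})

test_that("the replacement hook spawns one extra high performer who takes hard tasks", {
  run <- run_shift(default_config(scenario = "replacement", seed = 4,
                                  shift_length_s = 10000))
  ev <- run$events
  sp <- ev[event == "nurse_spawned"]
  expect_identical(nrow(sp), 1L)
  expect_identical(sp$detail, "high")
  new_id <- sp$actor_id
  claims <- ev[event == "request_claimed" & actor_id == new_id]
  expect_gt(nrow(claims), 0)
  expect_true(any(claims$requested_level > 2))
})

test_that("training scenario: trainer arrives, skill improves, trainer leaves", {
  cfg <- default_config(scenario = "training", seed = 4, noise = FALSE,
                        training = training_params(decrement = 0.05))
  run <- run_shift(cfg)
  ev <- run$events
  expect_identical(nrow(ev[event == "trainer_spawned"]), 1L)
  expect_identical(nrow(ev[event == "trainer_left"]), 1L)
  trainee <- ev[event == "trainer_spawned", actor_id]
  t_start <- ev[event == "trainer_spawned", time_s]
  t_end <- ev[event == "trainer_left", time_s]
  # mentored completions at a given true level get faster over the phase
  cmp <- ev[event == "task_completed" & actor_id == trainee &
              time_s > t_start & time_s <= t_end]
  lv <- cmp[, .N, by = true_level][which.max(N), true_level]
  d <- cmp[true_level == lv, value_s]
  skip_if(length(d) < 4, "too few mentored tasks at one level")
  half <- floor(length(d) / 2)
  expect_lt(mean(d[(half + 1):length(d)]), mean(d[1:half]))
  # after training the nurse keeps working at full range
  late <- ev[event == "request_claimed" & actor_id == trainee & time_s > t_end]
  expect_gt(nrow(late), 0)
})

test_that("baseline and replacement runs share a prefix up to the first self-assessment", {
  a <- run_shift(default_config(scenario = "baseline", seed = 6,
                                shift_length_s = 6000))
  b <- run_shift(default_config(scenario = "replacement", seed = 6,
                                shift_length_s = 6000))
  t_sa <- a$events[event == "self_assessed_unreliable", time_s][1]
  skip_if(is.na(t_sa), "no self-assessment in this window")
  pre_a <- a$events[time_s < t_sa & event != "shift_end"]
  pre_b <- b$events[time_s < t_sa & event != "shift_end"]
  expect_identical(as.data.frame(pre_a), as.data.frame(pre_b))
})
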