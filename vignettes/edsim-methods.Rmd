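---
title: "Trust-aware task allocation in a simulated emergency department: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trust-aware task allocation in a simulated emergency department: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edsim)
library(data.table)
```

## The system being modeled

`edsim` simulates one shift of a small emergency room as a discrete-event
agent-based system. Three kinds of agents interact around a fixed set of
beds:

* **Doctors** own disjoint blocks of beds (with 9 beds and 3 doctors, doctor
  1 owns beds 1–3, doctor 2 beds 4–6, doctor 3 beds 7–9). A doctor examines
  each newly bedded patient for a fixed 10 s and then broadcasts exactly one
  nursing task request (an IV-catheter insertion) to all nurses. The request
  carries a difficulty level from 1 (easiest) to 5 (most difficult) and the
  corresponding expected duration.
* **Nurses** hold a local store of broadcast requests and repeatedly claim
  one, travel to the bed, execute the task, and return to the staff waiting
  room. Claiming removes a request from every store, so the stores behave as
  one shared pending pool with per-nurse eligibility filters.
* **Patients** arrive under saturated demand: the nine beds are filled at
  t = 0 in the interleaved order 1, 4, 7, 2, 5, 8, 3, 6, 9 — so every doctor
  is engaged as early as possible — and each freed bed is refilled
  immediately (oldest-freed first once the initial sequence is exhausted).

Space is abstracted to a single configurable travel time per leg (default
5 s); geometry is presentation, not mechanics.

## Competence models

**Difficulty and duration.** The gold-standard execution time is linear in
the level, `70 - 10 * level` seconds, i.e. 60 s at level 1 down to 20 s at
level 5: harder tasks are more urgent and demand faster execution. The map is
configurable; the default is the minimal model through the two anchor points
(level 3 = 40 s, level 5 = 20 s) that define the scale.

**Doctor evaluation styles.** A doctor estimates the level `correct`ly, or
systematically `overestimate`s / `underestimate`s it by a configurable bias
(default 2 levels, clamped to 1..5). The *requested* level, not the true one,
sets the expected duration used for success labeling, so an overestimating
doctor imposes a stricter time threshold and an underestimating doctor a
laxer one.

**Nurse quality.** A nurse's execution time is

```
duration = gold(true level) * speed_factor * exp(noise_sd * z),  z ~ N(0, 1)
```

High performers default to `speed_factor` 0.9, low performers to 1.5 —
so with correct doctors a high performer almost always meets the requested
duration and a low performer essentially never does. The lognormal noise
scale is 0.05 for high quality and 0.25 for low ("slower *and more
variable*"). The high-quality scale is deliberately small: with a larger
scale (say 0.10) a high performer fails ~15% of correctly requested tasks,
and over the ~600 tasks of a shift a short failure streak will almost surely
push one of her trust weights below the reliability threshold — the whole
roster then self-restricts and the baseline ward deadlocks, which
contradicts the premise that high performers remain reliable providers. At
0.05 the per-shift probability of a spurious self-restriction is below 1%.
A `noise = FALSE` mode makes every duration deterministic for testing.

## The trust model and the FIFO comparator

Each nurse keeps one trust weight per difficulty level, initialized
optimistically at `w0 = 0.8`. After completing a task at requested level
`l` with binary outcome `s` (success iff the actual execution time does not
exceed the requested duration, non-strict), the weight is smoothed toward
the outcome:

```
w[l] <- w[l] + alpha * (s - w[l]),  alpha = 0.2
```

The exact update rule of the underlying trust literature is not fixed here;
exponential smoothing toward the binary outcome is adopted as a transparent
stand-in that preserves the mechanics that matter — feedback-driven weights
in [0, 1] with geometric forgetting, so all-success streams converge to 1 and
all-failure streams to 0 with closed-form trajectories the tests verify.

**Self-assessment.** After each update the nurse checks every level with at
least `min_attempts = 3` attempts; if any weight has fallen strictly below
`threshold = 0.5` she classifies herself unreliable. Self-assessment is
per-level but the consequence is global: she restricts herself to levels at
or below the configured cap (default 2). The warm-up guard prevents judging
a level on one or two unlucky tasks. With the defaults, a failing streak at
one level needs three attempts, and `0.8 * 0.8^3 = 0.41 < 0.5`, so a
persistent low performer self-assesses after roughly her third failure at
some level.

**Task selection.** Under the trust policy a nurse claims the *oldest*
pending request whose requested level she currently accepts (everything when
reliable; up to the cap when restricted; everything again while a trainer
supervises her). Under FIFO she claims the oldest request unconditionally.
Ties on issue time break toward the lower request id, and simultaneous
claims resolve in nurse-id order — both chosen once so a run replays
deterministically. FIFO has no self-assessment, so it is only valid in the
baseline scenario and the configuration layer rejects other combinations.

## Scenarios

All three scenarios react to the *first* self-assessment of each nurse (the
hook fires at most once per nurse):

* **Baseline** — the nurse is capped; no staffing change. If no eligible
  task is pending she idles in the waiting room.
* **Replacement** — one additional high-performing nurse spawns in the
  waiting room and immediately starts claiming; because pending requests
  live in the shared pool, the backlog of above-cap requests passes to her
  naturally, and she keeps serving all levels until shift end.
* **Training** — a trainer attaches to the nurse. The trainer supervises but
  never executes. The trainee keeps claiming all levels; each completed task
  under supervision decrements her speed factor by `decrement` (default
  0.0025) until it reaches the high-quality factor 0.9, with her noise scale
  interpolated toward the high-quality 0.05 in step. The trainer then
  leaves, her trust weights are re-initialized at `w0`, and she resumes full
  responsibilities — without the reset, stale sub-threshold weights would
  instantly re-flag a nurse who is now demonstrably fast.

The default decrement spreads the learning curve over roughly 240 supervised
completions, i.e. most of an 8-hour shift of continuous work. This models a
manual skill (IV-catheter insertion) that improves gradually with practice
rather than after a handful of demonstrations; it also makes the
within-shift learning trajectory observable in the logged task durations,
which is the quantity the experiments track. A larger decrement (e.g. 0.05)
compresses training into a few minutes and is used in tests where only the
completion mechanics matter.

## Metrics

All metrics are computed *from the event log alone*, so replaying a written
`events.csv` reproduces a run's metrics bit for bit. Per shift, per doctor
and per nurse:

* **patients served** — discharges; a patient is served when the one
  requested task is completed (regardless of its success label; the label
  reflects the doctor's possibly biased expectation, not whether care
  happened);
* **time damage** — `max(0, actual - requested duration)` summed over
  completed tasks, charged to the executing nurse and the requesting doctor.
  The reference is the doctor-requested duration, consistent with the
  success labeling;
* **total delay** — time a patient waits with an issued but unattended
  request. By default the wait ends when a nurse *commits* (claims);
  travel-to-bed counts as attention. The alternative convention (wait ends
  at arrival) is available as `count_travel_as_delay`; a request never
  attended accrues delay until shift end;
* **success / failure counts and utility** — utility grows by the requested
  level of each successful task (1..5);
* **doctor evaluation accuracy** — fraction of issued requests whose
  requested level equals the true level, plus per-doctor delay totals.

A task found already completed on arrival is abandoned silently and charges
nothing; with claim-removal from the shared pool this is a defensive branch
rather than a common path.

## Reproducibility and numerics

A run is a pure function of (configuration, seed). The master seed derives
one RNG substream per doctor (difficulty draws) and per nurse (duration
noise), plus a reserved stream for a spawned replacement nurse, so adding an
agent in one scenario does not perturb the draws of the others: arms of an
experiment with the same seed are common-random-number paired, and a
baseline and a replacement run coincide event-for-event until the first
self-assessment. Event-time ties break by kind (completion, exam end,
arrival, return), then actor, then scheduling order. Event logs are written
with shortest-exact decimal formatting so a log read back from disk carries
the same doubles.

The experiments layer runs the four scenario–policy combinations
(baseline–trust, baseline–FIFO, replacement–trust, training–trust) with
seeds `base_seed + replicate - 1`, 60 replicates by default, and reports
Welch t-tests, Wilcoxon rank-sum tests, Cohen's d, Shapiro–Wilk checks and
an optional omnibus ANOVA side by side, with optional Holm adjustment — the
battery is fixed and reported in full rather than auto-selected. No
multiple-testing correction is applied by default; the tool is exploratory.

## What the defaults represent, and known limitations

The default configuration is the small-ER case study: 9 beds, 3 correct
doctors, one high and one low performer, an 8-hour (28,800 s) shift, true
difficulties uniform on 1..5. Test and example runs in the documentation use
shorter shifts (600–6,000 s) and the batch analyses 30 paired seeds per arm;
these sizes make the distributional checks stable while keeping the suite
quick to run.

Structural limitations worth knowing:

* **Damage concentrates on easy tasks.** Because the slowdown is
  multiplicative and the gold duration *decreases* with level, a slow
  nurse's absolute overrun `(speed_factor - 1) * gold(level)` is largest on
  the easiest tasks. Confining a low performer to levels ≤ 2 therefore does
  not reduce her damage per completed task — it increases it — and in the
  saturated ward she stays busy on the easy-task backlog. In this regime the
  trust baseline beats FIFO on low-performer *failure counts* and the
  replacement arm on *delay*, but total time damage under the trust baseline
  sits within a few percent of FIFO rather than clearly below it. A
  level-dependent (non-multiplicative) competence model would change this;
  the package keeps the multiplicative form because it is the one the
  duration examples define.
* One task type, one task per patient; no triage prioritization, no
  nurse-to-nurse delegation or re-broadcast of ignored requests (an
  ineligible request simply stays pending).
* No fatigue, stress or shift-transition effects; agent behavior is
  rule-based, not learned from data.
* The trainer is not a spatial agent; mentoring is modeled purely through
  the trainee's parameters.

## A worked miniature

```{r example}
cfg <- default_config(shift_length_s = 3600, seed = 42)
run <- run_shift(cfg)
run$metrics$totals
run$metrics$per_nurse
```

The per-nurse table shows the asymmetry the trust model reacts to: the low
performer fails essentially every task she completes, self-assesses
unreliable after a few attempts, and spends the rest of the shift on
level ≤ 2 requests.

```{r batch}
plan <- experiment_plan(default_config(shift_length_s = 3600),
                        n_runs = 5, base_seed = 1)
batch <- run_batch(plan)
summarize_tradeoffs(batch$runs)
```
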