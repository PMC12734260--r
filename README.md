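# edsim — trust-aware simulation of emergency-department task allocation

`edsim` is a headless, reproducible discrete-event agent-based simulator for
studying how nurse task-allocation policies and staffing responses shape the
operation of a small emergency room. It is aimed at healthcare-operations
researchers and hospital decision-makers who want to compare "what-if"
staffing policies under controlled, repeatable conditions before touching a
real ward.

## The model in brief

Doctors own fixed blocks of the nine beds, examine each newly bedded patient
for 10 s, and broadcast one nursing task request (IV-catheter insertion)
carrying a difficulty level *l* ∈ {1, …, 5} and the expected duration
*g(l) = 70 − 10 l* seconds (level 3 → 40 s, level 5 → 20 s; harder tasks are
more urgent). A doctor's evaluation style may bias the requested level up or
down. A nurse of quality *q* executes a task of true level *l* in

&nbsp;&nbsp;&nbsp;&nbsp;*t = g(l) · s_q · exp(σ_q z)*, *z* ~ N(0, 1),

with speed factor *s* = 0.9 (high performers) or 1.5 (low performers) and
noise scale σ = 0.05 / 0.25. A task *succeeds* iff *t* does not exceed the
doctor-requested duration.

Two allocation policies are implemented. Under **FIFO** every idle nurse
claims the oldest pending request. Under the **trust policy** each nurse
keeps a per-level trust weight updated from outcome feedback,

&nbsp;&nbsp;&nbsp;&nbsp;*w_l ← w_l + α (s − w_l)*, α = 0.2, *s* ∈ {0, 1},

and self-assesses as unreliable when any sufficiently attempted level falls
strictly below θ = 0.5. Three scenarios respond to that event: **baseline**
(the nurse restricts herself to levels ≤ 2), **replacement** (an extra high
performer is spawned to absorb the harder tasks), and **training** (a mentor
supervises her; each completed task under supervision improves her speed and
consistency until she reaches high-performer parameters and the mentor
leaves).

Each shift yields an event log and metrics at total / per-doctor / per-nurse
granularity: patients served, time damage (positive overrun of actual vs
requested duration), total patient delay, success/failure counts, utility
(sum of requested levels of successful tasks) and doctor evaluation
accuracy. The metrics are a pure function of the event log, so any written
log replays to bit-identical metrics.

## A worked example

```r
library(edsim)

cfg <- default_config(shift_length_s = 3600, seed = 42) # 1 h, case-study roster
run <- run_shift(cfg)
run
#> <ed_run> baseline-ca-seed42: 120 patients served, damage 1164.6 s, delay 24417.0 s (878 events)
run$metrics$per_nurse
#>    nurse_id quality tasks_completed successes failures utility time_damage_s
#> 1:        1    high              81        81        0     264         0.000
#> 2:        2     low              39         3       36       4      1164.602
```

The high performer (factor 0.9) meets every correctly requested duration;
the low performer (factor 1.5) fails almost every task, self-assesses
unreliable after a few attempts, and spends the rest of the shift on
level ≤ 2 requests — all of the shift's time damage is hers.

Batch comparison of the four scenario–policy arms with paired seeds:

```r
plan <- experiment_plan(default_config(shift_length_s = 3600), n_runs = 5, base_seed = 1)
batch <- run_batch(plan)
summarize_tradeoffs(batch$runs)
#>             combo     n patients_served total_delay_s time_damage_s failures_lowq utility_total
#> 1:    baseline_ca     5           126.8      24492.01     1053.0560          36.8         314.8
#> 2:  baseline_fifo     5           129.0      24377.54     1029.7110          48.6         241.0
#> 3: replacement_ca     5           193.8      20904.62     1066.8394          37.2         509.6
#> 4:    training_ca     5           130.4      24369.95      961.7791          50.0         236.8
#>  * max patients served: replacement_ca (193.8)
#>  * min total delay: replacement_ca (20904.6)
#>  * min time damage: training_ca (961.8)
#>  * fewest low-performer failures: baseline_ca (36.8)
```

Replacement buys throughput and shorter waits at the cost of an extra
nurse; the trust baseline keeps the low performer away from urgent
high-level tasks (fewest of her failures); training converts her into a
high performer within the shift. `compare_arms()` /
`comparison_report()` add Welch and rank-sum tests with effect sizes for any
metric and pair of arms.

A thin command-line front end lives at `inst/cli/edsim.R`
(`run`, `experiment`, `replay`, `config-init` subcommands); configurations
are plain YAML, dumpable via `write_default_config()`.

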