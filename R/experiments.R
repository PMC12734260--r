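# Batch experimentation and the statistical comparison layer.

DEFAULT_COMBINATIONS <- list(
  c(scenario = "baseline", policy = "ca"),
  c(scenario = "baseline", policy = "fifo"),
  c(scenario = "replacement", policy = "ca"),
  c(scenario = "training", policy = "ca")
)

#' Experiment plan
#'
#' A batch design: a set of scenario-policy combinations, each replicated
#' `n_runs` times with seeds `base_seed + replicate - 1`. Seeds are shared
#' across combinations at equal replicate index (common random numbers), so
#' arm comparisons can be paired.
#'
#' @param template An [sim_config()] supplying everything but scenario,
#'   policy and seed.
#' @param combinations List of `c(scenario = , policy = )` pairs. The default
#'   is the four-arm design: baseline-ca, baseline-fifo, replacement-ca,
#'   training-ca.
#' @param n_runs Replicates per combination (default 60).
#' @param base_seed First seed.
#' @return A list of class `ed_plan`.
#' @export
experiment_plan <- function(template = default_config(),
                            combinations = DEFAULT_COMBINATIONS,
                            n_runs = 60L, base_seed = 1L) {
  stopifnot(inherits(template, "ed_config"), n_runs >= 1)
  for (cb in combinations) {
    stopifnot(all(c("scenario", "policy") %in% names(cb)))
  }
  structure(list(template = template, combinations = combinations,
                 n_runs = as.integer(n_runs), base_seed = as.integer(base_seed)),
            class = "ed_plan")
}

combo_label <- function(cb) paste(cb[["scenario"]], cb[["policy"]], sep = "_")

config_for <- function(plan, cb, seed) {
  cfg <- plan$template
  sim_config(
    doctors = lapply(cfg$doctors, function(d) doctor_profile(d$id, d$style, d$bias_magnitude)),
    nurses = cfg$nurses,
    scenario = cb[["scenario"]], policy = cb[["policy"]],
    n_beds = cfg$n_beds, shift_length_s = cfg$shift_length_s,
    travel_time_s = cfg$travel_time_s, exam_duration_s = cfg$exam_duration_s,
    level_durations = cfg$level_durations,
    difficulty_probs = cfg$difficulty_probs, noise = cfg$noise,
    trust = cfg$trust, training = cfg$training,
    replacement_quality = cfg$replacement_quality,
    count_travel_as_delay = cfg$count_travel_as_delay,
    seed = seed,
    run_id = sprintf("%s_seed%d", combo_label(cb), seed)
  )
}

trainee_thirds <- function(run) {
  # mean executed durations of the initially low-quality nurse per shift third
  low_ids <- run$events[event == "on_duty" & actor_type == "nurse" &
                          detail == "low", actor_id]
  if (!length(low_ids)) return(rep(NA_real_, 3))
  cmp <- run$events[event == "task_completed" & actor_id == low_ids[1L]]
  if (!nrow(cmp)) return(rep(NA_real_, 3))
  len <- run$config$shift_length_s
  third <- pmin(3L, 1L + floor(3 * cmp$time_s / len))
  vapply(1:3, function(k) {
    if (any(third == k)) mean(cmp$value_s[third == k]) else NA_real_
  }, numeric(1))
}

run_row <- function(run, combo, replicate) {
  tot <- run$metrics$totals
  pn <- run$metrics$per_nurse
  th <- trainee_thirds(run)
  data.table::data.table(
    run_id = run$run_id, combo = combo,
    scenario = run$config$scenario, policy = run$config$policy,
    seed = run$config$seed, replicate = replicate,
    patients_served = tot$patients_served,
    time_damage_s = tot$time_damage_s,
    total_delay_s = tot$total_delay_s,
    successes = tot$successes, failures = tot$failures,
    failures_lowq = sum(pn[quality == "low", failures]),
    utility_total = tot$utility_total,
    tasks_completed = tot$tasks_completed,
    trainee_dur_third1 = th[1], trainee_dur_third2 = th[2],
    trainee_dur_third3 = th[3]
  )
}

#' Run a batch of seeded replicates
#'
#' Executes every combination of the plan for `n_runs` replicates and
#' concatenates per-run, per-doctor and per-nurse metric tables. A failed run
#' aborts with its seed and combination echoed.
#'
#' @param plan An [experiment_plan()].
#' @param keep_runs If `TRUE`, the individual `ed_run` objects are returned
#'   too (memory-heavy; off by default).
#' @return A list of class `ed_batch` with data.tables `runs`, `doctors`,
#'   `nurses` (and optionally `run_objects`).
#' @export
run_batch <- function(plan, keep_runs = FALSE) {
  stopifnot(inherits(plan, "ed_plan"))
  rows <- list(); drows <- list(); nrows <- list(); robjs <- list()
  for (cb in plan$combinations) {
    combo <- combo_label(cb)
    for (r in seq_len(plan$n_runs)) {
      seed <- plan$base_seed + r - 1L
      run <- tryCatch(run_shift(config_for(plan, cb, seed)),
                      error = function(e) {
        stop(sprintf("run failed for combination %s, seed %d: %s",
                     combo, seed, conditionMessage(e)), call. = FALSE)
      })
      key <- paste(combo, r)
      rows[[key]] <- run_row(run, combo, r)
      drows[[key]] <- cbind(run_id = run$run_id, combo = combo,
                            run$metrics$per_doctor)
      nrows[[key]] <- cbind(run_id = run$run_id, combo = combo,
                            run$metrics$per_nurse)
      if (keep_runs) robjs[[key]] <- run
    }
  }
  out <- list(runs = data.table::rbindlist(rows),
              doctors = data.table::rbindlist(drows),
              nurses = data.table::rbindlist(nrows))
  if (keep_runs) out$run_objects <- robjs
  structure(out, class = "ed_batch")
}

#' @export
print.ed_batch <- function(x, ...) {
  cat(sprintf("<ed_batch> %d runs over %d combinations\n",
              nrow(x$runs), length(unique(x$runs$combo))))
  print(x$runs[, .(runs = .N, mean_served = mean(patients_served),
                   mean_damage_s = mean(time_damage_s),
                   mean_delay_s = mean(total_delay_s)), by = combo])
  invisible(x)
}

cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) return(if (mean(a) == mean(b)) 0 else Inf * sign(mean(a) - mean(b)))
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Compare one metric between two experiment arms
#'
#' Reports a Welch two-sample t-test, a Wilcoxon rank-sum test, Cohen's d,
#' and Shapiro-Wilk normality checks for both arms. It chooses nothing for
#' the user; all statistics are reported side by side. Degenerate inputs
#' (identical zero-variance samples) are flagged instead of crashing.
#'
#' @param runs The `runs` table of an [run_batch()] result.
#' @param metric Column name to compare (e.g. `"patients_served"`).
#' @param combo_a,combo_b Combination labels (e.g. `"baseline_fifo"`).
#' @return One-row data.table with means, sds, medians, IQRs, test
#'   statistics, p-values, effect size, and a `flag` column.
#' @export
compare_arms <- function(runs, metric, combo_a, combo_b) {
  stopifnot(metric %in% names(runs))
  a <- runs[combo == combo_a][[metric]]
  b <- runs[combo == combo_b][[metric]]
  if (length(a) < 2 || length(b) < 2) {
    stop("both combinations need at least 2 runs", call. = FALSE)
  }
  degenerate <- stats::var(a) == 0 && stats::var(b) == 0
  welch <- if (!degenerate) stats::t.test(a, b) else NULL
  ranksum <- if (!degenerate) {
    suppressWarnings(stats::wilcox.test(a, b))
  } else NULL
  shapiro_p <- function(x) {
    if (stats::var(x) == 0 || length(x) < 3) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  data.table::data.table(
    metric = metric, combo_a = combo_a, combo_b = combo_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sd_a = stats::sd(a), sd_b = stats::sd(b),
    median_a = stats::median(a), median_b = stats::median(b),
    iqr_a = stats::IQR(a), iqr_b = stats::IQR(b),
    t_stat = if (degenerate) NA_real_ else unname(welch$statistic),
    t_p = if (degenerate) NA_real_ else welch$p.value,
    w_stat = if (degenerate) NA_real_ else unname(ranksum$statistic),
    w_p = if (degenerate) NA_real_ else ranksum$p.value,
    cohens_d = cohens_d(a, b),
    shapiro_p_a = shapiro_p(a), shapiro_p_b = shapiro_p(b),
    flag = if (degenerate) "degenerate: both arms constant" else NA_character_
  )
}

#' Full pairwise comparison report
#'
#' All pairwise arm comparisons for the given metrics, with an optional
#' omnibus one-way ANOVA across all arms and optional Holm adjustment of the
#' pairwise p-values.
#'
#' @param runs The `runs` table of an [run_batch()] result.
#' @param metrics Metric columns to compare.
#' @param holm Apply Holm adjustment to the Welch and rank-sum p-values.
#' @return A list with `pairwise` (data.table) and `anova` (data.table of
#'   omnibus F-test per metric).
#' @export
comparison_report <- function(runs,
                              metrics = c("patients_served", "time_damage_s",
                                          "total_delay_s", "failures_lowq"),
                              holm = FALSE) {
  combos <- unique(runs$combo)
  pw <- list()
  for (m in metrics) {
    if (length(combos) >= 2) {
      prs <- utils::combn(combos, 2, simplify = FALSE)
      for (p in prs) pw[[paste(m, p[1], p[2])]] <- compare_arms(runs, m, p[1], p[2])
    }
  }
  pairwise <- data.table::rbindlist(pw)
  if (holm && nrow(pairwise)) {
    pairwise[, t_p_holm := stats::p.adjust(t_p, "holm")]
    pairwise[, w_p_holm := stats::p.adjust(w_p, "holm")]
  }
  an <- lapply(metrics, function(m) {
    if (length(combos) < 2 || stats::var(runs[[m]]) == 0) {
      return(data.table::data.table(metric = m, f_stat = NA_real_, f_p = NA_real_))
    }
    fit <- stats::aov(stats::as.formula(paste(m, "~ combo")), data = runs)
    s <- summary(fit)[[1]]
    data.table::data.table(metric = m, f_stat = s$`F value`[1], f_p = s$`Pr(>F)`[1])
  })
  list(pairwise = pairwise, anova = data.table::rbindlist(an))
}

#' Summarize policy trade-offs across arms
#'
#' Per-combination means of the headline metrics plus directional flags
#' naming the arm that maximizes throughput and the arms that minimize delay,
#' damage and low-performer failures. With a single (or identical) arm no
#' flags are emitted.
#'
#' @param runs The `runs` table of an [run_batch()] result.
#' @return A list of class `ed_tradeoffs` with `summary` (data.table) and
#'   `flags` (character vector).
#' @export
summarize_tradeoffs <- function(runs) {
  s <- runs[, .(n = .N,
                patients_served = mean(patients_served),
                total_delay_s = mean(total_delay_s),
                time_damage_s = mean(time_damage_s),
                failures_lowq = mean(failures_lowq),
                utility_total = mean(utility_total)),
            by = combo]
  flags <- character()
  flag_of <- function(col, best, label) {
    v <- s[[col]]
    if (length(unique(round(v, 10))) < 2) return(NULL)
    i <- if (best == "max") which.max(v) else which.min(v)
    sprintf("%s: %s (%.1f)", label, s$combo[i], v[i])
  }
  flags <- c(
    flag_of("patients_served", "max", "max patients served"),
    flag_of("total_delay_s", "min", "min total delay"),
    flag_of("time_damage_s", "min", "min time damage"),
    flag_of("failures_lowq", "min", "fewest low-performer failures")
  )
  structure(list(summary = s, flags = flags %||% character()),
            class = "ed_tradeoffs")
}

#' @export
print.ed_tradeoffs <- function(x, ...) {
  print(x$summary)
  for (f in x$flags) cat(" *", f, "\n")
  invisible(x)
}
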