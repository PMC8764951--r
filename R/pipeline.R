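#' Study design: groups, group sizes and session schedule
#'
#' Defaults mirror the emulated study: sham n = 7, neuropathic (NRP) n = 9,
#' Valerian-treated neuropathic (VAL_NRP) n = 8 (24 animals), each recorded
#' in three 150-minute sessions (450 minutes per animal) with behavioural
#' assays on days 3 and 6.
#'
#' @param n_animals named integer vector of group sizes.
#' @param sessions recording session labels.
#' @param session_minutes minutes per session.
#' @param behavior_days behavioural assay days.
#' @return object of class `study_design`.
#' @export
study_design <- function(n_animals = c(SHAM = 7, NRP = 9, VAL_NRP = 8),
                         sessions = STUDY_SESSIONS, session_minutes = 150,
                         behavior_days = BEHAVIOR_DAYS) {
  if (!all(names(n_animals) %in% STUDY_GROUPS) || any(n_animals < 1))
    stop_input("n_animals must be positive and named over %s",
               paste(STUDY_GROUPS, collapse = ", "))
  structure(list(n_animals = n_animals, sessions = sessions,
                 session_minutes = session_minutes,
                 behavior_days = behavior_days),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %s; %d sessions x %g min (%g min/animal)\n",
              paste(sprintf("%s n=%d", names(x$n_animals), x$n_animals),
                    collapse = ", "),
              length(x$sessions), x$session_minutes,
              length(x$sessions) * x$session_minutes))
  invisible(x)
}

#' Recording schedule implied by a design
#'
#' @param design a [study_design()].
#' @return data frame with one row per animal-session: `animal_id`, `group`,
#'   `session`, `minutes`.
#' @export
study_schedule <- function(design) {
  stopifnot(inherits(design, "study_design"))
  rows <- list()
  for (g in names(design$n_animals)) for (a in seq_len(design$n_animals[[g]]))
    for (s in design$sessions)
      rows[[length(rows) + 1L]] <-
        data.frame(animal_id = sprintf("%s_%02d", g, a), group = g,
                   session = s, minutes = design$session_minutes)
  do.call(rbind, rows)
}

# synthesize a constant-state segment for exemplar construction (the in-silico
# analogue of visually picking a typical stretch)
synth_state_segment <- function(config, state, duration = 40, seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  fs <- config$sampling_rate
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1L) / fs
  sp <- config$state_spectra[[state]]
  eeg <- numeric(n)
  if (nrow(sp$components) > 0L) for (j in seq_len(nrow(sp$components)))
    eeg <- eeg + sp$components[j, 2L] *
      sin(2 * pi * sp$components[j, 1L] * tt + stats::runif(1L, 0, 2 * pi))
  if (sp$noise > 0) eeg <- eeg + one_over_f_noise(n, fs) * sp$noise
  emg <- stats::rnorm(n) * config$emg_tone[[state]]
  exemplar(state, eeg, emg, fs)
}

#' Build a training exemplar set from the generator
#'
#' One constant-state segment per vigilance state, drawn from the same
#' spectral model as the recordings.
#'
#' @param config a [sim_config()].
#' @param duration seconds per exemplar (>= 30).
#' @param seed RNG seed.
#' @return list of three [exemplar()] objects.
#' @export
make_exemplars <- function(config, duration = 40, seed = config$seed) {
  lapply(seq_along(SLEEP_STATES), function(i)
    synth_state_segment(config, SLEEP_STATES[i], duration, seed + i))
}

#' Run the full in-silico study
#'
#' Simulates every animal-session in the design, stages each recording with
#' an exemplar-trained KNN stager, detects and characterises spindles, scores
#' the behavioural assays, and runs the study's comparison plan (within-group
#' across sessions, between-group per session) on REM%, NREM%, spindle
#' density, spindle mean frequency, allodynia withdrawals and EPM closed-arm
#' percentage. Deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param config a [sim_config()]; its `session_minutes` is overridden by the
#'   design's.
#' @param out optional output directory; when given, per-recording hypnograms
#'   and event lists, the summary tables and a Markdown report are written.
#' @param quick logical; the desk-scale profile (15-minute sessions at
#'   250 Hz) so the full 24-animal study runs in minutes. The full-scale
#'   profile (150 min at 3000 Hz) is the study's acquisition geometry.
#' @param seed master seed (default `config$seed`).
#' @param k,band,k_sd staging and detection parameters.
#' @return object of class `study_result`: `summaries` (one row per
#'   animal-session), `behavior` (one row per animal-day), `stats` (one row
#'   per planned comparison), plus `design`, `config`, `seed`.
#' @export
run_study <- function(design = study_design(), config = sim_config(),
                      out = NULL, quick = FALSE, seed = config$seed,
                      k = 5, band = c(12, 20), k_sd = 2.5) {
  stopifnot(inherits(design, "study_design"), inherits(config, "sim_config"))
  cfg <- config
  if (quick) {
    cfg$session_minutes <- 15
    cfg$sampling_rate <- 250
  } else {
    cfg$session_minutes <- design$session_minutes
  }

  exemplars <- make_exemplars(cfg, seed = seed + 777L)
  stager <- fit_stager(exemplars, k = k, epoch_length = cfg$epoch_length)

  sched <- study_schedule(design)
  sched$minutes <- cfg$session_minutes
  summaries <- vector("list", nrow(sched))
  artifacts <- list()
  for (i in seq_len(nrow(sched))) {
    rseed <- seed + 13L * i
    sim <- synthesize_recording(cfg, sched$group[i], sched$session[i],
                                animal_id = sched$animal_id[i], seed = rseed)
    hyp <- score_recording(stager, sim$recording)
    ev <- find_spindles(sim$recording, hyp, band = band, k_sd = k_sd)
    pc <- stage_percentages(hyp)
    ss <- spindle_summary(ev, hyp)
    summaries[[i]] <- data.frame(
      animal_id = sched$animal_id[i], group = sched$group[i],
      session = sched$session[i],
      pct_wake = pc[["pct_wake"]], pct_nrem = pc[["pct_nrem"]],
      pct_rem = pc[["pct_rem"]],
      spindle_density = ss[["density"]],
      spindle_mean_freq_hz = ss[["mean_freq_hz"]],
      spindle_mean_rms_uV = ss[["mean_rms_uV"]],
      n_spindles = ss[["n_events"]])
    if (!is.null(out))
      artifacts[[i]] <- list(hyp = hyp, events = ev,
                             name = sprintf("%s_%s", sched$animal_id[i],
                                            sched$session[i]))
  }
  summaries <- do.call(rbind, summaries)

  behavior <- list()
  for (g in names(design$n_animals)) for (d in design$behavior_days) {
    tab <- simulate_behavior(cfg, g, d, n_animals = design$n_animals[[g]],
                             seed = seed + 31L * match(g, STUDY_GROUPS) +
                               7L * match(d, BEHAVIOR_DAYS))
    sc <- score_behavior(tab)
    sc$group <- g
    behavior[[length(behavior) + 1L]] <- sc
  }
  behavior <- do.call(rbind, behavior)

  stats_rows <- run_comparison_plan(summaries, behavior, design)

  res <- structure(list(summaries = summaries, behavior = behavior,
                        stats = stats_rows, design = design, config = cfg,
                        seed = seed),
                   class = "study_result")
  if (!is.null(out)) write_study_result(res, artifacts, out)
  res
}

# the study's planned comparisons over the processed measures
run_comparison_plan <- function(summaries, behavior, design) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- as.data.frame(r)
  measures <- c(pct_rem = "REM%", pct_nrem = "NREM%",
                spindle_density = "spindle density",
                spindle_mean_freq_hz = "spindle mean frequency")
  groups <- names(design$n_animals)
  sessions <- design$sessions
  for (m in names(measures)) {
    for (g in groups) {
      sub <- summaries[summaries$group == g, ]
      pairs <- utils::combn(sessions, 2L)
      for (j in seq_len(ncol(pairs))) {
        a <- sub[sub$session == pairs[1L, j], ][order(sub$animal_id[sub$session == pairs[1L, j]]), m]
        b <- sub[sub$session == pairs[2L, j], ][order(sub$animal_id[sub$session == pairs[2L, j]]), m]
        ok <- stats::complete.cases(a, b)
        if (sum(ok) >= 3L)
          add(compare_within(a[ok], b[ok],
                             sprintf("%s: %s %s vs %s", measures[[m]], g,
                                     pairs[1L, j], pairs[2L, j])))
      }
    }
    for (s in sessions) {
      gl <- lapply(groups, function(g)
        stats::na.omit(summaries[summaries$group == g & summaries$session == s, m]))
      names(gl) <- groups
      if (all(lengths(gl) >= 3L))
        add(compare_between(gl, sprintf("%s: between groups at %s",
                                        measures[[m]], s)))
    }
  }
  bmeasures <- c(withdrawals = "allodynia withdrawals",
                 pct_closed = "EPM closed-arm %")
  for (m in names(bmeasures)) {
    for (d in design$behavior_days) {
      gl <- lapply(groups, function(g)
        behavior[behavior$group == g & behavior$day == d, m])
      names(gl) <- groups
      add(compare_between(gl, sprintf("%s: between groups at %s",
                                      bmeasures[[m]], d)))
    }
    for (g in groups) {
      sub <- behavior[behavior$group == g, ]
      a <- sub[sub$day == "DAY3", ][order(sub$animal_id[sub$day == "DAY3"]), m]
      b <- sub[sub$day == "DAY6", ][order(sub$animal_id[sub$day == "DAY6"]), m]
      add(compare_within(a, b, sprintf("%s: %s DAY3 vs DAY6",
                                       bmeasures[[m]], g)))
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d recordings, %d behavioural sessions, %d comparisons (seed %d)\n",
              nrow(x$summaries), nrow(x$behavior), nrow(x$stats), x$seed))
  sig <- x$stats[x$stats$significant, ]
  cat(sprintf("  significant at alpha = 0.05 (no multiplicity correction): %d\n",
              nrow(sig)))
  for (i in seq_len(min(nrow(sig), 12L)))
    cat(sprintf("   - %s (%s, p = %.3g)\n", sig$comparison[i],
                sig$test_name[i], sig$p_value[i]))
  invisible(x)
}

write_study_result <- function(res, artifacts, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(out, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(res$summaries, "recording_summaries.tsv")
  wt(res$behavior, "behavior_scores.tsv")
  wt(res$stats, "stat_report.tsv")
  hd <- file.path(out, "hypnograms"); ed <- file.path(out, "events")
  dir.create(hd, showWarnings = FALSE); dir.create(ed, showWarnings = FALSE)
  for (a in artifacts) {
    write_hypnogram(a$hyp, file.path(hd, paste0(a$name, ".tsv")))
    write_spindle_events(a$events, file.path(ed, paste0(a$name, ".tsv")))
  }
  md <- c("# In-silico study report", "",
          sprintf("Seed %d; %d recordings of %g min at %g Hz.", res$seed,
                  nrow(res$summaries), res$config$session_minutes,
                  res$config$sampling_rate),
          "", "Significance at alpha = 0.05, two-sided, no multiple-testing correction.",
          "", "## Comparisons", "",
          sprintf("- %s — %s, statistic %.4g, p = %.4g%s",
                  res$stats$comparison, res$stats$test_name,
                  res$stats$statistic, res$stats$p_value,
                  ifelse(res$stats$significant, " (*)", "")))
  writeLines(md, file.path(out, "report.md"))
  invisible(out)
}
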