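#' Simulation configuration for synthetic polysomnography
#'
#' Bundles every parameter of the synthetic-recording generator: session
#' geometry, the per-epoch Markov chain over vigilance states, per-state
#' spectral content and EMG tone, the spindle point process, and the
#' group-by-session effect modifiers that encode the study's qualitative
#' contrasts (directions only; the source study reports no effect magnitudes).
#'
#' @param seed integer seed controlling all randomness downstream.
#' @param sampling_rate sampling rate in Hz (default 3000, the acquisition
#'   rate of the emulated recording system).
#' @param epoch_length scoring epoch length in seconds (default 5).
#' @param session_minutes length of one recording session in minutes
#'   (default 150; three sessions per animal give 450 recorded minutes).
#' @param state_transition 3x3 row-stochastic matrix over
#'   `WAKE`, `NREM`, `REM`: per-epoch transition probabilities.
#' @param state_spectra named list (one entry per state) of lists with
#'   `components` (2-column matrix: frequency Hz, amplitude uV of sinusoidal
#'   oscillators) and `noise` (RMS amplitude uV of the 1/f background).
#' @param emg_tone named numeric vector of per-state EMG RMS amplitudes (uV).
#' @param spindle_rate spindle events per minute of NREM sleep.
#' @param spindle_freq_range 2-vector, Hz interval spindle carrier
#'   frequencies are drawn from (default 9-15 Hz, the canonical spindle range).
#' @param spindle_duration_range 2-vector, seconds interval spindle durations
#'   are drawn from (default 0.5-3 s).
#' @param spindle_amplitude peak amplitude of the raised-cosine spindle
#'   envelope, uV.
#' @param group_effects nested list `group -> session/day -> modifier` of
#'   multiplicative modifiers (`spindle`, `rem`, `nrem`) and behavioural
#'   parameters (`withdrawal_p`, `epm_dwell`); see [default_group_effects()].
#'
#' @return An object of class `sim_config`.
#' @seealso [synthesize_recording()], [simulate_hypnogram()],
#'   [simulate_behavior()]
#' @export
sim_config <- function(seed = 1L,
                       sampling_rate = 3000,
                       epoch_length = 5,
                       session_minutes = 150,
                       state_transition = default_state_transition(),
                       state_spectra = default_state_spectra(),
                       emg_tone = c(WAKE = 60, NREM = 15, REM = 4),
                       spindle_rate = 2,
                       spindle_freq_range = c(9, 15),
                       spindle_duration_range = c(0.5, 3),
                       spindle_amplitude = 80,
                       group_effects = default_group_effects()) {
  check_scalar_num(seed, "seed")
  check_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  check_scalar_num(epoch_length, "epoch_length", 0, strict = TRUE)
  check_scalar_num(session_minutes, "session_minutes", 0, strict = TRUE)
  validate_transition_matrix(state_transition)
  if (!is.list(state_spectra) || !all(SLEEP_STATES %in% names(state_spectra)))
    stop_input("state_spectra must be a named list covering %s",
               paste(SLEEP_STATES, collapse = ", "))
  for (st in SLEEP_STATES) {
    sp <- state_spectra[[st]]
    cm <- sp$components
    if (!is.matrix(cm) || ncol(cm) != 2L)
      stop_input("state_spectra$%s$components must be a 2-column (freq, amp) matrix", st)
    if (nrow(cm) > 0L && (any(cm[, 1L] <= 0) || any(cm[, 2L] < 0)))
      stop_input("state_spectra$%s components need positive frequencies and non-negative amplitudes", st)
    check_scalar_num(sp$noise %||% NA_real_, sprintf("state_spectra$%s$noise", st), 0)
  }
  if (!all(SLEEP_STATES %in% names(emg_tone)) || any(emg_tone < 0))
    stop_input("emg_tone must name all three states with non-negative RMS values")
  check_scalar_num(spindle_rate, "spindle_rate", 0)
  check_band(spindle_freq_range, "spindle_freq_range")
  if (spindle_freq_range[2L] >= sampling_rate / 2)
    stop_input("spindle_freq_range must lie below the Nyquist frequency %g Hz",
               sampling_rate / 2)
  check_band(spindle_duration_range, "spindle_duration_range", strict_low = TRUE)
  check_scalar_num(spindle_amplitude, "spindle_amplitude", 0)

  structure(
    list(seed = as.integer(seed), sampling_rate = sampling_rate,
         epoch_length = epoch_length, session_minutes = session_minutes,
         state_transition = state_transition, state_spectra = state_spectra,
         emg_tone = emg_tone[SLEEP_STATES], spindle_rate = spindle_rate,
         spindle_freq_range = spindle_freq_range,
         spindle_duration_range = spindle_duration_range,
         spindle_amplitude = spindle_amplitude,
         group_effects = group_effects),
    class = "sim_config")
}

validate_transition_matrix <- function(P) {
  if (!is.matrix(P) || !identical(dim(P), c(3L, 3L)) || !is.numeric(P))
    stop_input("state_transition must be a numeric 3x3 matrix")
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-9))
    stop_input("state_transition rows must be non-negative and sum to 1 (within 1e-9)")
  invisible(P)
}

check_band <- function(b, name, strict_low = FALSE) {
  if (!is.numeric(b) || length(b) != 2L || any(!is.finite(b)))
    stop_input("'%s' must be a numeric 2-vector", name)
  if (b[1L] >= b[2L] || b[1L] < 0 || (strict_low && b[1L] <= 0))
    stop_input("'%s' must satisfy %s low < high", name,
               if (strict_low) "0 <" else "0 <=")
  invisible(b)
}

#' Default per-epoch state transition matrix
#'
#' Dwell times of a morning rat recording: minutes-long wake and NREM bouts,
#' shorter REM bouts, no direct wake-to-REM transitions.
#' @return 3x3 row-stochastic matrix with dimnames over the state alphabet.
#' @export
default_state_transition <- function() {
  P <- matrix(c(0.92, 0.08, 0.00,
                0.04, 0.93, 0.03,
                0.07, 0.03, 0.90),
              nrow = 3, byrow = TRUE,
              dimnames = list(SLEEP_STATES, SLEEP_STATES))
  P
}

#' Default state spectral signatures
#'
#' Canonical rodent state signatures: desynchronised low-voltage wake,
#' high-amplitude delta NREM, theta-dominated REM, each over a 1/f floor.
#' @return named list consumed by [sim_config()].
#' @export
default_state_spectra <- function() {
  list(
    WAKE = list(components = cbind(freq = c(8, 25), amp = c(15, 8)),  noise = 20),
    NREM = list(components = cbind(freq = 1.5,      amp = 100),      noise = 25),
    REM  = list(components = cbind(freq = 7,        amp = 60),       noise = 15)
  )
}

#' Default group-by-session effect modifiers
#'
#' Encodes the study contrasts as directions: Valerian-treated neuropathic
#' animals (VAL_NRP) carry a higher spindle rate and a higher baseline REM
#' propensity that declines across sessions with NREM rising by day 6;
#' untreated neuropathy (NRP) shows elevated cold-allodynia withdrawal
#' probability and longer closed-arm dwell on day 6; sham animals never
#' withdraw. Magnitudes are package choices (the emulated study reports
#' group effects in figures only).
#'
#' @return nested list `group -> list(spindle, rem, nrem, withdrawal_p,
#'   epm_dwell)`; `spindle`/`rem`/`nrem` are per-session multiplicative
#'   modifiers, `withdrawal_p` per-day Bernoulli probabilities, `epm_dwell`
#'   per-day mean dwell seconds for open/closed/center zones.
#' @export
default_group_effects <- function() {
  sess <- function(b, d3, d6) stats::setNames(c(b, d3, d6), STUDY_SESSIONS)
  day <- function(d3, d6) stats::setNames(c(d3, d6), BEHAVIOR_DAYS)
  dwell <- function(open3, closed3, open6, closed6)
    list(DAY3 = c(OPEN = open3, CLOSED = closed3, CENTER = 15),
         DAY6 = c(OPEN = open6, CLOSED = closed6, CENTER = 15))
  list(
    SHAM = list(
      spindle = sess(1.00, 1.03, 1.06), rem = sess(1, 1, 1),
      nrem = sess(1.00, 1.02, 1.04),
      withdrawal_p = day(0, 0), epm_dwell = dwell(30, 60, 30, 60)),
    NRP = list(
      spindle = sess(1.00, 1.03, 1.06), rem = sess(1, 1, 1),
      nrem = sess(1, 1, 1),
      withdrawal_p = day(0.70, 0.80), epm_dwell = dwell(25, 70, 12, 140)),
    VAL_NRP = list(
      spindle = sess(1.35, 1.39, 1.43), rem = sess(1.8, 1.3, 0.9),
      nrem = sess(1.00, 1.05, 1.15),
      withdrawal_p = day(0.30, 0.00), epm_dwell = dwell(30, 60, 28, 65))
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  sampling_rate: %g Hz | epoch: %g s | session: %g min\n",
              x$sampling_rate, x$epoch_length, x$session_minutes))
  cat(sprintf("  spindles: %g /NREM-min, %g-%g Hz, %g-%g s, %g uV\n",
              x$spindle_rate, x$spindle_freq_range[1], x$spindle_freq_range[2],
              x$spindle_duration_range[1], x$spindle_duration_range[2],
              x$spindle_amplitude))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as YAML-style text
#'
#' Flat serialisation of the scalar and vector fields plus the transition
#' matrix; group effects round-trip as nested maps.
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  x$state_transition <- as.vector(t(x$state_transition))
  x$state_spectra <- lapply(x$state_spectra, function(sp)
    list(freq = as.vector(sp$components[, 1L]),
         amp = as.vector(sp$components[, 2L]), noise = sp$noise))
  x$emg_tone <- as.list(x$emg_tone)
  # named vectors must become maps, or their names are lost in YAML
  x$group_effects <- lapply(x$group_effects, function(g) {
    g$spindle <- as.list(g$spindle); g$rem <- as.list(g$rem)
    g$nrem <- as.list(g$nrem); g$withdrawal_p <- as.list(g$withdrawal_p)
    g$epm_dwell <- lapply(g$epm_dwell, as.list)
    g
  })
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  spectra <- lapply(x$state_spectra, function(sp)
    list(components = cbind(freq = as.numeric(sp$freq), amp = as.numeric(sp$amp)),
         noise = sp$noise))
  ge <- lapply(x$group_effects, function(g) {
    g$spindle <- unlist(g$spindle); g$rem <- unlist(g$rem); g$nrem <- unlist(g$nrem)
    g$withdrawal_p <- unlist(g$withdrawal_p)
    g$epm_dwell <- lapply(g$epm_dwell, unlist)
    g
  })
  sim_config(seed = x$seed, sampling_rate = x$sampling_rate,
             epoch_length = x$epoch_length, session_minutes = x$session_minutes,
             state_transition = matrix(as.numeric(x$state_transition), 3, 3,
                                       byrow = TRUE,
                                       dimnames = list(SLEEP_STATES, SLEEP_STATES)),
             state_spectra = spectra,
             emg_tone = unlist(x$emg_tone),
             spindle_rate = x$spindle_rate,
             spindle_freq_range = as.numeric(x$spindle_freq_range),
             spindle_duration_range = as.numeric(x$spindle_duration_range),
             spindle_amplitude = x$spindle_amplitude,
             group_effects = ge)
}
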