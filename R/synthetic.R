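#' Simulate a hypnogram from the configured Markov chain
#'
#' Draws a per-epoch sequence of vigilance states from the first-order Markov
#' chain in `config$state_transition`, started in `WAKE`. Randomness is taken
#' from the current RNG stream; callers wanting reproducibility set the seed
#' (as [synthesize_recording()] does from `config$seed`).
#'
#' @param config a [sim_config()].
#' @param n_epochs number of epochs to draw (>= 1).
#' @param transition optional override of the transition matrix (used
#'   internally to apply group/session dwell modifiers).
#' @return a [hypnogram()] of `n_epochs` labels.
#' @export
simulate_hypnogram <- function(config, n_epochs, transition = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar_num(n_epochs, "n_epochs", 1)
  P <- transition %||% config$state_transition
  validate_transition_matrix(P)
  labels <- character(n_epochs)
  s <- 1L  # WAKE
  for (i in seq_len(n_epochs)) {
    labels[i] <- SLEEP_STATES[s]
    s <- sample.int(3L, 1L, prob = P[s, ])
  }
  hypnogram(labels, config$epoch_length)
}

#' Add a raised-cosine spindle burst to a signal
#'
#' Adds an amplitude-enveloped sinusoid: the envelope is a raised-cosine
#' (Hann) window, zero at both burst edges and peaking mid-burst, emulating
#' the waxing-and-waning morphology of a sleep spindle. Samples outside the
#' burst interval are untouched.
#'
#' @param signal numeric sample vector (uV).
#' @param sampling_rate Hz.
#' @param start burst onset in seconds from signal start.
#' @param duration burst length in seconds (> 0).
#' @param frequency carrier frequency, Hz.
#' @param amplitude peak envelope amplitude, uV.
#' @return the signal with the burst added.
#' @export
inject_spindle <- function(signal, sampling_rate, start, duration, frequency,
                           amplitude) {
  check_scalar_num(start, "start", 0)
  check_scalar_num(duration, "duration", 0, strict = TRUE)
  check_scalar_num(frequency, "frequency", 0, strict = TRUE)
  check_scalar_num(amplitude, "amplitude", 0)
  i0 <- floor(start * sampling_rate) + 1L
  n <- round(duration * sampling_rate)
  if (i0 < 1L || i0 + n - 1L > length(signal))
    stop_input("spindle burst [%g, %g) s exceeds signal bounds (%g s)",
               start, start + duration, length(signal) / sampling_rate)
  if (n == 0L || amplitude == 0) return(signal)
  tt <- (seq_len(n) - 1L) / sampling_rate
  env <- amplitude * sin(pi * tt / duration)^2
  idx <- seq.int(i0, i0 + n - 1L)
  signal[idx] <- signal[idx] + env * sin(2 * pi * frequency * tt)
  signal
}

# 1/f-shaped noise with unit RMS, by spectral shaping of white noise
one_over_f_noise <- function(n, sampling_rate) {
  if (n < 4L) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, sampling_rate, length.out = n + 1L)[seq_len(n)]
  f[f > sampling_rate / 2] <- sampling_rate - f[f > sampling_rate / 2]
  g <- 1 / sqrt(pmax(f, 0.5))   # amplitude ~ f^-1/2 => power ~ 1/f
  g[1L] <- 0
  y <- Re(stats::fft(X * g, inverse = TRUE) / n)
  y / sd_pop(y)
}

# modify the transition matrix by multiplying the columns into NREM/REM and
# renormalising rows; encodes group/session dwell effects
modulate_transition <- function(P, rem_mult = 1, nrem_mult = 1) {
  Q <- P
  Q[, "REM"] <- Q[, "REM"] * rem_mult
  Q[, "NREM"] <- Q[, "NREM"] * nrem_mult
  Q / rowSums(Q)
}

group_effect <- function(config, group, session) {
  ge <- config$group_effects[[group]]
  list(spindle = unname(ge$spindle[session]),
       rem = unname(ge$rem[session]),
       nrem = unname(ge$nrem[session]))
}

#' Synthesize one animal-session EEG+EMG recording with ground truth
#'
#' Builds a full synthetic polysomnogram: a Markov-chain hypnogram (with
#' group/session dwell modifiers applied to the transition matrix), per-state
#' sinusoidal oscillation mixtures over a 1/f noise floor, spindle bursts
#' injected during NREM at the (group, session)-modified Poisson rate, and a
#' white-noise EMG scaled to the state's tone. The accompanying ground truth
#' carries the true hypnogram and the injected spindle intervals.
#'
#' @param config a [sim_config()].
#' @param group one of `SHAM`, `NRP`, `VAL_NRP`.
#' @param session one of `BASE`, `DAY3`, `DAY6`.
#' @param animal_id identifier stored in the recording.
#' @param seed RNG seed; defaults to `config$seed` so an identical config
#'   yields a bit-identical recording.
#' @return list with elements `recording` (a [recording()]) and `truth`
#'   (list: `hypnogram`, `spindle_events` data frame with columns
#'   `start_s`, `end_s`, `freq_hz`).
#' @export
synthesize_recording <- function(config, group, session, animal_id = "sim01",
                                 seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  group <- match_label(group, STUDY_GROUPS, "group")
  session <- match_label(session, STUDY_SESSIONS, "session")
  set.seed(seed %% .Machine$integer.max)

  fs <- config$sampling_rate
  ep_len <- config$epoch_length
  n_epochs <- floor(config$session_minutes * 60 / ep_len)
  eff <- group_effect(config, group, session)
  P <- modulate_transition(config$state_transition, eff$rem, eff$nrem)
  hyp <- simulate_hypnogram(config, n_epochs, transition = P)

  ep_n <- round(ep_len * fs)
  n <- n_epochs * ep_n
  state_idx <- rep(match(hyp$labels, SLEEP_STATES), each = ep_n)
  tt <- (seq_len(n) - 1L) / fs

  eeg <- numeric(n)
  for (si in seq_along(SLEEP_STATES)) {
    mask <- state_idx == si
    if (!any(mask)) next
    sp <- config$state_spectra[[SLEEP_STATES[si]]]
    cm <- sp$components
    if (nrow(cm) > 0L) for (j in seq_len(nrow(cm))) {
      phase <- stats::runif(1L, 0, 2 * pi)
      eeg[mask] <- eeg[mask] + cm[j, 2L] * sin(2 * pi * cm[j, 1L] * tt[mask] + phase)
    }
  }
  noise_amp <- vapply(config$state_spectra, function(sp) sp$noise, numeric(1))
  if (any(noise_amp > 0))
    eeg <- eeg + one_over_f_noise(n, fs) * noise_amp[state_idx]

  # spindles: homogeneous Poisson within NREM spans, overlap-rejected
  events <- place_spindles(hyp, config, rate = config$spindle_rate * eff$spindle)
  if (nrow(events) > 0L) for (i in seq_len(nrow(events)))
    eeg <- inject_spindle(eeg, fs, events$start_s[i],
                          events$end_s[i] - events$start_s[i],
                          events$freq_hz[i], config$spindle_amplitude)

  emg <- stats::rnorm(n) * config$emg_tone[state_idx]

  rec <- recording(eeg, emg, fs, animal_id = animal_id,
                   group = group, session = session)
  list(recording = rec,
       truth = list(hypnogram = hyp, spindle_events = events))
}

# draw spindle events within contiguous NREM spans
place_spindles <- function(hyp, config, rate) {
  ep_len <- hyp$epoch_length
  runs <- rle(hyp$labels == "NREM")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    span <- c((starts[r] - 1L) * ep_len, ends[r] * ep_len)
    lambda <- rate * (span[2L] - span[1L]) / 60
    k <- stats::rpois(1L, lambda)
    if (k == 0L) next
    acc <- matrix(numeric(0), ncol = 3L)
    for (i in seq_len(k)) {
      dur <- stats::runif(1L, config$spindle_duration_range[1L],
                          config$spindle_duration_range[2L])
      if (span[2L] - span[1L] <= dur) next
      st <- stats::runif(1L, span[1L], span[2L] - dur)
      if (nrow(acc) > 0L && any(st < acc[, 2L] & st + dur > acc[, 1L])) next
      fr <- stats::runif(1L, config$spindle_freq_range[1L],
                         config$spindle_freq_range[2L])
      acc <- rbind(acc, c(st, st + dur, fr))
    }
    if (nrow(acc) > 0L) out[[length(out) + 1L]] <- acc
  }
  if (length(out) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      freq_hz = numeric(0)))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1L]), , drop = FALSE]
  data.frame(start_s = m[, 1L], end_s = m[, 2L], freq_hz = m[, 3L])
}

#' Simulate behavioural assay tables for one group and day
#'
#' Per animal: five acetone-application trials with binary hind-paw withdrawal
#' indicators drawn at the group-by-day probability, and one 300-s elevated
#' plus maze session as a zone-entry event sequence starting at the maze
#' center, with exponentially distributed dwell times at the group-by-day
#' zone means.
#'
#' @param config a [sim_config()].
#' @param group group label.
#' @param day `DAY3` or `DAY6`.
#' @param n_animals number of animals to simulate.
#' @param seed RNG seed (default `config$seed`).
#' @return list of class `behavior_table`: `acetone` (animal_id, day, trial,
#'   withdrawal) and `epm` (animal_id, day, time_s, zone) data frames.
#' @export
simulate_behavior <- function(config, group, day, n_animals = 8,
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  group <- match_label(group, STUDY_GROUPS, "group")
  day <- match_label(day, BEHAVIOR_DAYS, "day")
  check_scalar_num(n_animals, "n_animals", 1)
  set.seed(seed %% .Machine$integer.max)
  ge <- config$group_effects[[group]]
  p <- unname(ge$withdrawal_p[day])
  dwell <- ge$epm_dwell[[day]]

  acetone <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    data.frame(animal_id = sprintf("%s_%02d", group, a), day = day,
               trial = 1:5, withdrawal = stats::rbinom(5L, 1L, p))
  }))
  epm <- do.call(rbind, lapply(seq_len(n_animals), function(a) {
    ev <- simulate_epm_events(dwell)
    data.frame(animal_id = sprintf("%s_%02d", group, a), day = day,
               time_s = ev$time_s, zone = ev$zone)
  }))
  structure(list(acetone = acetone, epm = epm), class = "behavior_table")
}

simulate_epm_events <- function(dwell, session_length = 300) {
  p_open <- dwell[["OPEN"]] / (dwell[["OPEN"]] + dwell[["CLOSED"]])
  times <- 0; zones <- "CENTER"
  t <- stats::rexp(1L, 1 / dwell[["CENTER"]])
  in_center <- TRUE
  while (t < session_length) {
    if (in_center) {
      z <- if (stats::runif(1L) < p_open) "OPEN" else "CLOSED"
    } else {
      z <- "CENTER"
    }
    times <- c(times, t); zones <- c(zones, z)
    t <- t + stats::rexp(1L, 1 / dwell[[z]])
    in_center <- z == "CENTER"
  }
  list(time_s = times, zone = zones)
}
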