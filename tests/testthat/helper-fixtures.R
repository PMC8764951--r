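# shared fixtures, built in code at test time

# degenerate chain that stays in NREM after the first epoch
all_nrem_transition <- function() {
  matrix(c(0, 1, 0, 0, 1, 0, 0, 1, 0), 3, byrow = TRUE,
         dimnames = list(SLEEP_STATES, SLEEP_STATES))
}

# fast, sigma-clean config: per-state oscillations retained, 1/f floor off,
# so the only power in the 12-20 Hz band comes from injected bursts
sigma_clean_config <- function(minutes = 2, fs = 250, seed = 5) {
  sp <- default_state_spectra()
  for (s in names(sp)) sp[[s]]$noise <- 0
  sim_config(sampling_rate = fs, session_minutes = minutes, spindle_rate = 0,
             state_spectra = sp, state_transition = all_nrem_transition(),
             seed = seed)
}

# small default-physics config for recovery tests
quick_config <- function(minutes = 10, fs = 250, seed = 11, ...) {
  sim_config(sampling_rate = fs, session_minutes = minutes, seed = seed, ...)
}

# >= 50% interval-overlap event matching (overlap relative to the shorter
# interval); returns logicals for detected and truth rows
match_events <- function(det, truth, min_overlap = 0.5) {
  dm <- logical(nrow(det)); tm <- logical(nrow(truth))
  for (i in seq_len(nrow(det))) for (j in seq_len(nrow(truth))) {
    ov <- min(det$end_s[i], truth$end_s[j]) -
      max(det$start_s[i], truth$start_s[j])
    len <- min(det$end_s[i] - det$start_s[i],
               truth$end_s[j] - truth$start_s[j])
    if (ov > min_overlap * len) { dm[i] <- TRUE; tm[j] <- TRUE }
  }
  list(det = dm, truth = tm)
}

# ground-truth events the 12-20 Hz / 0.5-2 s detector can see by design
detectable_truth <- function(truth, band = c(12, 20), durs = c(0.5, 2)) {
  dur <- truth$end_s - truth$start_s
  truth[dur >= durs[1] & dur <= durs[2] &
          truth$freq_hz >= band[1] & truth$freq_hz <= band[2], ]
}

# direct DFT periodogram oracle: O(n^2) sum over complex exponentials,
# scaled like the staging features (unit-amplitude sinusoid -> 1/2)
direct_periodogram <- function(x) {
  n <- length(x)
  k <- 0:(floor(n / 2))
  W <- exp(-2i * pi * outer(k, 0:(n - 1)) / n)
  (2 / n^2) * Mod(W %*% x)^2
}
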