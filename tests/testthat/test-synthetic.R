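test_that("hypnogram simulation follows the configured Markov chain", {
  cfg <- quick_config()
  # absorbing start state
  ident <- diag(3); dimnames(ident) <- list(SLEEP_STATES, SLEEP_STATES)
  cfg_i <- cfg; cfg_i$state_transition <- ident
  expect_equal(simulate_hypnogram(cfg_i, 10)$labels, rep("WAKE", 10))
  # deterministic chain: WAKE then all NREM
  cfg_n <- cfg; cfg_n$state_transition <- all_nrem_transition()
  expect_equal(simulate_hypnogram(cfg_n, 5)$labels,
               c("WAKE", rep("NREM", 4)))
  bad <- default_state_transition(); bad[2, ] <- c(1, 1, 1)
  expect_error(simulate_hypnogram(cfg, 5, transition = bad), "sum to 1")
})

test_that("long-run state frequencies match the eigen-decomposition stationary distribution", {
  cfg <- quick_config(seed = 21)
  set.seed(21)
  n <- 20000
  hyp <- simulate_hypnogram(cfg, n)
  # oracle: stationary distribution as the left unit eigenvector
  e <- eigen(t(cfg$state_transition))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_star <- v / sum(v)
  emp <- tabulate(match(hyp$labels, SLEEP_STATES), 3) / n
  # SE by batch means (the chain is autocorrelated)
  x <- match(hyp$labels, SLEEP_STATES)
  batches <- matrix(x, ncol = 100)
  for (s in 1:3) {
    bmeans <- colMeans(batches == s)
    se <- stats::sd(bmeans) / sqrt(length(bmeans))
    expect_lt(abs(emp[s] - pi_star[s]), 3 * se + 1e-12)
  }
})

test_that("spindle injection adds a raised-cosine burst and nothing else", {
  fs <- 250
  x <- numeric(5 * fs)
  expect_identical(inject_spindle(x, fs, 1, 1, 13, 0), x)
  y <- inject_spindle(x, fs, 1, 1.2, 13, 50)
  idx <- seq(fs + 1, fs + round(1.2 * fs))
  expect_true(all(y[-idx] == 0))
  # energy oracle: direct summation of the closed-form envelope x carrier
  tt <- (seq_along(idx) - 1) / fs
  oracle <- sum((50 * sin(pi * tt / 1.2)^2 * sin(2 * pi * 13 * tt))^2)
  expect_equal(sum(y^2), oracle)
  # linearity of two non-overlapping injections
  z0 <- stats::rnorm(5 * fs)
  z12 <- inject_spindle(inject_spindle(z0, fs, 0.5, 0.8, 11, 40),
                        fs, 3, 0.6, 14, 60)
  b1 <- inject_spindle(numeric(5 * fs), fs, 0.5, 0.8, 11, 40)
  b2 <- inject_spindle(numeric(5 * fs), fs, 3, 0.6, 14, 60)
  expect_equal(z12, z0 + b1 + b2)
  expect_error(inject_spindle(x, fs, 4.5, 1, 13, 50), "exceeds signal bounds")
})

test_that("synthesized recordings honour rate, geometry and reproducibility", {
  cfg <- quick_config(minutes = 5, seed = 3)
  sim1 <- synthesize_recording(cfg, "SHAM", "BASE")
  sim2 <- synthesize_recording(cfg, "SHAM", "BASE")
  expect_identical(sim1, sim2)            # bit-identical for identical config
  expect_length(sim1$recording$eeg, 5 * 60 * cfg$sampling_rate)
  expect_error(synthesize_recording(cfg, "DRUG", "BASE"), "group")
  expect_error(synthesize_recording(cfg, "SHAM", "DAY9"), "session")

  cfg0 <- quick_config(minutes = 5, spindle_rate = 0)
  expect_equal(nrow(synthesize_recording(cfg0, "SHAM", "BASE")$truth$spindle_events), 0)
})

test_that("every injected spindle lies inside a NREM span with in-range duration", {
  cfg <- quick_config(minutes = 20, seed = 8)
  sim <- synthesize_recording(cfg, "VAL_NRP", "DAY3")
  ev <- sim$truth$spindle_events
  hyp <- sim$truth$hypnogram
  expect_gt(nrow(ev), 0)
  expect_true(all(diff(ev$start_s) > 0))
  expect_true(all(ev$start_s[-1] >= ev$end_s[-nrow(ev)]))  # non-overlapping
  dur <- ev$end_s - ev$start_s
  expect_true(all(dur >= cfg$spindle_duration_range[1] &
                    dur <= cfg$spindle_duration_range[2]))
  for (i in seq_len(nrow(ev))) {
    eps <- seq(floor(ev$start_s[i] / 5) + 1, ceiling(ev$end_s[i] / 5))
    expect_true(all(hyp$labels[eps] == "NREM"))
  }
})

test_that("a zero-noise NREM epoch containing one burst is a windowed sinusoid", {
  cfg <- sigma_clean_config(minutes = 0.5)
  sp <- cfg$state_spectra
  for (s in names(sp)) sp[[s]]$components <- sp[[s]]$components[0, , drop = FALSE]
  cfg$state_spectra <- sp
  sim <- synthesize_recording(cfg, "SHAM", "BASE")
  eeg <- inject_spindle(sim$recording$eeg, 250, 10, 1, 13, 60)
  idx <- seq(10 * 250 + 1, 11 * 250)
  tt <- (seq_along(idx) - 1) / 250
  expect_equal(eeg[idx], 60 * sin(pi * tt)^2 * sin(2 * pi * 13 * tt))
  P <- Mod(stats::fft(eeg[idx]))^2
  freqs <- (seq_along(idx) - 1)      # 1-s segment -> 1 Hz bins
  expect_equal(freqs[which.max(P[1:126])], 13)
})

test_that("injected spindle counts follow the configured Poisson rate", {
  cfg <- quick_config(minutes = 30, seed = 17)
  sim <- synthesize_recording(cfg, "SHAM", "BASE")
  nrem_min <- sum(sim$truth$hypnogram$labels == "NREM") * 5 / 60
  lambda <- cfg$spindle_rate * nrem_min
  expect_lt(abs(nrow(sim$truth$spindle_events) - lambda), 3 * sqrt(lambda))
})

test_that("per-state EMG RMS tracks the configured tone", {
  cfg <- quick_config(minutes = 30, seed = 4)
  sim <- synthesize_recording(cfg, "SHAM", "BASE")
  states <- rep(sim$truth$hypnogram$labels, each = 5 * cfg$sampling_rate)
  for (s in SLEEP_STATES) {
    mins <- sum(states == s) / cfg$sampling_rate / 60
    if (mins < 10) next
    rms <- sqrt(mean(sim$recording$emg[states == s]^2))
    expect_lt(abs(rms - cfg$emg_tone[[s]]) / cfg$emg_tone[[s]], 0.1)
  }
})

test_that("behavioural simulation reproduces the degenerate group outcomes", {
  cfg <- quick_config()
  # sham animals never withdraw
  sham <- simulate_behavior(cfg, "SHAM", "DAY3", n_animals = 6)
  expect_true(all(sham$acetone$withdrawal == 0))
  # Valerian-treated animals at day 6 have zero withdrawal probability
  val6 <- simulate_behavior(cfg, "VAL_NRP", "DAY6", n_animals = 6)
  expect_equal(mean(val6$acetone$withdrawal), 0)
  expect_error(simulate_behavior(cfg, "SHAM", "BASE"), "day")
  # EPM occupancy partitions the 300-s session exactly
  nrp <- simulate_behavior(cfg, "NRP", "DAY6", n_animals = 5)
  sc <- score_behavior(nrp)
  expect_equal(sc$open_time_s + sc$closed_time_s + sc$center_time_s,
               rep(300, 5))
})
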