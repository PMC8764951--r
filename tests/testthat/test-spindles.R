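test_that("the spectrogram localises tones and matches a direct DFT oracle", {
  fs <- 250
  tt <- (0:(20 * fs - 1)) / fs
  tone <- 50 * sin(2 * pi * 13 * tt)
  spec <- compute_spectrogram(tone, fs)
  avg <- colMeans(spec$power)
  expect_equal(spec$freqs[which.max(avg)], 13)
  expect_true(all(compute_spectrogram(numeric(5 * fs), fs)$power == 0))
  expect_error(compute_spectrogram(numeric(100), fs, window = 1), "longer")

  # one frame equals the direct periodogram of that tapered segment
  set.seed(3)
  x <- stats::rnorm(3 * fs)
  spec2 <- compute_spectrogram(x, fs, window = 1, step = 0.5)
  W <- fs
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(W) / W)
  seg <- x[(0.5 * fs + 1):(1.5 * fs)] * w      # frame 2 starts at 0.5 s
  k <- 0:(W / 2)
  F <- exp(-2i * pi * outer(k, 0:(W - 1)) / W)
  P_direct <- Mod(F %*% seg)^2 / (fs * sum(w^2))
  P_direct[2:(length(k) - 1)] <- 2 * P_direct[2:(length(k) - 1)]
  expect_equal(spec2$power[2, ], as.vector(P_direct), tolerance = 1e-10)
})

test_that("spectrogram energy is Parseval-consistent on white noise", {
  set.seed(9)
  fs <- 250
  x <- stats::rnorm(30 * fs, sd = 20)
  spec <- compute_spectrogram(x, fs)
  df <- spec$freqs[2] - spec$freqs[1]
  spectral <- mean(rowSums(spec$power)) * df
  expect_lt(abs(spectral - 400) / 400, 0.05)   # sd^2 = 400
})

test_that("sigma band power is an inclusive-band column sum", {
  fs <- 250
  tt <- (0:(20 * fs - 1)) / fs
  spec13 <- compute_spectrogram(40 * sin(2 * pi * 13 * tt), fs)
  tr13 <- sigma_power_trace(spec13)
  df <- spec13$freqs[2] - spec13$freqs[1]
  total <- rowSums(spec13$power) * df
  expect_true(all(tr13$sigma_power >= 0.9 * total))
  spec25 <- compute_spectrogram(40 * sin(2 * pi * 25 * tt), fs)
  tr25 <- sigma_power_trace(spec25)
  expect_true(all(tr25$sigma_power <=
                    0.05 * rowSums(spec25$power) * df + 1e-12))
  # brute-force column summation oracle
  sel <- spec13$freqs >= 12 & spec13$freqs <= 20
  oracle <- apply(spec13$power[, sel], 1, sum) * df
  expect_equal(tr13$sigma_power, oracle)
  expect_error(sigma_power_trace(spec13, c(300, 400)), "band")
})

test_that("the adaptive threshold is mean + k SD (population) of NREM sigma power", {
  mk_trace <- function(p) structure(
    list(times = seq_along(p) * 5 - 2.5, sigma_power = p, band = c(12, 20),
         step = 5), class = "sigma_trace")
  hyp4 <- hypnogram(rep("NREM", 4), 5)
  expect_equal(compute_threshold(mk_trace(c(1, 1, 1, 5)), hyp4, k_sd = 1),
               2 + sqrt(3))
  expect_equal(compute_threshold(mk_trace(rep(7, 4)), hyp4, k_sd = 3), 7)
  expect_equal(compute_threshold(mk_trace(c(1, 1, 1, 5)), hyp4, k_sd = 0), 2)
  expect_error(compute_threshold(mk_trace(1:4), hypnogram(rep("WAKE", 4), 5)),
               "NREM")
})

test_that("the detector accepts exactly the 0.5-2 s, 12-20 Hz, NREM events", {
  cfg <- sigma_clean_config()
  base <- synthesize_recording(cfg, "SHAM", "BASE")
  hyp <- base$truth$hypnogram
  burst <- function(D, f, at = 50) {
    rec <- base$recording
    rec$eeg <- inject_spindle(rec$eeg, 250, at, D, f, 80)
    rec
  }
  expect_equal(nrow(find_spindles(burst(1.0, 13), hyp, threshold = 100)), 1)
  ev <- find_spindles(burst(1.0, 13), hyp, threshold = 100)
  ov <- min(ev$end_s, 51) - max(ev$start_s, 50)
  expect_gte(ov, 0.8)                     # >= 80% overlap with the injection
  expect_equal(nrow(find_spindles(burst(0.3, 13), hyp, threshold = 100)), 0)
  expect_equal(nrow(find_spindles(burst(2.5, 13), hyp, threshold = 100)), 0)
  # same burst during WAKE is rejected by the NREM midpoint rule
  hyp_w <- hyp; hyp_w$labels[] <- "WAKE"
  expect_equal(nrow(find_spindles(burst(1.0, 13), hyp_w, threshold = 100)), 0)
  # out-of-band carriers are rejected
  expect_equal(nrow(find_spindles(burst(1.0, 8), hyp, threshold = 100)), 0)
  expect_equal(nrow(find_spindles(burst(1.0, 25), hyp, threshold = 100)), 0)
})

test_that("spindle RMS matches closed forms and direct summation", {
  fs <- 100
  expect_equal(spindle_rms(rep(-3, 500), c(1, 4), fs), 3)
  tt <- (0:(10 * fs - 1)) / fs
  sine <- 60 * sin(2 * pi * 10 * tt)
  expect_lt(abs(spindle_rms(sine, c(0, 10), fs) - 60 / sqrt(2)) / (60 / sqrt(2)),
            0.01)
  set.seed(5)
  v <- stats::rnorm(10)
  expect_equal(spindle_rms(v, c(0, 10 / fs), fs), sqrt(mean(v^2)))
  expect_error(spindle_rms(v, c(0.05, 0.05), fs), "empty")
})

test_that("mean frequency is the power-weighted average of Fourier components", {
  fs <- 200
  tt <- (0:(2 * fs - 1)) / fs
  pure <- sin(2 * pi * 13 * tt)
  expect_equal(spindle_mean_frequency(pure, c(0, 2), fs), 13, tolerance = 0.5)
  mix <- sin(2 * pi * 12 * tt) + sin(2 * pi * 14 * tt)
  expect_equal(spindle_mean_frequency(mix, c(0, 2), fs), 13, tolerance = 0.5)
  # powers (1, 2, 1) at 12, 14, 16 Hz -> weighted mean 14
  w3 <- sin(2 * pi * 12 * tt) + sqrt(2) * sin(2 * pi * 14 * tt) +
    sin(2 * pi * 16 * tt)
  expect_equal(spindle_mean_frequency(w3, c(0, 2), fs), 14, tolerance = 0.5)
  expect_true(is.na(spindle_mean_frequency(sin(2 * pi * 3 * tt), c(0, 2), fs)))
})

test_that("spindle density divides events by NREM minutes", {
  ev <- data.frame(start_s = seq_len(10), end_s = seq_len(10) + 0.5)
  hyp <- hypnogram(rep("NREM", 240), 5)    # 20 NREM minutes
  expect_equal(spindle_density(ev, hyp), 0.5)
  expect_equal(spindle_density(ev[0, ], hyp), 0)
  wake <- hypnogram(rep("WAKE", 12), 5)
  expect_equal(spindle_density(ev[0, ], wake), 0)
  expect_error(spindle_density(ev, wake), "inconsistent")
})

test_that("detection recovers injected spindles at high SNR and is threshold-monotone", {
  cfg <- quick_config(minutes = 20, seed = 11)
  sim <- synthesize_recording(cfg, "SHAM", "BASE")
  hyp <- sim$truth$hypnogram
  ev <- find_spindles(sim$recording, hyp)
  expect_gt(nrow(ev), 0)
  # duration filter and band membership hold on every returned event
  expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 2))
  expect_true(all(ev$mean_freq_hz >= 12 & ev$mean_freq_hz <= 20))
  truth <- sim$truth$spindle_events
  m <- match_events(ev, truth)
  md <- match_events(ev, detectable_truth(truth))
  expect_gte(mean(m$det), 0.9)            # precision vs all ground truth
  expect_gte(mean(md$truth), 0.9)         # recall of detectable ground truth
  # raising the threshold never increases the event count
  thr <- attr(ev, "threshold")
  counts <- vapply(thr * c(0.6, 1, 1.5, 2.5, 4, 8), function(t2)
    nrow(find_spindles(sim$recording, hyp, threshold = t2)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected density recovers the configured rate when all events are detectable", {
  # carriers and durations drawn inside the detector's passband, so the
  # configured rate is the detectable rate
  cfg <- quick_config(minutes = 20, seed = 12,
                      spindle_freq_range = c(12, 15),
                      spindle_duration_range = c(0.5, 2))
  sim <- synthesize_recording(cfg, "SHAM", "BASE")
  hyp <- sim$truth$hypnogram
  dens <- spindle_density(find_spindles(sim$recording, hyp), hyp)
  expect_lt(abs(dens - cfg$spindle_rate) / cfg$spindle_rate, 0.25)
})
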