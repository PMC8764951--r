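test_that("staging features place band power where it belongs", {
  fs <- 100
  tt <- (0:(5 * fs - 1)) / fs
  silent <- numeric(5 * fs)
  f2 <- extract_features(sin(2 * pi * 2 * tt), silent, fs)
  expect_true(f2[["log_delta"]] > max(f2[["log_theta"]], f2[["log_sigma"]],
                                      f2[["log_beta"]]))
  f6 <- extract_features(sin(2 * pi * 6 * tt), silent, fs)
  expect_gt(f6[["theta_delta_ratio"]], 1)
  # all-zero epoch still yields finite features
  expect_true(all(is.finite(extract_features(silent, silent, fs))))
})

test_that("feature band powers equal direct-DFT periodogram band sums", {
  set.seed(7)
  fs <- 100
  x <- stats::rnorm(5 * fs)
  e <- stats::rnorm(5 * fs)
  got <- extract_features(x, e, fs)
  P <- direct_periodogram(x)
  freqs <- (0:(length(P) - 1)) * fs / length(x)
  bsum <- function(lo, hi) sum(P[freqs >= lo & freqs < hi])
  expect_equal(got[["log_delta"]], log(bsum(0.5, 4) + 1e-12), tolerance = 1e-8)
  expect_equal(got[["log_sigma"]], log(bsum(12, 20) + 1e-12), tolerance = 1e-8)
  expect_equal(got[["emg_rms"]], sqrt(mean(e^2)))
})

make_training <- function(cfg, duration = 40, seed = 100) {
  make_exemplars(cfg, duration = duration, seed = seed)
}

test_that("stager training enforces the exemplar contract", {
  cfg <- quick_config()
  ex <- make_training(cfg)
  expect_s3_class(fit_stager(ex), "sleep_stager")
  # a 20-s exemplar violates the 30-s minimum
  short <- make_exemplars(cfg, duration = 20)
  expect_error(fit_stager(short), "30 s")
  expect_error(fit_stager(ex[1:2]), "REM")
  expect_error(fit_stager(list()), "exemplar")
})

test_that("k = 1 self-classification of the training epochs is perfect", {
  cfg <- quick_config(seed = 31)
  ex <- make_training(cfg, seed = 131)
  model <- fit_stager(ex, k = 1)
  for (e in ex) {
    hyp <- score_recording(model, recording(e$eeg, e$emg, e$sampling_rate))
    expect_true(all(hyp$labels == e$state))
  }
})

test_that("predictions are invariant to exemplar order and deterministic", {
  cfg <- quick_config(seed = 32)
  ex <- make_training(cfg, seed = 132)
  sim <- synthesize_recording(quick_config(minutes = 3, seed = 33), "SHAM", "BASE")
  h1 <- score_recording(fit_stager(ex), sim$recording)
  h2 <- score_recording(fit_stager(rev(ex)), sim$recording)
  expect_identical(h1$labels, h2$labels)
})

test_that("a recording made of one repeated training epoch scores constant", {
  cfg <- quick_config(seed = 34)
  ex <- make_training(cfg, seed = 134)
  model <- fit_stager(ex)
  nrem <- ex[[which(vapply(ex, function(e) e$state, "") == "NREM")]]
  ep <- seq_len(5 * cfg$sampling_rate)
  rec <- recording(rep(nrem$eeg[ep], 6), rep(nrem$emg[ep], 6),
                   cfg$sampling_rate)
  expect_equal(score_recording(model, rec)$labels, rep("NREM", 6))
})

test_that("an empty epoch set yields an empty hypnogram", {
  cfg <- quick_config()
  model <- fit_stager(make_training(cfg))
  rec <- recording(numeric(100), numeric(100), cfg$sampling_rate)
  expect_length(score_recording(model, rec)$labels, 0)
})

test_that("staging recovers the generator ground truth on separated spectra", {
  cfg <- quick_config(minutes = 10, seed = 35)
  sim <- synthesize_recording(cfg, "NRP", "BASE")
  model <- fit_stager(make_exemplars(cfg, seed = 200))
  hyp <- score_recording(model, sim$recording)
  acc <- mean(hyp$labels == sim$truth$hypnogram$labels)
  expect_gte(acc, 0.9)
})

test_that("accuracy degrades monotonically as state separation vanishes", {
  blend <- function(sep) {
    sp <- default_state_spectra()
    for (s in names(sp)) {
      sp[[s]]$components[, "amp"] <- sp[[s]]$components[, "amp"] * sep
      sp[[s]]$noise <- 20
    }
    tone <- c(WAKE = 60, NREM = 15, REM = 4) * sep + 20 * (1 - sep)
    quick_config(minutes = 8, seed = 36, state_spectra = sp, emg_tone = tone)
  }
  accs <- vapply(c(1, 0.25, 0.02), function(sep) {
    cfg <- blend(sep)
    sim <- synthesize_recording(cfg, "SHAM", "BASE")
    model <- fit_stager(make_exemplars(cfg, seed = 300))
    mean(score_recording(model, sim$recording)$labels ==
           sim$truth$hypnogram$labels)
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_gte(accs[1], 0.9)
})

test_that("the deterministic KNN vote agrees with a reference KNN on tie-free data", {
  skip_if_not_installed("class")
  cfg <- quick_config(seed = 37)
  ex <- make_training(cfg, seed = 137)
  model <- fit_stager(ex, k = 1)
  sim <- synthesize_recording(quick_config(minutes = 2, seed = 38), "SHAM", "BASE")
  eps <- epoch_signal(sim$recording, 5)
  X <- t(vapply(seq_len(eps$n_epochs), function(i)
    extract_features(eps$eeg[, i], eps$emg[, i], eps$sampling_rate),
    numeric(6)))
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  ref <- as.character(class::knn(model$features, Xs,
                                 factor(model$labels, SLEEP_STATES), k = 1))
  got <- predict(model, eps)$labels
  expect_equal(got, ref)
})

test_that("stage percentages follow the chosen denominator", {
  labs <- c("WAKE", "WAKE", rep("NREM", 3), rep("REM", 5))
  h <- hypnogram(labs, 5)
  expect_equal(stage_percentages(h),
               c(pct_wake = 20, pct_nrem = 30, pct_rem = 50))
  ts <- stage_percentages(h, "TOTAL_SLEEP")
  expect_equal(ts[["pct_rem"]], 62.5)
  expect_equal(ts[["pct_nrem"]] + ts[["pct_rem"]], 100)
  all_nrem <- hypnogram(rep("NREM", 4), 5)
  expect_equal(stage_percentages(all_nrem)[["pct_nrem"]], 100)
  expect_equal(stage_percentages(all_nrem, "TOTAL_SLEEP")[["pct_nrem"]], 100)
  expect_error(stage_percentages(hypnogram(character(0), 5)), "empty")
  expect_error(stage_percentages(hypnogram(rep("WAKE", 3), 5), "TOTAL_SLEEP"),
               "no sleep")
})
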