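#' Hypnogram: per-epoch vigilance-state labels
#'
#' @param labels character vector over `WAKE`/`NREM`/`REM`.
#' @param epoch_length seconds per epoch.
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_length = 5) {
  labels <- as.character(labels)
  if (length(labels) > 0L && !all(labels %in% SLEEP_STATES))
    stop_input("hypnogram labels must be in {%s}",
               paste(SLEEP_STATES, collapse = ", "))
  check_scalar_num(epoch_length, "epoch_length", 0, strict = TRUE)
  structure(list(labels = labels, epoch_length = epoch_length),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("<hypnogram> %d x %g-s epochs", n, x$epoch_length))
  if (n > 0L) {
    tb <- table(factor(x$labels, SLEEP_STATES))
    cat(": ", paste(sprintf("%s %.1f%%", names(tb), 100 * tb / n),
                    collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Write / read a hypnogram as tab-separated text
#'
#' Columns: `epoch_index`, `start_s`, `state`.
#' @param hyp a [hypnogram()].
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(epoch_index = seq_along(hyp$labels),
                   start_s = (seq_along(hyp$labels) - 1L) * hyp$epoch_length,
                   state = hyp$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.delim(path)
  ep <- if (nrow(df) > 1L) df$start_s[2L] - df$start_s[1L] else 5
  hypnogram(df$state, ep)
}

#' A labelled exemplar segment for stager training
#'
#' One visually identified, state-typical stretch of EEG+EMG used to train
#' the epoch classifier. Segments must be at least 30 s long (enforced at
#' fit time).
#'
#' @param state `WAKE`, `NREM` or `REM`.
#' @param eeg,emg numeric sample vectors of equal length.
#' @param sampling_rate Hz.
#' @return object of class `exemplar`.
#' @export
exemplar <- function(state, eeg, emg, sampling_rate) {
  state <- match_label(state, SLEEP_STATES, "state")
  if (length(eeg) != length(emg))
    stop_input("exemplar eeg and emg must have equal length")
  check_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  structure(list(state = state, eeg = as.numeric(eeg), emg = as.numeric(emg),
                 sampling_rate = sampling_rate,
                 duration = length(eeg) / sampling_rate),
            class = "exemplar")
}

# band power of one epoch: one-sided periodogram mass in [lo, hi), scaled so
# a unit-amplitude sinusoid contributes 1/2 regardless of epoch length
band_power <- function(X2, freqs, lo, hi) {
  sum(X2[freqs >= lo & freqs < hi])
}

#' Per-epoch staging features
#'
#' Log band powers (delta 0.5-4, theta 4-9, sigma 12-20, beta 20-30 Hz) of
#' the EEG periodogram, the theta/delta power ratio, and the EMG RMS. An
#' all-zero epoch is still defined (log powers floored at a small epsilon).
#' Feature z-scoring against training statistics is applied by the stager,
#' not here.
#'
#' @param eeg_epoch,emg_epoch numeric sample vectors (one epoch).
#' @param sampling_rate Hz.
#' @return named numeric feature vector.
#' @export
extract_features <- function(eeg_epoch, emg_epoch, sampling_rate) {
  n <- length(eeg_epoch)
  X2 <- (2 / n^2) * Mod(stats::fft(eeg_epoch))^2
  nf <- floor(n / 2) + 1L
  X2 <- X2[seq_len(nf)]
  freqs <- (seq_len(nf) - 1L) * sampling_rate / n
  eps <- 1e-12
  d <- band_power(X2, freqs, 0.5, 4)
  th <- band_power(X2, freqs, 4, 9)
  si <- band_power(X2, freqs, 12, 20)
  be <- band_power(X2, freqs, 20, 30)
  c(log_delta = log(d + eps), log_theta = log(th + eps),
    log_sigma = log(si + eps), log_beta = log(be + eps),
    theta_delta_ratio = (th + eps) / (d + eps),
    emg_rms = sqrt(mean(emg_epoch^2)))
}

feature_matrix <- function(eps, ...) {
  t(vapply(seq_len(eps$n_epochs), function(i)
    extract_features(eps$eeg[, i], eps$emg[, i], eps$sampling_rate),
    numeric(6L)))
}

#' Fit an exemplar-trained k-nearest-neighbour sleep stager
#'
#' The semi-automatic scoring scheme: state-typical exemplar segments
#' (at least 30 s each, all three states represented) are cut into scoring
#' epochs, per-epoch features extracted, and a KNN classifier over the
#' z-scored features is stored. Prediction assigns each 5-s epoch the
#' majority state among its `k` nearest training epochs (Euclidean distance);
#' distance and vote ties are broken by the fixed state order
#' WAKE < NREM < REM so results never depend on exemplar input order.
#'
#' @param exemplars list of [exemplar()] objects.
#' @param k neighbourhood size (default 5).
#' @param epoch_length scoring epoch length, seconds (default 5).
#' @return object of class `sleep_stager`.
#' @seealso [score_recording()], [predict.sleep_stager()]
#' @export
fit_stager <- function(exemplars, k = 5, epoch_length = 5) {
  if (!is.list(exemplars) || !all(vapply(exemplars, inherits, TRUE, "exemplar")))
    stop_input("exemplars must be a list of exemplar objects")
  check_scalar_num(k, "k", 1)
  states <- vapply(exemplars, function(e) e$state, character(1))
  missing <- setdiff(SLEEP_STATES, states)
  if (length(missing) > 0L)
    stop_input("training set lacks exemplar(s) for state(s): %s",
               paste(missing, collapse = ", "))
  short <- vapply(exemplars, function(e) e$duration, numeric(1)) < 30
  if (any(short))
    stop_input("exemplar(s) shorter than the 30 s minimum: %s",
               paste(sprintf("%s (%.1f s)", states[short],
                             vapply(exemplars[short], function(e) e$duration,
                                    numeric(1))), collapse = ", "))
  fs <- unique(vapply(exemplars, function(e) e$sampling_rate, numeric(1)))
  if (length(fs) != 1L)
    stop_input("all exemplars must share one sampling rate (got %s)",
               paste(fs, collapse = ", "))

  feats <- list(); labs <- character(0)
  for (e in exemplars) {
    eps <- epoch_signal(recording(e$eeg, e$emg, e$sampling_rate), epoch_length)
    feats[[length(feats) + 1L]] <- feature_matrix(eps)
    labs <- c(labs, rep(e$state, eps$n_epochs))
  }
  X <- do.call(rbind, feats)
  mu <- colMeans(X)
  sg <- pmax(apply(X, 2L, stats::sd), 1e-8)
  structure(list(
    features = sweep(sweep(X, 2L, mu), 2L, sg, "/"),
    labels = labs, center = mu, scale = sg,
    k = as.integer(k), epoch_length = epoch_length, sampling_rate = fs),
    class = "sleep_stager")
}

#' @export
print.sleep_stager <- function(x, ...) {
  cat(sprintf("<sleep_stager> k=%d, %d training epochs (%s), %g-s epochs @ %g Hz\n",
              x$k, length(x$labels),
              paste(sprintf("%s %d", SLEEP_STATES,
                            tabulate(match(x$labels, SLEEP_STATES), 3L)),
                    collapse = ", "),
              x$epoch_length, x$sampling_rate))
  invisible(x)
}

# deterministic KNN vote for one scaled feature vector
knn_vote <- function(model, v) {
  d2 <- colSums((t(model$features) - v)^2)
  st <- match(model$labels, SLEEP_STATES)
  ord <- order(d2, st)                # distance ties -> state order
  top <- st[ord[seq_len(min(model$k, length(ord)))]]
  counts <- tabulate(top, 3L)
  SLEEP_STATES[which.max(counts)]     # vote ties -> state order
}

#' Score a recording into a hypnogram
#'
#' @param model a fitted [fit_stager()] model.
#' @param rec a [recording()] (same sampling rate as the exemplars).
#' @return a [hypnogram()], one label per epoch (empty if the recording is
#'   shorter than one epoch).
#' @export
score_recording <- function(model, rec) {
  stopifnot(inherits(model, "sleep_stager"), inherits(rec, "recording"))
  if (abs(rec$sampling_rate - model$sampling_rate) > 1e-9)
    stop_input("recording sampling rate (%g Hz) differs from training (%g Hz)",
               rec$sampling_rate, model$sampling_rate)
  eps <- epoch_signal(rec, model$epoch_length)
  predict(model, eps)
}

#' @rdname score_recording
#' @param object a `sleep_stager`.
#' @param newdata a [recording()] or `epoch_set`.
#' @param ... unused.
#' @export
predict.sleep_stager <- function(object, newdata, ...) {
  if (inherits(newdata, "recording"))
    return(score_recording(object, newdata))
  stopifnot(inherits(newdata, "epoch_set"))
  if (newdata$n_epochs == 0L)
    return(hypnogram(character(0), object$epoch_length))
  X <- feature_matrix(newdata)
  X <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  labels <- vapply(seq_len(nrow(X)), function(i) knn_vote(object, X[i, ]),
                   character(1))
  hypnogram(labels, object$epoch_length)
}

#' Stage-occupancy percentages
#'
#' Fraction of epochs per state, over the whole recording
#' (`TOTAL_RECORDING`: the three percentages sum to 100) or over sleep only
#' (`TOTAL_SLEEP`: NREM + REM sum to 100, wake reported as NA).
#'
#' @param hyp a [hypnogram()] (non-empty).
#' @param denominator `"TOTAL_RECORDING"` (default) or `"TOTAL_SLEEP"`.
#' @return named numeric vector `pct_wake`, `pct_nrem`, `pct_rem`.
#' @export
stage_percentages <- function(hyp,
                              denominator = c("TOTAL_RECORDING", "TOTAL_SLEEP")) {
  stopifnot(inherits(hyp, "hypnogram"))
  denominator <- match.arg(denominator)
  n <- length(hyp$labels)
  if (n == 0L) stop_input("cannot compute stage percentages of an empty hypnogram")
  counts <- tabulate(match(hyp$labels, SLEEP_STATES), 3L)
  names(counts) <- SLEEP_STATES
  if (denominator == "TOTAL_RECORDING") {
    p <- 100 * counts / n
    c(pct_wake = unname(p["WAKE"]), pct_nrem = unname(p["NREM"]),
      pct_rem = unname(p["REM"]))
  } else {
    sleep <- counts["NREM"] + counts["REM"]
    if (sleep == 0L)
      stop_input("TOTAL_SLEEP denominator undefined: no sleep epochs")
    c(pct_wake = NA_real_, pct_nrem = unname(100 * counts["NREM"] / sleep),
      pct_rem = unname(100 * counts["REM"] / sleep))
  }
}
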