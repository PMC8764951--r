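#' @export
plot.hypnogram <- function(x, ...) {
  n <- length(x$labels)
  if (n == 0L) stop_input("nothing to plot: empty hypnogram")
  t <- (seq_len(n) - 1L) * x$epoch_length / 60
  y <- match(x$labels, SLEEP_STATES)
  plot(t, y, type = "s", yaxt = "n", ylim = c(0.5, 3.5),
       xlab = "time (min)", ylab = "", main = "Hypnogram", ...)
  graphics::axis(2, at = 1:3, labels = SLEEP_STATES, las = 1)
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, flim = c(0, 40), ...) {
  sel <- x$freqs >= flim[1L] & x$freqs <= flim[2L]
  graphics::image(x$times / 60, x$freqs[sel],
                  log10(x$power[, sel, drop = FALSE] + 1e-12),
                  xlab = "time (min)", ylab = "frequency (Hz)",
                  main = "EEG spectrogram (log10 power)", ...)
  invisible(x)
}

#' @export
plot.sigma_trace <- function(x, threshold = NULL, ...) {
  plot(x$times / 60, x$sigma_power, type = "l", xlab = "time (min)",
       ylab = expression(paste("sigma power (", mu, V^2, ")")),
       main = sprintf("Band power %g-%g Hz", x$band[1L], x$band[2L]), ...)
  if (!is.null(threshold))
    graphics::abline(h = threshold, col = "red", lty = 2)
  invisible(x)
}
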