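# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input("'%s' must be a finite numeric scalar", name)
  ok <- if (strict) x > lower else x >= lower
  if (!ok)
    stop_input("'%s' must be %s %s, got %s", name,
               if (strict) ">" else ">=", format(lower), format(x))
  invisible(x)
}

match_label <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    stop_input("'%s' must be one of %s (got '%s')",
               name, paste(choices, collapse = ", "), paste(x, collapse = ","))
  x
}

# analytic-signal amplitude envelope (FFT method)
amplitude_envelope <- function(x) {
  n <- length(x)
  if (n < 2L) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Hann taper, periodic convention
hann_window <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

# population (divide-by-n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
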