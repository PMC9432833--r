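# Shared numeric helpers: filters, smoothing, seeds.

#' Centered moving average ("span" smoothing)
#'
#' Smooths a trace with a centered moving average of odd span; at the ends the
#' window shrinks symmetrically so the output has no edge NAs. With
#' `span = 5` this is the "low-pass filter with a span of 5" used before
#' event-average alignment.
#'
#' @param x numeric vector.
#' @param span odd window length in samples (default 5).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, span = 5L) {
  span <- as.integer(span)
  stopifnot(span >= 1L, span %% 2L == 1L)
  n <- length(x)
  if (span == 1L || n == 0L) return(x)
  h <- span %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Windowed-sinc FIR high-pass filter coefficients
#'
#' Designs a linear-phase FIR high-pass by spectral inversion of a
#' Hamming-windowed sinc low-pass. `order` is the filter order (taps =
#' order + 1); `order` must be even so the inversion delta lands on the
#' center tap.
#'
#' @param order filter order (default 50).
#' @param cutoff_hz cutoff frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return numeric vector of `order + 1` coefficients.
#' @export
fir_highpass <- function(order = 50L, cutoff_hz = 1, fs = 9.76) {
  order <- as.integer(order)
  stopifnot(order >= 2L, order %% 2L == 0L, cutoff_hz > 0, cutoff_hz < fs / 2)
  m <- order / 2
  n <- 0:order
  fc <- cutoff_hz / (fs / 2)              # normalized to Nyquist
  arg <- n - m
  h_lp <- ifelse(arg == 0, fc, fc * sin(pi * fc * arg) / (pi * fc * arg))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)   # Hamming
  h_lp <- h_lp * w
  h_lp <- h_lp / sum(h_lp)                # unit DC gain before inversion
  h_hp <- -h_lp
  h_hp[m + 1] <- h_hp[m + 1] + 1
  h_hp
}

#' Apply an FIR filter forward (causal convolution)
#'
#' Forward-only convolution; the first `length(h) - 1` samples, where the
#' filter has not yet filled, are dropped from the output.
#'
#' @param x numeric vector, length > filter order.
#' @param h FIR coefficients.
#' @return filtered vector of length `length(x) - length(h) + 1`.
#' @export
fir_apply <- function(x, h) {
  ord <- length(h) - 1L
  if (length(x) <= ord) stop("trace too short for filter order ", ord)
  y <- stats::filter(x, h, method = "convolution", sides = 1)
  as.numeric(y[(ord + 1L):length(x)])
}

# Derive a child seed from a top-level seed; keeps results < 2^31 so R
# integers never overflow. `slot` distinguishes modules/uses.
child_seed <- function(seed, slot) {
  seed <- as.double(seed)
  (seed * 48271 + 7919 * as.double(slot)) %% 2147483587
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Double-exponential calcium indicator kernel, normalized to unit peak.
# Analytic time to peak: rise * log((rise + decay) / rise).
calcium_kernel <- function(rate, rise = 0.2, decay = 1.8, duration = NULL) {
  if (is.null(duration)) duration <- decay * 5
  t <- seq(0, duration, by = 1 / rate)
  h <- (1 - exp(-t / rise)) * exp(-t / decay)
  h / max(h)
}

kernel_time_to_peak <- function(rise = 0.2, decay = 1.8) {
  rise * log((rise + decay) / rise)
}
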