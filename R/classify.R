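# Permutation-null classification of neurons into socially activated (SAN),
# socially inactivated (SIN) and other neurons, plus the statistics that
# accompany it: signal-behavior correlation, peri-event average traces,
# high-pass noise estimation, and engagement analysis.

#' Similarity between a behavior vector and a calcium trace
#'
#' `S = (B . C) / (|B|^2 + |C|^2)`. For a binary `B` and `C = B` this equals
#' 0.5; disjoint supports give 0.
#'
#' @param B behavior vector (usually binary).
#' @param C dF/F trace, equal length.
#' @return scalar similarity.
#' @export
similarity <- function(B, C) {
  stopifnot(length(B) == length(C))
  den <- sum(B^2) + sum(C^2)
  if (den == 0) stop("similarity undefined: both vectors are zero")
  sum(B * C) / den
}

#' Permutation null distribution of the similarity
#'
#' Randomly permutes `B` `k` times (full shuffles) and recomputes the
#' similarity against `C`. Norms are permutation-invariant, so only the dot
#' product is resampled; binary `B` uses an O(k m) sampling shortcut.
#' Draws consume R's RNG stream, so results are reproducible under
#' `set.seed()`.
#'
#' @inheritParams similarity
#' @param k number of shuffles (default 1000).
#' @return numeric vector of `k` null similarities.
#' @export
permutation_null <- function(B, C, k = 1000L) {
  stopifnot(length(B) == length(C), k >= 1)
  den <- sum(B^2) + sum(C^2)
  if (den == 0) stop("similarity undefined: both vectors are zero")
  if (all(B %in% c(0, 1))) {
    dots <- perm_null_dot_binary(as.numeric(C), as.integer(sum(B)),
                                 as.integer(k))
  } else {
    dots <- perm_null_dot_full(as.numeric(B), as.numeric(C), as.integer(k))
  }
  dots / den
}

#' Classify one neuron against its permutation null
#'
#' SAN if `S` is strictly greater than the upper percentile of the null
#' samples, SIN if strictly lower than the lower percentile, otherwise Other.
#' Percentiles use linear interpolation between order statistics
#' (`quantile type 7`; configurable).
#'
#' @param S observed similarity.
#' @param null_samples numeric vector of null similarities.
#' @param upper_pct,lower_pct percentile thresholds (defaults 99.17 / 0.83,
#'   about 1/120 per tail).
#' @param type quantile algorithm (default 7).
#' @return list with `label` ("SAN"/"SIN"/"Other"), `thr_hi`, `thr_lo`.
#' @export
classify_neuron <- function(S, null_samples, upper_pct = 99.17,
                            lower_pct = 0.83, type = 7) {
  stopifnot(length(null_samples) >= 1)
  thr <- stats::quantile(null_samples, c(lower_pct, upper_pct) / 100,
                         names = FALSE, type = type)
  label <- if (S > thr[2]) "SAN" else if (S < thr[1]) "SIN" else "Other"
  list(label = label, thr_hi = thr[2], thr_lo = thr[1])
}

#' Classify every neuron of a dF/F matrix
#'
#' @param dff a [dff_matrix()] (or plain neurons x frames matrix).
#' @param B binary social behavior vector on the imaging timebase.
#' @param k shuffles per neuron (default 1000).
#' @inheritParams classify_neuron
#' @param seed optional seed set once before the neuron loop.
#' @return data.frame (neuron, S, thr_lo, thr_hi, label).
#' @export
classify_neurons <- function(dff, B, k = 1000L, upper_pct = 99.17,
                             lower_pct = 0.83, type = 7, seed = NULL) {
  C <- if (inherits(dff, "dff_matrix")) dff$C else as.matrix(dff)
  stopifnot(ncol(C) == length(B))
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nrow(C))
  for (i in seq_len(nrow(C))) {
    S <- similarity(B, C[i, ])
    nulls <- permutation_null(B, C[i, ], k)
    cl <- classify_neuron(S, nulls, upper_pct, lower_pct, type)
    out[[i]] <- data.frame(neuron = i, S = S, thr_lo = cl$thr_lo,
                           thr_hi = cl$thr_hi, label = cl$label,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Mean ensemble similarity (signal-behavior correlation)
#'
#' Mean similarity over the SAN ensemble and over the SIN ensemble. Empty
#' ensembles are reported as NA (missing), never as 0.
#'
#' @param labels character vector of per-neuron labels.
#' @param similarities matching numeric vector of `S` values.
#' @return named numeric `c(SAN = ..., SIN = ...)`.
#' @export
signal_behavior_correlation <- function(labels, similarities) {
  stopifnot(length(labels) == length(similarities))
  one <- function(lab) {
    s <- similarities[labels == lab]
    if (!length(s)) NA_real_ else mean(s)
  }
  c(SAN = one("SAN"), SIN = one("SIN"))
}

# valid peri-onset fragments: 4 s of clean NE before the epoch start and 4 s
# inside the event after it (mirrored for offsets). Returns start indices
# (R, 1-based) of the 8 s windows.
valid_fragments <- function(b_event, b_ne, rate, mode, window_s = 4) {
  w <- round(window_s * rate)
  ep <- vector_to_epochs(b_event, seq_along(b_event) / rate)
  starts <- integer(0)
  for (i in seq_len(nrow(ep))) {
    if (mode == "onset") {
      s <- ep$start_frame[i] + 1L        # first event frame, R index
      pre <- (s - w):(s - 1L); post <- s:(s + w - 1L)
      if (min(pre) < 1L || max(post) > length(b_event)) next
      if (all(b_ne[pre] == 1L) && all(b_event[post] == 1L))
        starts <- c(starts, s - w)
    } else {
      e <- ep$end_frame[i]               # last event frame, R index
      pre <- (e - w + 1L):e; post <- (e + 1L):(e + w)
      if (min(pre) < 1L || max(post) > length(b_event)) next
      if (all(b_event[pre] == 1L) && all(b_ne[post] == 1L))
        starts <- c(starts, e - w + 1L)
    }
  }
  starts
}

#' Peri-event average dF/F trace
#'
#' Valid fragments are 8 s windows around event onsets whose first 4 s are
#' entirely nonexploration (NE) and whose last 4 s are entirely inside the
#' event (reversed for `mode = "offset"`). Each neuron's trace is smoothed
#' with a span-5 moving average, valid fragments are aligned and averaged;
#' with `relative = TRUE` the neuron's mean dF/F over NE frames is subtracted
#' first.
#'
#' @param C_i one trace, or a neurons x frames matrix (rows averaged into an
#'   ensemble trace after per-neuron averaging).
#' @param b_event binary event vector on the imaging timebase.
#' @param b_ne binary NE vector.
#' @param rate imaging rate, Hz.
#' @param mode `"onset"` or `"offset"`.
#' @param relative subtract the NE-mean baseline first.
#' @param span smoothing span (default 5).
#' @param window_s half-window, s (default 4).
#' @return list with `time` (s, 0 at the transition), `mean`, `n_events`;
#'   `mean` is NA with `n_events = 0` when no fragment is valid.
#' @export
event_average_trace <- function(C_i, b_event, b_ne, rate = 9.76,
                                mode = c("onset", "offset"), relative = FALSE,
                                span = 5L, window_s = 4) {
  mode <- match.arg(mode)
  M <- if (is.matrix(C_i)) C_i else matrix(C_i, nrow = 1)
  w <- round(window_s * rate)
  starts <- valid_fragments(b_event, b_ne, rate, mode, window_s)
  time <- (seq_len(2L * w) - w - 0.5) / rate
  if (!length(starts))
    return(list(time = time, mean = rep(NA_real_, 2L * w), n_events = 0L))
  per_neuron <- matrix(NA_real_, nrow(M), 2L * w)
  for (i in seq_len(nrow(M))) {
    x <- M[i, ]
    if (relative) {
      ne_mean <- mean(x[b_ne == 1L])
      x <- x - ne_mean
    }
    xs <- moving_average(x, span)
    frag <- vapply(starts, function(s) xs[s:(s + 2L * w - 1L)],
                   numeric(2L * w))
    per_neuron[i, ] <- rowMeans(frag)
  }
  list(time = time, mean = colMeans(per_neuron), n_events = length(starts))
}

#' High-pass noise level of a trace
#'
#' SD of the trace after a forward pass of a 50th-order FIR high-pass
#' (Hamming-windowed sinc, spectral inversion) with 1 Hz cutoff.
#'
#' @param x dF/F trace, length > `order`.
#' @param rate sampling rate, Hz (default 9.76).
#' @param order filter order (default 50).
#' @param cutoff_hz cutoff (default 1).
#' @return noise SD (scalar).
#' @export
noise_highpass <- function(x, rate = 9.76, order = 50L, cutoff_hz = 1) {
  h <- fir_highpass(order, cutoff_hz, rate)
  stats::sd(fir_apply(x, h))
}

#' Engagement of a neuron in behavior events
#'
#' A neuron is engaged in an event iff at least `n` samples inside the event
#' exceed `factor` times its noise level (noise from [noise_highpass()] on
#' the whole trace). Events shorter than `n` frames can never be engaged.
#'
#' @param C_i one dF/F trace.
#' @param epochs epoch table with `start_frame`/`end_frame` (0-based,
#'   half-open).
#' @param rate imaging rate, Hz.
#' @param n required number of supra-threshold samples (default 10).
#' @param factor noise multiplier (default 3).
#' @param noise optional precomputed noise level.
#' @return list with per-event logical `engaged`, `consistency`
#'   (engaged / total events) and `noise`.
#' @export
engagement <- function(C_i, epochs, rate = 9.76, n = 10L, factor = 3,
                       noise = NULL) {
  noise <- noise %||% noise_highpass(C_i, rate)
  thr <- factor * noise
  engaged <- vapply(seq_len(nrow(epochs)), function(i) {
    sel <- (epochs$start_frame[i] + 1L):epochs$end_frame[i]
    sel <- sel[sel >= 1L & sel <= length(C_i)]
    sum(C_i[sel] > thr) >= n
  }, logical(1))
  list(engaged = engaged,
       consistency = if (nrow(epochs)) mean(engaged) else NA_real_,
       noise = noise)
}

#' Percentage of ensemble neurons engaged per event
#'
#' @param C neurons x frames matrix (an ensemble).
#' @param epochs epoch table.
#' @inheritParams engagement
#' @return numeric vector, one fraction in `[0, 1]` per event.
#' @export
engagement_percentage <- function(C, epochs, rate = 9.76, n = 10L,
                                  factor = 3) {
  eng <- vapply(seq_len(nrow(C)), function(i)
    engagement(C[i, ], epochs, rate, n, factor)$engaged,
    logical(nrow(epochs)))
  if (nrow(epochs) == 1L) eng <- matrix(eng, nrow = 1)
  rowMeans(eng)
}
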