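# Socially activated epoch detection and per-neuron kinetic summaries:
# activation probability (P_up), rise time (time to peak) and amplitude of
# cue-evoked transients.

#' Status of one epoch for one neuron
#'
#' An epoch is discarded if it is shorter than `window_s` seconds or if the
#' exploration-free interval immediately before it is shorter than
#' `window_s` (cross-talk guard). Otherwise the peak is the maximum of the
#' trace over `[start - window_s, start + window_s]`; the epoch is activated
#' iff the peak time falls strictly after the start and within `window_s`
#' after it (a peak exactly at start counts as nonactivated; frame ties take
#' the earliest frame).
#'
#' @param C_i dF/F trace.
#' @param timestamps frame times, s.
#' @param start_time,end_time epoch bounds, s.
#' @param prev_end_time end of the previous exploration epoch of any type
#'   (-Inf if none).
#' @param window_s analysis window, s (default 4).
#' @return list: `status` ("activated"/"nonactivated"/"discarded"),
#'   `peak_time` (s, relative to start), `peak_value`, `baseline` (min over
#'   the 4 s pre-window).
#' @export
epoch_status <- function(C_i, timestamps, start_time, end_time,
                         prev_end_time = -Inf, window_s = 4) {
  if (end_time - start_time < window_s ||
      start_time - prev_end_time < window_s)
    return(list(status = "discarded", peak_time = NA_real_,
                peak_value = NA_real_, baseline = NA_real_))
  sel <- which(timestamps >= start_time - window_s &
                 timestamps <= start_time + window_s)
  pre <- which(timestamps >= start_time - window_s & timestamps < start_time)
  if (!length(sel) || !length(pre))
    return(list(status = "discarded", peak_time = NA_real_,
                peak_value = NA_real_, baseline = NA_real_))
  pk <- sel[which.max(C_i[sel])]          # which.max -> earliest on ties
  pk_t <- timestamps[pk] - start_time
  status <- if (pk_t > 0 && pk_t <= window_s) "activated" else "nonactivated"
  list(status = status, peak_time = pk_t, peak_value = C_i[pk],
       baseline = min(C_i[pre]))
}

#' Kinetic summary of one neuron over the epochs of one cue
#'
#' `P_up` = activated / (activated + nonactivated); discarded epochs are
#' excluded from the denominator. Rise time (peak time - start) and
#' amplitude (peak - pre-window minimum) are averaged over activated epochs.
#'
#' @param C_i dF/F trace.
#' @param timestamps frame times, s.
#' @param epochs epoch table for the cue (`start_time`, `end_time`).
#' @param all_epochs optional epoch table of every exploration event in the
#'   session, used to find the preceding epoch for the pre-gap rule
#'   (defaults to `epochs`).
#' @param window_s analysis window, s (default 4).
#' @return list: `P_up`, `rise_time`, `amplitude` (NA when no activated
#'   epoch), `n_activated`, `n_nonactivated`, `n_discarded`, and the
#'   per-epoch `status` table.
#' @export
kinetic_summary <- function(C_i, timestamps, epochs, all_epochs = epochs,
                            window_s = 4) {
  n <- nrow(epochs)
  st <- character(n); pk_t <- numeric(n); amp <- numeric(n)
  for (i in seq_len(n)) {
    prev <- all_epochs$end_time[all_epochs$end_time <= epochs$start_time[i]]
    prev_end <- if (length(prev)) max(prev) else -Inf
    r <- epoch_status(C_i, timestamps, epochs$start_time[i],
                      epochs$end_time[i], prev_end, window_s)
    st[i] <- r$status
    pk_t[i] <- r$peak_time
    amp[i] <- if (is.na(r$peak_value)) NA_real_ else r$peak_value - r$baseline
  }
  act <- st == "activated"; non <- st == "nonactivated"
  denom <- sum(act) + sum(non)
  list(P_up = if (denom > 0) sum(act) / denom else NA_real_,
       rise_time = if (any(act)) mean(pk_t[act]) else NA_real_,
       amplitude = if (any(act)) mean(amp[act]) else NA_real_,
       n_activated = sum(act), n_nonactivated = sum(non),
       n_discarded = sum(st == "discarded"),
       status = data.frame(epoch = seq_len(n), status = st,
                           peak_time = pk_t, amplitude = amp,
                           stringsAsFactors = FALSE))
}

#' Kinetics for every neuron x cue combination
#'
#' @param dff a [dff_matrix()].
#' @param session a `behavior_session`.
#' @param cues event types to analyze (default `new` and `old`).
#' @param neurons neuron indices (default all).
#' @param window_s analysis window, s.
#' @return data.frame (neuron, cue, P_up, rise_time, amplitude, counts).
#' @export
kinetics_table <- function(dff, session, cues = c("new", "old"),
                           neurons = NULL, window_s = 4) {
  neurons <- neurons %||% seq_len(nrow(dff$C))
  rows <- list()
  for (cue in cues) {
    ep <- session$epochs[session$epochs$event == cue, , drop = FALSE]
    for (i in neurons) {
      ks <- kinetic_summary(dff$C[i, ], dff$timestamps, ep, session$epochs,
                            window_s)
      rows[[length(rows) + 1L]] <- data.frame(
        neuron = i, cue = cue, P_up = ks$P_up, rise_time = ks$rise_time,
        amplitude = ks$amplitude, n_activated = ks$n_activated,
        n_nonactivated = ks$n_nonactivated, n_discarded = ks$n_discarded,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
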