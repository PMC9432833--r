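# Event-associated neuron (EAN) detection across the three-stage paradigm,
# social-cue-preferred neuron set logic, and the behavioral correlation
# matrix.
#
# Stage-correct pairing: each event type is contrasted against its own
# stage's nonexploration (NE) frames — cage in habituation, object/mouse in
# sociability, new/old in the novelty stage.

#' Mean dF/F amplitude during a state
#'
#' Conditional mean of `C_i` over frames with `B == 1` (default). The
#' alternative reading of the bracketed mean `<B . C>` — masked sum divided
#' by the full trace length, which conflates tuning with event frequency —
#' is available as `normalize = "full"`.
#'
#' @param C_i dF/F trace.
#' @param B binary state vector.
#' @param normalize `"active"` (default) or `"full"`.
#' @return scalar; NA if the state has no active frames.
#' @export
mean_state_amplitude <- function(C_i, B, normalize = c("active", "full")) {
  normalize <- match.arg(normalize)
  stopifnot(length(C_i) == length(B))
  if (sum(B) == 0) return(NA_real_)
  if (normalize == "active") mean(C_i[B == 1]) else sum(C_i * B) / length(C_i)
}

#' NE-spliced noise level
#'
#' Concatenates the NE frames of a trace and applies the same 50th-order /
#' 1 Hz high-pass + SD estimate as [noise_highpass()].
#'
#' @param C_i dF/F trace.
#' @param B_NE binary NE vector.
#' @inheritParams noise_highpass
#' @return noise SD; error if fewer NE frames than the filter needs.
#' @export
noise_ne <- function(C_i, B_NE, rate = 9.76, order = 50L, cutoff_hz = 1) {
  x <- C_i[B_NE == 1]
  if (length(x) <= order)
    stop("too few NE frames (", length(x), ") for filter order ", order)
  noise_highpass(x, rate, order, cutoff_hz)
}

#' EAN flag for one event type
#'
#' Strict threshold: flagged iff `c_E - c_NE > beta * noise_NE`.
#'
#' @param c_e,c_ne mean amplitudes during the event / during NE.
#' @param noise scalar NE noise level.
#' @param beta significance threshold (default 0.5).
#' @return logical.
#' @export
detect_ean <- function(c_e, c_ne, noise, beta = 0.5) {
  !is.na(c_e) && !is.na(c_ne) && (c_e - c_ne > beta * noise)
}

#' Social-cue-preferred label from the five EAN flags
#'
#' NewPN iff NewN and none of CageN/ON/MN/OldN; OldPN iff OldN and none of
#' CageN/ON/MN/NewN; otherwise "none". Mutually exclusive by construction.
#'
#' @param flags named logical vector with elements `cage`, `object`, `mouse`,
#'   `new`, `old`.
#' @return "NewPN", "OldPN" or "none".
#' @export
preferred_labels <- function(flags) {
  stopifnot(all(EVENT_TYPES %in% names(flags)))
  f <- flags[EVENT_TYPES]
  if (f[["new"]] && !f[["cage"]] && !f[["object"]] && !f[["mouse"]] &&
      !f[["old"]]) return("NewPN")
  if (f[["old"]] && !f[["cage"]] && !f[["object"]] && !f[["mouse"]] &&
      !f[["new"]]) return("OldPN")
  "none"
}

# stage-specific NE vector: frames of `stg` with no event of any type active
stage_ne_vector <- function(session, stg) {
  as.integer(session$stage == stg & session$B_NE == 1L)
}

#' Per-neuron tuning profiles over the five event types
#'
#' For every neuron and event type: mean amplitude during the event, mean
#' amplitude during that stage's NE frames, their difference, the NE-spliced
#' noise level, the EAN flag at threshold `beta`, and the resulting preferred
#' label.
#'
#' @param dff a [dff_matrix()].
#' @param session a `behavior_session` (provides event vectors, stages, NE).
#' @param beta EAN threshold (default 0.5).
#' @param normalize passed to [mean_state_amplitude()].
#' @return data.frame, one row per neuron: `c_<event>` columns,
#'   `c_ne_<stage>`, `noise_ne_<stage>`, `ean_<event>` flags, `preferred`.
#' @export
tuning_profile <- function(dff, session, beta = 0.5,
                           normalize = c("active", "full")) {
  normalize <- match.arg(normalize)
  C <- dff$C
  rate <- 1 / stats::median(diff(dff$timestamps))
  ne_vecs <- lapply(STAGES, function(s) stage_ne_vector(session, s))
  names(ne_vecs) <- STAGES
  rows <- vector("list", nrow(C))
  for (i in seq_len(nrow(C))) {
    c_ne <- vapply(STAGES, function(s)
      mean_state_amplitude(C[i, ], ne_vecs[[s]], normalize), numeric(1))
    nse <- vapply(STAGES, function(s)
      noise_ne(C[i, ], ne_vecs[[s]], rate), numeric(1))
    c_e <- vapply(EVENT_TYPES, function(e)
      mean_state_amplitude(C[i, ], session$B[, e], normalize), numeric(1))
    flags <- vapply(EVENT_TYPES, function(e) {
      s <- EVENT_STAGES[[e]]
      detect_ean(c_e[[e]], c_ne[[s]], nse[[s]], beta)
    }, logical(1))
    row <- c(list(neuron = i),
             as.list(stats::setNames(c_e, paste0("c_", EVENT_TYPES))),
             as.list(stats::setNames(c_ne, paste0("c_ne_", STAGES))),
             as.list(stats::setNames(nse, paste0("noise_ne_", STAGES))),
             as.list(stats::setNames(flags, paste0("ean_", EVENT_TYPES))),
             list(preferred = preferred_labels(flags)))
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "beta") <- beta
  out
}

#' Behavioral correlation matrix of an ensemble
#'
#' Per neuron, a state-response profile is built for every state (default:
#' the onset-aligned 8 s event-average trace; alternatively the concatenated
#' raw dF/F segments, truncated to the shortest state); the matrix of
#' pairwise Pearson correlations between state profiles is computed per
#' neuron and averaged over the ensemble. Zero-variance profiles give NA
#' entries.
#'
#' @param dff a [dff_matrix()].
#' @param session a `behavior_session`.
#' @param neurons indices of the ensemble (default all).
#' @param states event types to include (default all five).
#' @param profile `"event_average"` (default) or `"segments"`.
#' @return states x states symmetric matrix with unit diagonal.
#' @export
behavior_correlation_matrix <- function(dff, session, neurons = NULL,
                                        states = EVENT_TYPES,
                                        profile = c("event_average",
                                                    "segments")) {
  profile <- match.arg(profile)
  neurons <- neurons %||% seq_len(nrow(dff$C))
  stopifnot(length(states) >= 2)
  rate <- 1 / stats::median(diff(dff$timestamps))
  acc <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
  cnt <- matrix(0, length(states), length(states))
  for (i in neurons) {
    profs <- lapply(states, function(e) {
      if (profile == "event_average") {
        s <- EVENT_STAGES[[e]]
        ea <- event_average_trace(dff$C[i, ], session$B[, e],
                                  stage_ne_vector(session, s), rate,
                                  mode = "onset")
        if (ea$n_events == 0) NULL else ea$mean
      } else {
        dff$C[i, session$B[, e] == 1]
      }
    })
    if (profile == "segments") {
      len <- min(vapply(profs, length, integer(1)))
      if (len < 3) next
      profs <- lapply(profs, function(p) p[seq_len(len)])
    }
    for (a in seq_along(states)) for (b in seq_along(states)) {
      pa <- profs[[a]]; pb <- profs[[b]]
      if (is.null(pa) || is.null(pb)) next
      if (stats::sd(pa) == 0 || stats::sd(pb) == 0) next
      acc[a, b] <- acc[a, b] + stats::cor(pa, pb)
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  diag(out) <- 1
  out
}
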