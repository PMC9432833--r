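# Behavior: trajectory smoothing, distance-threshold epoching, alignment of
# the 30 Hz behavior clock onto the imaging clock, occupancy summaries.
#
# Conventions used throughout the package:
#   * imaging frames are 0-based; an epoch covers the half-open frame
#     interval [start_frame, end_frame);
#   * epoch times are seconds on the shared session clock; a frame belongs to
#     an epoch iff its timestamp lies in [start_time, end_time).

#' Construct a trajectory table
#'
#' @param t time in seconds (strictly increasing, ~30 Hz).
#' @param x,y head coordinates in cm.
#' @return a `data.frame` with class `trajectory`.
#' @export
trajectory <- function(t, x, y) {
  stopifnot(length(t) == length(x), length(t) == length(y))
  if (any(diff(t) <= 0)) stop("trajectory timestamps must be strictly increasing")
  out <- data.frame(t = t, x = x, y = y)
  class(out) <- c("trajectory", "data.frame")
  out
}

#' Running-median smoothing of a trajectory
#'
#' Coordinatewise running median with an odd window; endpoints are handled by
#' shrinking the window (`stats::runmed(endrule = "median")`). Timestamps are
#' unchanged.
#'
#' @param traj a [trajectory()].
#' @param window odd window length in behavior frames (default 5).
#' @return smoothed trajectory.
#' @export
smooth_trajectory <- function(traj, window = 5L) {
  window <- as.integer(window)
  stopifnot(window >= 1L, window %% 2L == 1L)
  if (window > nrow(traj)) stop("median window larger than trajectory")
  if (window == 1L) return(traj)
  out <- traj
  out$x <- as.numeric(stats::runmed(traj$x, window, endrule = "median"))
  out$y <- as.numeric(stats::runmed(traj$y, window, endrule = "median"))
  out
}

#' Detect direct-exploration epochs by distance thresholding
#'
#' Maximal runs of behavior frames whose Euclidean head-to-target distance is
#' below `distance_threshold` and whose duration is at least `min_duration`
#' become epochs. No gap merging is performed: a single above-threshold frame
#' splits a run in two.
#'
#' @param traj a [trajectory()] (smooth it first).
#' @param target_xy numeric length-2, target center (cm).
#' @param distance_threshold cm (default 3); an automated proxy for
#'   mouth-to-mouth contact.
#' @param min_duration seconds (default 0.5).
#' @param event_type label to assign to the detected epochs.
#' @return a `data.frame` (event, start_time, end_time, duration) plus a
#'   `distance` attribute holding the per-frame distance trace.
#' @export
detect_epochs <- function(traj, target_xy, distance_threshold = 3,
                          min_duration = 0.5, event_type = "mouse") {
  stopifnot(distance_threshold > 0, length(target_xy) == 2)
  d <- sqrt((traj$x - target_xy[1])^2 + (traj$y - target_xy[2])^2)
  below <- d < distance_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  rows <- list()
  dt <- if (nrow(traj) > 1) stats::median(diff(traj$t)) else 0
  for (j in keep) {
    i0 <- starts[j]; i1 <- ends[j]
    t0 <- traj$t[i0]
    # half-open: epoch ends where the next (above-threshold) frame begins
    t1 <- if (i1 < nrow(traj)) traj$t[i1 + 1L] else traj$t[i1] + dt
    if (t1 - t0 >= min_duration) {
      rows[[length(rows) + 1L]] <-
        data.frame(event = event_type, start_time = t0, end_time = t1,
                   duration = t1 - t0, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event = character(), start_time = numeric(),
               end_time = numeric(), duration = numeric())
  attr(out, "distance") <- d
  out
}

#' Binary behavior vector on the imaging timebase
#'
#' A frame is active iff its timestamp falls in some epoch's
#' `[start_time, end_time)` interval.
#'
#' @param epochs epoch table with `start_time`/`end_time` columns.
#' @param timestamps imaging frame timestamps (s).
#' @return integer 0/1 vector, one entry per imaging frame.
#' @export
epochs_to_vector <- function(epochs, timestamps) {
  b <- integer(length(timestamps))
  if (nrow(epochs) == 0) return(b)
  for (i in seq_len(nrow(epochs))) {
    b[timestamps >= epochs$start_time[i] & timestamps < epochs$end_time[i]] <- 1L
  }
  b
}

#' Recover epochs (frame intervals) from a binary vector
#'
#' Inverse of [epochs_to_vector()] up to one imaging frame per boundary.
#'
#' @param b 0/1 vector on the imaging timebase.
#' @param timestamps imaging timestamps (s).
#' @param event_type epoch label.
#' @return epoch table with 0-based half-open frame intervals and times.
#' @export
vector_to_epochs <- function(b, timestamps, event_type = "event") {
  r <- rle(as.integer(b) != 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  n <- length(timestamps)
  dt <- if (n > 1) stats::median(diff(timestamps)) else 0
  out <- data.frame(
    event = rep(event_type, length(keep)),
    start_frame = starts[keep] - 1L,
    end_frame = ends[keep],
    start_time = timestamps[starts[keep]],
    end_time = ifelse(ends[keep] < n, timestamps[pmin(ends[keep] + 1L, n)],
                      timestamps[n] + dt),
    stringsAsFactors = FALSE
  )
  out$end_time <- ifelse(out$end_frame < n, timestamps[out$end_frame + 1L],
                         timestamps[n] + dt)
  out
}

#' Align a behavior-clock vector to the imaging clock
#'
#' Each imaging frame takes the label of the nearest behavior timestamp
#' (ties to the earlier stamp); reports the mean and SD of the absolute
#' clock mismatch of matched stamps.
#'
#' @param values vector sampled on the behavior clock.
#' @param behavior_t behavior timestamps (s), increasing.
#' @param imaging_t imaging timestamps (s), increasing.
#' @return list with `values` (length of `imaging_t`), `mean_dt`, `sd_dt`,
#'   `max_dt` (seconds).
#' @export
align_to_imaging <- function(values, behavior_t, imaging_t) {
  stopifnot(length(values) == length(behavior_t))
  if (max(behavior_t) < min(imaging_t) || min(behavior_t) > max(imaging_t))
    stop("behavior and imaging clocks do not overlap")
  idx <- findInterval(imaging_t, behavior_t, all.inside = FALSE)
  idx[idx < 1L] <- 1L
  nb <- length(behavior_t)
  use_next <- idx < nb &
    (imaging_t - behavior_t[idx]) > (behavior_t[pmin(idx + 1L, nb)] - imaging_t)
  idx[use_next] <- idx[use_next] + 1L
  dt <- abs(imaging_t - behavior_t[idx])
  list(values = values[idx], mean_dt = mean(dt), sd_dt = stats::sd(dt),
       max_dt = max(dt))
}

#' Direct-exploration time ratio between the two targets
#'
#' Fraction of the total direct-exploration time (summed over both targets)
#' spent on each side; the two ratios sum to 1. With
#' `denominator = "session"` the session duration is the denominator instead.
#'
#' @param time_a,time_b total exploration seconds for each side (or epoch
#'   tables, whose `duration` column is summed).
#' @param denominator "targets" (default) or "session".
#' @param session_duration required when `denominator = "session"`.
#' @return named numeric of length 2 (`a`, `b`); NaNs with a warning if no
#'   exploration at all.
#' @export
exploration_ratio <- function(time_a, time_b, denominator = c("targets", "session"),
                              session_duration = NULL) {
  denominator <- match.arg(denominator)
  if (is.data.frame(time_a)) time_a <- sum(time_a$duration)
  if (is.data.frame(time_b)) time_b <- sum(time_b$duration)
  tot <- time_a + time_b
  if (tot <= 0) {
    warning("no direct exploration: ratio undefined")
    return(c(a = NaN, b = NaN))
  }
  den <- if (denominator == "session") {
    stopifnot(!is.null(session_duration), session_duration > 0)
    session_duration
  } else tot
  c(a = time_a / den, b = time_b / den)
}
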