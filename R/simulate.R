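# Synthetic sessions with planted ground truth: behavior epochs across the
# three-stage paradigm, dF/F matrices with planted tuning classes, and
# rendered fluorescence videos (soma + annulus + shared neuropil).

PLANTED_CLASSES <- c("SAN", "SIN", "CageN", "ON", "MN", "NewN", "OldN",
                     "NewPN", "OldPN", "null")

# which event types each planted class responds to; SIN is handled separately
# (tonic baseline suppressed during social epochs); non-preferred classes
# respond to several event types, preferred classes to exactly one.
CLASS_RESPONDS <- list(
  SAN   = c("mouse", "new", "old"),
  SIN   = character(),
  CageN = "cage",
  ON    = "object",
  MN    = "mouse",
  NewN  = c("new", "mouse"),
  OldN  = c("old", "mouse"),
  NewPN = "new",
  OldPN = "old",
  null  = character()
)

#' Simulation configuration
#'
#' Defaults mirror the recording setup the package targets: 512 px frames at
#' 9.76 Hz (FOV 420 um), 30 Hz behavior video, and three 5-min stages
#' (habituation / sociability / social novelty).
#'
#' @param imaging_rate imaging frame rate, Hz.
#' @param behavior_rate behavior video rate, Hz.
#' @param stage_durations seconds per stage, length 3.
#' @param n_neurons total simulated neurons.
#' @param class_counts named counts of planted classes (subset of
#'   `SAN, SIN, CageN, ON, MN, NewN, OldN, NewPN, OldPN, null`); any
#'   remainder is filled with nulls.
#' @param response_gain transient peak amplitude, dF/F units.
#' @param response_prob per-epoch Bernoulli probability that a responsive
#'   neuron emits a transient.
#' @param kernel_rise,kernel_decay GCaMP6s-like double-exponential kinetics, s.
#' @param baseline_level tonic dF/F level of ordinary neurons.
#' @param sin_baseline elevated tonic level of SINs (suppressed during social
#'   epochs).
#' @param baseline_noise_sd white-noise SD, dF/F units.
#' @param epoch_rate direct-exploration epochs per minute per event type.
#' @param epoch_duration_range epoch duration bounds, s.
#' @param epoch_min_gap minimum gap between epochs in a stage, s.
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @return a `sim_config` list.
#' @export
sim_config <- function(imaging_rate = 9.76, behavior_rate = 30,
                       stage_durations = c(300, 300, 300),
                       n_neurons = 120,
                       class_counts = c(SAN = 20, SIN = 20, NewPN = 20,
                                        OldPN = 20, null = 40),
                       response_gain = 1.0, response_prob = 0.7,
                       kernel_rise = 0.2, kernel_decay = 1.8,
                       baseline_level = 0.2, sin_baseline = 1.0,
                       baseline_noise_sd = 0.2,
                       epoch_rate = 2, epoch_duration_range = c(2, 8),
                       epoch_min_gap = 1, seed = 1L) {
  stopifnot(imaging_rate > 0, behavior_rate > 0, all(stage_durations > 0),
            length(stage_durations) == 3, n_neurons >= 1,
            all(epoch_duration_range > 0), length(epoch_duration_range) == 2,
            epoch_duration_range[1] <= epoch_duration_range[2],
            epoch_rate >= 0, epoch_min_gap >= 0,
            response_gain >= 0, response_prob >= 0, response_prob <= 1,
            kernel_rise > 0, kernel_decay > 0, baseline_noise_sd >= 0)
  if (is.list(class_counts)) class_counts <- unlist(class_counts)
  if (length(class_counts)) {
    stopifnot(!is.null(names(class_counts)),
              all(names(class_counts) %in% PLANTED_CLASSES))
    if (sum(class_counts) > n_neurons)
      stop("class counts sum exceeds n_neurons")
  }
  names(stage_durations) <- STAGES
  cfg <- list(imaging_rate = imaging_rate, behavior_rate = behavior_rate,
              stage_durations = stage_durations, n_neurons = n_neurons,
              class_counts = class_counts, response_gain = response_gain,
              response_prob = response_prob, kernel_rise = kernel_rise,
              kernel_decay = kernel_decay, baseline_level = baseline_level,
              sin_baseline = sin_baseline,
              baseline_noise_sd = baseline_noise_sd, epoch_rate = epoch_rate,
              epoch_duration_range = epoch_duration_range,
              epoch_min_gap = epoch_min_gap, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# sequential epoch placement inside one stage: durations drawn first, the
# remaining slack split over the gaps; deterministic feasibility check.
place_epochs <- function(events_per_type, stage_start, stage_dur, dur_range,
                         min_gap) {
  n <- sum(events_per_type)
  if (n == 0) return(NULL)
  durs <- runif(n, dur_range[1], dur_range[2])
  slack <- stage_dur - sum(durs) - n * min_gap
  if (slack < 0)
    stop("stage too short to place requested epochs (need ",
         round(sum(durs) + n * min_gap, 1), " s, have ", stage_dur, " s)")
  w <- runif(n + 1)
  extra <- slack * w / sum(w)
  types <- sample(rep(names(events_per_type), events_per_type))
  starts <- numeric(n)
  t <- stage_start + extra[1]
  for (i in seq_len(n)) {
    starts[i] <- t
    t <- t + durs[i] + min_gap + extra[i + 1]
  }
  data.frame(event = types, start_time = starts, end_time = starts + durs,
             stringsAsFactors = FALSE)
}

#' Simulate a three-stage behavior session
#'
#' Places direct-exploration epochs (cage epochs in habituation, object/mouse
#' in sociability, new/old in the novelty stage), builds binary behavior
#' vectors on the imaging timebase, and synthesizes a matching 30 Hz head
#' trajectory: an Ornstein-Uhlenbeck walk around the arena center pulled onto
#' the active target (within contact radius) during each epoch.
#'
#' @param config a [sim_config()].
#' @param seed overrides `config$seed`.
#' @return a `behavior_session`: list with `timestamps`, `stage` (per frame),
#'   `B` (frames x 5 binary matrix, one column per event type), `B_NE`,
#'   `epochs` (table with frames and times), `trajectory`, `targets`,
#'   `config`.
#' @export
simulate_behavior <- function(config, seed = config$seed) {
  set.seed(seed)
  fs <- config$imaging_rate
  stage_ends <- cumsum(config$stage_durations)
  stage_starts <- c(0, stage_ends[-3])
  total <- stage_ends[3]
  timestamps <- seq(0, by = 1 / fs, length.out = floor(total * fs))
  stage <- STAGES[findInterval(timestamps, stage_ends) + 1L]

  epochs <- list()
  for (s in seq_along(STAGES)) {
    types <- EVENT_TYPES[EVENT_STAGES == STAGES[s]]
    counts <- vapply(types, function(ty)
      max(0L, as.integer(round(config$epoch_rate * config$stage_durations[s] / 60))),
      integer(1))
    ep <- place_epochs(counts, stage_starts[s], config$stage_durations[s],
                       config$epoch_duration_range, config$epoch_min_gap)
    if (!is.null(ep)) { ep$stage <- STAGES[s]; epochs[[s]] <- ep }
  }
  epochs <- if (length(epochs)) do.call(rbind, epochs) else
    data.frame(event = character(), start_time = numeric(),
               end_time = numeric(), stage = character())
  if (nrow(epochs)) {
    epochs$start_frame <- findInterval(epochs$start_time - 1e-9, timestamps)
    epochs$end_frame <- findInterval(epochs$end_time - 1e-9, timestamps)
    epochs$duration <- epochs$end_time - epochs$start_time
    epochs <- epochs[order(epochs$start_time), ]
    rownames(epochs) <- NULL
    epochs$epoch_id <- seq_len(nrow(epochs))
  }

  B <- sapply(EVENT_TYPES, function(ty)
    epochs_to_vector(epochs[epochs$event == ty, , drop = FALSE], timestamps))
  if (is.null(dim(B))) B <- matrix(B, nrow = length(timestamps),
                                   dimnames = list(NULL, EVENT_TYPES))
  b_ne <- as.integer(rowSums(B) == 0)

  # arena: two 28 x 24 cm chambers side by side; targets at chamber centers
  targets <- list(cage = c(10, 12), object = c(46, 12), mouse = c(10, 12),
                  new = c(46, 12), old = c(10, 12))
  bt <- seq(0, by = 1 / config$behavior_rate, length.out = floor(total * config$behavior_rate))
  x <- numeric(length(bt)); y <- numeric(length(bt))
  x[1] <- 28; y[1] <- 12
  dt <- 1 / config$behavior_rate
  theta <- 0.8; sig <- 6
  active_tgt <- matrix(NA_real_, length(bt), 2)
  if (nrow(epochs)) {
    for (i in seq_len(nrow(epochs))) {
      sel <- bt >= epochs$start_time[i] & bt < epochs$end_time[i]
      tg <- targets[[epochs$event[i]]]
      active_tgt[sel, 1] <- tg[1]; active_tgt[sel, 2] <- tg[2]
    }
  }
  contact_r <- 1.2
  nse <- matrix(rnorm(2 * length(bt)), ncol = 2)
  for (i in seq_len(length(bt))[-1]) {
    if (!is.na(active_tgt[i, 1])) {
      ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, contact_r)
      x[i] <- active_tgt[i, 1] + rad * cos(ang)
      y[i] <- active_tgt[i, 2] + rad * sin(ang)
    } else {
      x[i] <- x[i - 1] + theta * (28 - x[i - 1]) * dt + sig * sqrt(dt) * nse[i, 1]
      y[i] <- y[i - 1] + theta * (12 - y[i - 1]) * dt + sig * sqrt(dt) * nse[i, 2]
      x[i] <- min(max(x[i], 0), 56); y[i] <- min(max(y[i], 0), 24)
    }
  }

  out <- list(timestamps = timestamps, stage = stage, B = B, B_NE = b_ne,
              epochs = epochs, trajectory = trajectory(bt, x, y),
              targets = targets, config = config)
  class(out) <- "behavior_session"
  out
}

#' Social behavior vector of a session
#'
#' Union of the social event vectors (default: mouse, new, old) — the binary
#' vector the SAN/SIN permutation test is run against.
#'
#' @param session a `behavior_session`.
#' @param events event types counted as social.
#' @return integer 0/1 vector on the imaging timebase.
#' @export
social_vector <- function(session, events = c("mouse", "new", "old")) {
  as.integer(rowSums(session$B[, events, drop = FALSE]) > 0)
}

#' Simulate a dF/F matrix with planted tuning classes
#'
#' Each responsive neuron emits, with probability `response_prob` per epoch of
#' its trigger event types, a transient `gain * k(t)` where `k` is a unit-peak
#' double-exponential kernel. SINs carry an elevated tonic level that is
#' suppressed (by a kernel-smoothed step of depth `gain`) during social
#' epochs; nulls are baseline + noise.
#'
#' @param config a [sim_config()].
#' @param session output of [simulate_behavior()].
#' @param seed overrides `config$seed` (offset internally so behavior and
#'   dF/F draws do not collide).
#' @return list with `dff` (a `dff_matrix`: `C` neurons x frames,
#'   `timestamps`) and `truth` (per-neuron `class`, `responds_to`, kernel
#'   parameters, and per-epoch `activations` table).
#' @export
simulate_dff <- function(config, session, seed = config$seed) {
  set.seed(child_seed(seed, 2))
  n <- config$n_neurons
  tt <- session$timestamps
  nt <- length(tt)
  cls <- rep("null", n)
  if (length(config$class_counts)) {
    idx <- 1L
    for (nm in names(config$class_counts)) {
      cnt <- config$class_counts[[nm]]
      if (cnt > 0) { cls[idx:(idx + cnt - 1L)] <- nm; idx <- idx + cnt }
    }
  }
  kern <- calcium_kernel(config$imaging_rate, config$kernel_rise,
                         config$kernel_decay)
  kstep <- kern / sum(kern)   # unit-gain step response for SIN suppression
  # analytic peak value, so transients are normalized to peak = gain even
  # though they are sampled at the (arbitrary) epoch-onset phase
  tpk <- kernel_time_to_peak(config$kernel_rise, config$kernel_decay)
  kpeak <- (1 - exp(-tpk / config$kernel_rise)) * exp(-tpk / config$kernel_decay)
  b_social <- social_vector(session)
  suppress <- stats::convolve(b_social, rev(kstep), type = "open")[seq_len(nt)]
  suppress <- pmin(pmax(suppress, 0), 1)

  C <- matrix(rnorm(n * nt, sd = config$baseline_noise_sd), nrow = n)
  ep <- session$epochs
  acts <- list()
  for (i in seq_len(n)) {
    base <- if (cls[i] == "SIN") config$sin_baseline else config$baseline_level
    C[i, ] <- C[i, ] + base
    if (cls[i] == "SIN") {
      C[i, ] <- C[i, ] - config$response_gain * suppress
      next
    }
    trig <- CLASS_RESPONDS[[cls[i]]]
    if (!length(trig) || !nrow(ep)) next
    rows <- which(ep$event %in% trig)
    for (r in rows) {
      on <- runif(1) < config$response_prob
      acts[[length(acts) + 1L]] <- data.frame(
        neuron = i, epoch_id = ep$epoch_id[r], event = ep$event[r],
        activated = on)
      if (!on) next
      f0 <- ep$start_frame[r] + 1L            # 0-based -> R index
      len <- min(length(kern), nt - f0 + 1L)
      if (len > 0) {
        sel <- f0:(f0 + len - 1L)
        # kernel starts at the behavioral onset, sampled on the imaging grid
        koff <- tt[sel] - ep$start_time[r]
        resp <- (1 - exp(-koff / config$kernel_rise)) *
          exp(-koff / config$kernel_decay) / kpeak
        C[i, sel] <- C[i, sel] + config$response_gain * resp
      }
    }
  }
  activations <- if (length(acts)) do.call(rbind, acts) else
    data.frame(neuron = integer(), epoch_id = integer(),
               event = character(), activated = logical())
  dff <- dff_matrix(C, tt)
  truth <- list(class = cls, responds_to = CLASS_RESPONDS[cls],
                kernel_rise = config$kernel_rise,
                kernel_decay = config$kernel_decay,
                response_prob = config$response_prob,
                activations = activations)
  list(dff = dff, truth = truth)
}

#' Regular soma layout for rendered videos
#'
#' Disk somata on a jittered grid; guaranteed non-overlapping (the grid pitch
#' exceeds two radii plus the jitter).
#'
#' @param n number of somata.
#' @param dim frame size `c(H, W)` in px.
#' @param radius soma radius, px.
#' @param margin border kept free, px.
#' @param seed RNG seed for the jitter.
#' @return a `soma_layout`: list with `dim`, `centers` (n x 2, row/col),
#'   `radius`.
#' @export
soma_layout <- function(n, dim = c(128, 128), radius = 4, margin = 10,
                        seed = 1L) {
  set.seed(seed)
  k <- ceiling(sqrt(n))
  pitch_r <- (dim[1] - 2 * margin) / k
  pitch_c <- (dim[2] - 2 * margin) / k
  jmax <- pmax(0, (min(pitch_r, pitch_c) - 2 * radius - 2) / 2)
  cells <- expand.grid(r = seq_len(k), c = seq_len(k))[seq_len(n), ]
  centers <- cbind(
    margin + (cells$r - 0.5) * pitch_r + runif(n, -jmax, jmax),
    margin + (cells$c - 0.5) * pitch_c + runif(n, -jmax, jmax))
  out <- list(dim = dim, centers = centers, radius = radius)
  class(out) <- "soma_layout"
  out
}

disk_pixels <- function(center, radius, dim) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(dim[1], ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(dim[2], ceiling(center[2] + radius))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  g <- g[(g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2, ]
  g$r + (g$c - 1L) * dim[1]              # linear indices, column-major
}

#' Render a fluorescence video from planted dF/F traces
#'
#' Pixel model: `offset + soma * f0 * dff_i(t) + neuropil_gain * f0 *
#' field(x, y) * p(t) + noise`, where `field` is a smooth spatial neuropil
#' field and `p(t)` a slow shared temporal trace; the result is clamped at 0.
#'
#' @param dff a `dff_matrix` (neurons x frames) of planted traces.
#' @param layout a [soma_layout()] with one soma per neuron; overlapping
#'   somata are an error (ground truth must stay identifiable).
#' @param neuropil_gain relative strength of the shared neuropil field.
#' @param noise_sd pixel noise SD in dF/F units (scaled by `f0`).
#' @param seed RNG seed.
#' @param f0 baseline intensity scale (counts per unit dF/F).
#' @param offset camera offset, counts.
#' @return list with `video` (H x W x T array), `masks` (per-neuron linear
#'   pixel indices), `layout`, `field`, `np_trace`, `f0`, `offset`.
#' @export
render_video <- function(dff, layout, neuropil_gain = 1, noise_sd = 0.03,
                         seed = 1L, f0 = 1000, offset = 100) {
  set.seed(child_seed(seed, 3))
  C <- dff$C
  n <- nrow(C); nt <- ncol(C)
  stopifnot(n == nrow(layout$centers))
  d <- as.matrix(stats::dist(layout$centers))
  diag(d) <- Inf
  if (any(d <= 2 * layout$radius))
    stop("overlapping somata in layout")
  H <- layout$dim[1]; W <- layout$dim[2]
  masks <- lapply(seq_len(n), function(i)
    disk_pixels(layout$centers[i, ], layout$radius, layout$dim))
  if (anyDuplicated(unlist(masks)))
    stop("overlapping somata in layout")

  rr <- matrix(seq_len(H), H, W); cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  ph <- runif(2, 0, 2 * pi)
  field <- 0.6 + 0.2 * cos(2 * pi * rr / H + ph[1]) +
    0.2 * cos(2 * pi * cc / W + ph[2])
  field <- 0.2 + 0.8 * (field - min(field)) / (max(field) - min(field))

  # slow shared neuropil trace: OU with tau ~2 s around 1, kept nonnegative
  np <- numeric(nt); np[1] <- 1
  a <- exp(-1 / (2 * 9.76)); s <- 0.3 * sqrt(1 - a^2)
  eps <- rnorm(nt, sd = s)
  for (t in 2:max(nt, 2)) np[t] <- 1 + a * (np[t - 1] - 1) + eps[t]
  np <- pmax(np, 0)

  vid <- matrix(offset, H * W, nt)
  if (neuropil_gain > 0)
    vid <- vid + neuropil_gain * f0 * outer(as.vector(field), np)
  for (i in seq_len(n))
    vid[masks[[i]], ] <- vid[masks[[i]], ] +
      matrix(f0 * C[i, ], length(masks[[i]]), nt, byrow = TRUE)
  if (noise_sd > 0)
    vid <- vid + matrix(rnorm(length(vid), sd = noise_sd * f0), nrow(vid))
  vid[vid < 0] <- 0
  dim(vid) <- c(H, W, nt)
  list(video = vid, masks = masks, layout = layout, field = field,
       np_trace = np, f0 = f0, offset = offset)
}
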