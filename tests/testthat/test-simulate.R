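# synthetic_data: behavior sessions, dF/F with planted classes, rendering.

test_that("behavior vectors partition the session and respect stages", {
  s <- FIX_SESSION
  # every frame is either NE or in >= 1 event
  expect_true(all(s$B_NE + as.integer(rowSums(s$B) > 0) == 1L))
  # events stay inside their stage
  for (e in EVENT_TYPES) {
    on <- which(s$B[, e] == 1L)
    if (length(on)) expect_true(all(s$stage[on] == EVENT_STAGES[[e]]))
  }
  # epochs of one type are sorted and non-overlapping
  for (e in EVENT_TYPES) {
    ep <- s$epochs[s$epochs$event == e, ]
    if (nrow(ep) > 1) {
      expect_true(all(diff(ep$start_time) > 0))
      expect_true(all(ep$start_time[-1] >= ep$end_time[-nrow(ep)]))
    }
  }
})

test_that("epoch_rate = 0 gives an all-NE session", {
  cfg <- sim_config(stage_durations = c(30, 30, 30), n_neurons = 2,
                    class_counts = c(null = 2), epoch_rate = 0, seed = 1)
  s <- simulate_behavior(cfg)
  expect_equal(nrow(s$epochs), 0L)
  expect_true(all(s$B == 0L))
  expect_true(all(s$B_NE == 1L))
})

test_that("frame counts of planted epochs match a direct frame-count oracle", {
  # 10 mouse epochs of exactly 5 s: oracle counts frames in [start, start+5)
  rate <- 9.76
  nt <- 3000L
  tt <- (seq_len(nt) - 1) / rate
  starts <- seq(10, by = 28, length.out = 10)
  ep <- mk_epochs(starts, starts + 5)
  b <- epochs_to_vector(ep, tt)
  oracle <- sum(vapply(starts, function(s0)
    sum(tt >= s0 & tt < s0 + 5), numeric(1)))
  expect_equal(sum(b), oracle)
  expect_lte(abs(sum(b) - 10 * 5 * rate), 10)  # <= 1 frame per epoch
})

test_that("sessions, matrices and videos are deterministic under the seed", {
  cfg <- small_config()
  s1 <- simulate_behavior(cfg); s2 <- simulate_behavior(cfg)
  expect_identical(s1$epochs, s2$epochs)
  expect_identical(s1$trajectory, s2$trajectory)
  d1 <- simulate_dff(cfg, s1); d2 <- simulate_dff(cfg, s2)
  expect_identical(d1$dff$C, d2$dff$C)
  lay <- soma_layout(4, dim = c(48, 48), radius = 3, seed = 5)
  sub <- dff_matrix(d1$dff$C[1:4, 1:200], d1$dff$timestamps[1:200])
  v1 <- render_video(sub, lay, 0.5, 0.02, seed = 9)
  v2 <- render_video(sub, lay, 0.5, 0.02, seed = 9)
  expect_identical(v1$video, v2$video)
})

test_that("stage too short to hold the requested epochs is an error", {
  cfg <- sim_config(stage_durations = c(10, 300, 300), n_neurons = 2,
                    class_counts = c(null = 2), epoch_rate = 20,
                    epoch_duration_range = c(4, 6), seed = 1)
  expect_error(simulate_behavior(cfg), "too short")
})

test_that("all-null, zero-noise dF/F is a constant matrix", {
  cfg <- sim_config(stage_durations = c(30, 30, 30), n_neurons = 3,
                    class_counts = c(null = 3), baseline_noise_sd = 0,
                    seed = 2)
  s <- simulate_behavior(cfg)
  d <- simulate_dff(cfg, s)
  expect_true(all(d$dff$C == cfg$baseline_level))
})

test_that("planted SAN state contrast matches an explicit convolution oracle", {
  cfg <- sim_config(stage_durations = c(60, 60, 60), n_neurons = 1,
                    class_counts = c(SAN = 1), baseline_noise_sd = 0,
                    response_prob = 1, response_gain = 2, seed = 11)
  s <- simulate_behavior(cfg)
  d <- simulate_dff(cfg, s)
  # oracle: rebuild the trace by explicit kernel evaluation at social onsets
  r0 <- cfg$kernel_rise; d0 <- cfg$kernel_decay
  tpk <- r0 * log((r0 + d0) / r0)
  kpeak <- (1 - exp(-tpk / r0)) * exp(-tpk / d0)
  klen <- length(seq(0, d0 * 5, by = 1 / cfg$imaging_rate))
  nt <- length(s$timestamps)
  tt <- s$timestamps
  oracle <- rep(cfg$baseline_level, nt)
  ep <- s$epochs[s$epochs$event %in% c("mouse", "new", "old"), ]
  for (i in seq_len(nrow(ep))) {
    f0 <- ep$start_frame[i] + 1L
    len <- min(klen, nt - f0 + 1L)
    sel <- f0:(f0 + len - 1L)
    koff <- tt[sel] - ep$start_time[i]
    oracle[sel] <- oracle[sel] + cfg$response_gain *
      (1 - exp(-koff / r0)) * exp(-koff / d0) / kpeak
  }
  expect_equal(d$dff$C[1, ], oracle, tolerance = 1e-12)
  # and the social-vs-NE mean contrast equals the oracle's contrast
  b <- social_vector(s)
  got <- mean(d$dff$C[1, b == 1]) - mean(d$dff$C[1, b == 0])
  want <- mean(oracle[b == 1]) - mean(oracle[b == 0])
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("rendering respects its trivial contracts", {
  lay <- soma_layout(2, dim = c(40, 40), radius = 3, seed = 1)
  tt <- (0:99) / 9.76
  # all-zero dff: video is offset + neuropil + noise only (here both off)
  z <- dff_matrix(matrix(0, 2, 100), tt)
  rv <- render_video(z, lay, neuropil_gain = 0, noise_sd = 0, seed = 1)
  expect_true(all(rv$video == rv$offset))
  # single soma, no neuropil, no noise: ARS recovers the planted trace
  # exactly up to the F_0 = mean(F_ROI) scaling
  tr <- 0.2 + 0.8 * (sin(tt) > 0.5)
  one <- dff_matrix(matrix(tr, 1, 100), tt)
  lay1 <- soma_layout(1, dim = c(40, 40), radius = 3, seed = 1)
  rv1 <- render_video(one, lay1, neuropil_gain = 0, noise_sd = 0, seed = 1)
  rois <- roi_set(rv1$masks, dim = c(40, 40))
  got <- ars_dff(extract_traces(rv1$video, rois)[[1]])
  expect_equal(got, tr / mean(tr), tolerance = 1e-6)
})

test_that("ring-mean trace tracks the planted neuropil field when gain > 0", {
  lay <- soma_layout(3, dim = c(48, 48), radius = 3, seed = 2)
  tt <- (0:299) / 9.76
  z <- dff_matrix(matrix(0.2, 3, 300), tt)
  rv <- render_video(z, lay, neuropil_gain = 1, noise_sd = 0.005, seed = 4)
  rois <- roi_set(rv$masks, dim = c(48, 48))
  ring_tr <- colMeans(matrix(rv$video, 48 * 48, 300)[rois$rings[[1]], ])
  expect_gt(cor(ring_tr, rv$np_trace), 0.99)
})

test_that("overlapping somata are rejected", {
  lay <- soma_layout(2, dim = c(40, 40), radius = 3, seed = 1)
  lay$centers[2, ] <- lay$centers[1, ] + c(2, 0)
  z <- dff_matrix(matrix(0, 2, 10), (0:9) / 9.76)
  expect_error(render_video(z, lay, 0, 0, seed = 1), "overlap")
})
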