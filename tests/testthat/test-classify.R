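# classify: similarity statistic, permutation null, thresholds, event
# averages, noise, engagement.

test_that("similarity closed forms hold", {
  B <- c(1, 1, 0, 0, 1, 0)
  expect_equal(similarity(B, B), 0.5)
  expect_equal(similarity(c(1, 1, 0, 0), c(0, 0, 2, 3)), 0)
  expect_equal(similarity(c(1, 1, 0, 0), c(2, 0, 0, 0)), 1 / 3)
  expect_error(similarity(c(0, 0), c(0, 0)), "zero")
  # symmetric in its arguments and invariant under a joint permutation
  set.seed(2)
  for (i in 1:20) {
    b <- rbinom(50, 1, 0.3); x <- rnorm(50)
    expect_equal(similarity(b, x), similarity(x, b))
    p <- sample(50)
    expect_equal(similarity(b[p], x[p]), similarity(b, x))
  }
})

test_that("permutation_null degenerates correctly and is reproducible", {
  B <- rbinom(100, 1, 0.4)
  expect_equal(permutation_null(B, rep(2, 100), k = 50),
               rep(similarity(B, rep(2, 100)), 50))
  x <- rnorm(100)
  expect_equal(permutation_null(rep(1, 100), x, k = 50),
               rep(similarity(rep(1, 100), x), 50))
  set.seed(9); a <- permutation_null(B, x, k = 100)
  set.seed(9); b <- permutation_null(B, x, k = 100)
  expect_identical(a, b)
  # binary shortcut agrees with the general shuffle path in distribution
  set.seed(4)
  fast <- permutation_null(B, x, k = 4000)
  set.seed(4)
  slow <- socens:::perm_null_dot_full(as.numeric(B), x, 4000L) /
    (sum(B^2) + sum(x^2))
  expect_lt(abs(mean(fast) - mean(slow)), 3 * sd(slow) / sqrt(4000) * 2)
  expect_lt(abs(sd(fast) - sd(slow)) / sd(slow), 0.1)
})

test_that("classification thresholds are strict percentiles", {
  # tie with every null sample -> Other
  expect_equal(classify_neuron(1, rep(1, 100))$label, "Other")
  expect_equal(classify_neuron(2, rep(1, 100))$label, "SAN")
  expect_equal(classify_neuron(0.5, rep(1, 100))$label, "SIN")
  # interpolated percentile oracle: null = 1..1000
  cl <- classify_neuron(995, 1:1000)
  expect_equal(cl$thr_hi, quantile(1:1000, 0.9917, names = FALSE))
  expect_equal(cl$thr_hi, 1 + 0.9917 * 999, tolerance = 1e-9)
  expect_equal(cl$label, "SAN")
  expect_equal(classify_neuron(990, 1:1000)$label, "Other")
})

test_that("planted SAN reaches small empirical p-values at high gain", {
  cfg <- sim_config(stage_durations = c(60, 60, 60), n_neurons = 1,
                    class_counts = c(SAN = 1), response_gain = 1,
                    baseline_noise_sd = 0.2, response_prob = 1, seed = 31)
  s <- simulate_behavior(cfg)
  b <- social_vector(s)
  hits <- 0L
  for (sd_i in 1:10) {
    d <- simulate_dff(cfg, s, seed = 1000 + sd_i)
    S <- similarity(b, d$dff$C[1, ])
    set.seed(sd_i)
    nulls <- permutation_null(b, d$dff$C[1, ], k = 1000)
    if (mean(nulls >= S) < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("ensemble signal-behavior correlation is the mean similarity", {
  expect_equal(signal_behavior_correlation(c("SAN"), 0.4), c(SAN = 0.4, SIN = NA))
  expect_equal(signal_behavior_correlation(c("SAN", "SAN", "SIN"),
                                           c(0.2, 0.4, 0.1)),
               c(SAN = 0.3, SIN = 0.1))
  r <- signal_behavior_correlation(c("Other", "SAN"), c(0.1, 0.2))
  expect_true(is.na(r[["SIN"]]))
})

test_that("event averages align valid 8 s fragments and smooth with span 5", {
  rate <- 9.76; nt <- 2000L; w <- round(4 * rate)
  b <- integer(nt)
  onsets <- c(300, 700, 1100, 1500)
  for (s0 in onsets) b[s0:(s0 + 60)] <- 1L
  ne <- 1L - b
  # constant trace -> flat average; relative variant flat at 0
  ea <- event_average_trace(rep(3, nt), b, ne, rate, "onset")
  expect_equal(ea$n_events, 4L)
  expect_equal(ea$mean, rep(3, 2 * w))
  ear <- event_average_trace(rep(3, nt), b, ne, rate, "onset", relative = TRUE)
  expect_equal(ear$mean, rep(0, 2 * w), tolerance = 1e-12)
  # deterministic square pulse locked to onsets: average equals the span-5
  # smoothed step, closed form
  x <- as.numeric(b)
  ea2 <- event_average_trace(x, b, ne, rate, "onset")
  step <- c(rep(0, w), rep(1, w))
  oracle <- rep(0, 2 * w)
  oracle[w - 1] <- 1 / 5; oracle[w] <- 2 / 5
  oracle[w + 1] <- 3 / 5; oracle[w + 2] <- 4 / 5
  oracle[(w + 3):(2 * w)] <- 1
  expect_equal(ea2$mean, oracle, tolerance = 1e-12)
  # single valid fragment equals that fragment smoothed
  b1 <- integer(nt); b1[500:580] <- 1L
  x1 <- rnorm(nt)
  ea3 <- event_average_trace(x1, b1, 1L - b1, rate, "onset")
  xs <- moving_average(x1, 5)
  expect_equal(ea3$n_events, 1L)
  expect_equal(ea3$mean, xs[(500 - w):(500 + w - 1)])
  # no valid fragment -> flagged missing
  ea4 <- event_average_trace(x1, integer(nt), rep(1L, nt), rate, "onset")
  expect_equal(ea4$n_events, 0L)
  expect_true(all(is.na(ea4$mean)))
  # relative variant: mean over the NE half is ~0 for behavior-independent noise
  set.seed(7)
  xn <- rnorm(nt, sd = 0.2)
  ea5 <- event_average_trace(xn, b, ne, rate, "onset", relative = TRUE)
  expect_lt(abs(mean(ea5$mean[1:w])), 5 * 0.2 / sqrt(4 * w))
})

test_that("offset-mode fragments mirror onset-mode", {
  rate <- 9.76; nt <- 1500L; w <- round(4 * rate)
  b <- integer(nt); b[400:480] <- 1L
  x <- as.numeric(b)
  ea <- event_average_trace(x, b, 1L - b, rate, "offset")
  expect_equal(ea$n_events, 1L)
  # first half inside the event (high), second half NE (low)
  expect_gt(mean(ea$mean[1:(w - 3)]), 0.9)
  expect_lt(mean(ea$mean[(w + 4):(2 * w)]), 0.1)
})

test_that("high-pass noise estimation tracks fast noise, not slow trends", {
  expect_equal(noise_highpass(rep(2.5, 500)), 0, tolerance = 1e-10)
  # white noise of SD sigma recovered within 15% at 3000 frames
  set.seed(12)
  sds <- replicate(5, noise_highpass(rnorm(3000, sd = 0.7)))
  expect_true(all(abs(sds - 0.7) / 0.7 < 0.15))
  # slow ramp (<< 1 Hz) leaves the estimate on the noise, not the ramp
  set.seed(13)
  noise <- rnorm(3000, sd = 0.3)
  ramp <- seq(0, 5, length.out = 3000)
  expect_lt(abs(noise_highpass(noise + ramp) - noise_highpass(noise)) /
              noise_highpass(noise), 0.1)
  expect_error(noise_highpass(rnorm(30)), "short")
})

test_that("engagement needs n supra-threshold samples inside the event", {
  rate <- 9.76
  ep <- mk_epochs(c(10, 40), c(20, 50))
  flat <- rep(0, 600)
  e0 <- engagement(flat, ep, rate, noise = 0.1)
  expect_false(any(e0$engaged))
  expect_equal(e0$consistency, 0)
  # 20-frame plateau at 10x noise inside event 1 -> engaged
  x <- rnorm(600, sd = 0.05)
  x[110:129] <- 1
  e1 <- engagement(x, ep, rate, noise = 0.1)
  expect_true(e1$engaged[1])
  expect_false(e1$engaged[2])
  expect_equal(e1$consistency, 0.5)
  # event of 9 frames can never be engaged with n = 10
  ep9 <- data.frame(event = "mouse", start_frame = 100, end_frame = 109,
                    start_time = 0, end_time = 0)
  xhi <- rep(100, 600)
  expect_false(engagement(xhi, ep9, rate, noise = 0.1)$engaged[1])
  # percentage across an ensemble
  M <- rbind(x, flat)
  pct <- engagement_percentage(M, ep, rate)
  expect_equal(pct, c(0.5, 0))
})
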