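# extraction: background, rings, ARS arithmetic, cross-day matching.

test_that("background_trace is the per-frame pixel minimum", {
  v <- array(7, dim = c(4, 4, 3))
  expect_equal(background_trace(v), c(7, 7, 7))
  v[2, 3, 2] <- 0
  expect_equal(background_trace(v)[2], 0)
  set.seed(3)
  vr <- array(rnorm(5 * 6 * 4), dim = c(5, 6, 4))
  oracle <- vapply(1:4, function(t) min(vr[, , t]), numeric(1))  # full scan
  expect_equal(background_trace(vr), oracle)
  expect_equal(background_trace(vr, per_frame = FALSE), min(vr))
})

test_that("make_ring builds a proper annulus (pixel-enumeration oracle)", {
  dims <- c(41, 41)
  soma <- socens:::disk_pixels(c(21, 21), 5, dims)
  ring <- make_ring(soma, gap = 2, width = 4, all_somata = list(soma),
                    dim = dims)
  # oracle: brute-force min distance over every frame pixel
  g <- expand.grid(r = 1:41, c = 1:41)
  sr <- (soma - 1) %% 41 + 1; sc <- (soma - 1) %/% 41 + 1
  dmin <- apply(sqrt(outer(g$r, sr, "-")^2 + outer(g$c, sc, "-")^2), 1, min)
  oracle <- sort(g$r[dmin > 2 & dmin <= 6] + (g$c[dmin > 2 & dmin <= 6] - 1) * 41)
  expect_equal(ring, oracle)
  expect_length(intersect(ring, soma), 0)
  # area close to the analytic annulus pi((r+g+w)^2 - (r+g)^2)
  analytic <- pi * ((5 + 6)^2 - (5 + 2)^2)
  expect_lt(abs(length(ring) - analytic) / analytic, 0.2)
})

test_that("rings exclude neighboring somata and survive frame edges", {
  dims <- c(40, 40)
  s1 <- socens:::disk_pixels(c(20, 16), 4, dims)
  s2 <- socens:::disk_pixels(c(20, 28), 4, dims)
  r1 <- make_ring(s1, 2, 4, list(s1, s2), dims)
  r2 <- make_ring(s2, 2, 4, list(s1, s2), dims)
  expect_length(intersect(r1, s2), 0)
  expect_length(intersect(r2, s1), 0)
  # soma at the frame edge: ring clipped but nonempty
  se <- socens:::disk_pixels(c(3, 3), 3, dims)
  re <- make_ring(se, 2, 4, list(se), dims)
  expect_gt(length(re), 0)
  rr <- (re - 1) %% 40 + 1; rc <- (re - 1) %/% 40 + 1
  expect_true(all(rr >= 1 & rr <= 40 & rc >= 1 & rc <= 40))
})

test_that("ars_dff follows the ARS formulas exactly", {
  # hand-arithmetic oracle
  b <- list(F_raw = c(10, 12, 10, 10), F_ring = rep(2, 4), F_b = rep(1, 4))
  expect_equal(ars_dff(b, alpha = 1),
               c(8, 10, 8, 8) / 9.5, tolerance = 1e-12)
  # no contamination (F_ring == F_b), constant F_raw -> dF/F identically 1
  b2 <- list(F_raw = rep(5, 6), F_ring = rep(1, 6), F_b = rep(1, 6))
  expect_equal(ars_dff(b2), rep(1, 6))
  # alpha = 0 reduces to F_ROI / mean(F_ROI)
  b3 <- list(F_raw = c(4, 6, 8, 2), F_ring = c(9, 9, 9, 9), F_b = rep(1, 4))
  froi <- b3$F_raw - b3$F_b
  expect_equal(ars_dff(b3, alpha = 0), froi / mean(froi))
  # relative convention is ratio - 1
  expect_equal(ars_dff(b, convention = "relative"), ars_dff(b) - 1)
  # F_0 = 0 names the neuron
  b4 <- list(F_raw = c(1, -1), F_ring = c(0, 0), F_b = c(0, 0))
  expect_error(ars_dff(b4, neuron = 17), "17")
})

test_that("ars_dff is scale-invariant and linear in added transients", {
  set.seed(5)
  base <- list(F_raw = 50 + rnorm(100), F_ring = 20 + rnorm(100),
               F_b = rep(5, 100))
  d1 <- ars_dff(base)
  # joint scaling of (F_raw - F_b) and (F_ring - F_b) cancels through F_0
  for (g in c(2, 7)) {
    sc <- list(F_raw = base$F_b + g * (base$F_raw - base$F_b),
               F_ring = base$F_b + g * (base$F_ring - base$F_b),
               F_b = base$F_b)
    expect_equal(ars_dff(sc), d1, tolerance = 1e-12)
  }
  # adding delta to F_raw adds (delta - mean-shift) / F_0 linearly
  delta <- c(rep(0, 50), rep(3, 50))
  pl <- base; pl$F_raw <- pl$F_raw + delta
  f0_new <- mean(pl$F_raw - pl$F_b)
  want <- ((base$F_raw - base$F_b - (base$F_ring - base$F_b)) + delta) / f0_new
  expect_equal(ars_dff(pl), want, tolerance = 1e-12)
})

test_that("ARS beats no-subtraction on neuropil-contaminated video", {
  cfg <- sim_config(stage_durations = c(40, 40, 40), n_neurons = 4,
                    class_counts = c(SAN = 3, null = 1), seed = 8)
  s <- simulate_behavior(cfg)
  d <- simulate_dff(cfg, s)
  lay <- soma_layout(4, dim = c(48, 48), radius = 3, seed = 8)
  rv <- render_video(d$dff, lay, neuropil_gain = 1, noise_sd = 0.02, seed = 8)
  rois <- roi_set(rv$masks, dim = c(48, 48))
  bundles <- extract_traces(rv$video, rois)
  for (i in 1:4) {
    ars <- ars_dff(bundles[[i]])
    nosub <- (bundles[[i]]$F_raw - bundles[[i]]$F_b)
    nosub <- nosub / mean(nosub)
    expect_gt(cor(ars, d$dff$C[i, ]), cor(nosub, d$dff$C[i, ]))
  }
})

test_that("cross-day matching applies the 3 um / 0.75 overlap rule", {
  dims <- c(64, 64)
  px <- 420 / 512                          # um per px
  mk <- function(centers, radius = 16) {
    roi_set(lapply(seq_len(nrow(centers)), function(i)
      socens:::disk_pixels(centers[i, ], radius, dims)), dims)
  }
  a <- mk(rbind(c(24, 24), c(24, 44)))
  # identical sets, zero displacement: perfect matching
  m0 <- match_across_days(a, a)
  expect_equal(m0$a, 1:2); expect_equal(m0$b, 1:2)
  # shifted by 5 um (> 3 um rule): unmatched
  shift5 <- 5 / px
  b5 <- mk(rbind(c(24 + shift5, 24), c(24 + shift5, 44)))
  expect_equal(nrow(match_across_days(a, b5)), 0L)
  # shifted by ~1 um with overlap ~0.9: matched (direct rule oracle)
  shift1 <- round(1 / px)
  b1 <- mk(rbind(c(24 + shift1, 24), c(24 + shift1, 44)))
  ov <- length(intersect(a$masks[[1]], b1$masks[[1]])) /
    length(union(a$masks[[1]], b1$masks[[1]]))
  expect_gt(ov, 0.75)
  m1 <- match_across_days(a, b1)
  expect_equal(nrow(m1), 2L)
  # symmetry under swapping A/B with inverted displacement
  b_off <- mk(rbind(c(26, 24), c(26, 44)))
  mf <- match_across_days(a, b_off, displacement = c(-2, 0))
  mr <- match_across_days(b_off, a, displacement = c(2, 0))
  expect_equal(mf[order(mf$a), c("a", "b")],
               mr[order(mr$b), c("b", "a")], ignore_attr = TRUE)
})
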