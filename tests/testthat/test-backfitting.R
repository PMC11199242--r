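test_that("backfit labels by correlation and applies the gate", {
  st <- make_template_maps(16, 3, seed = 2)
  # sample equal to template 2 (scaled): label 2, corr 1
  orth <- residuals(lm(rnorm(16) ~ st$maps))   # orthogonal to all templates
  dat <- cbind(5 * st$maps[, 2], -3 * st$maps[, 1], orth)
  seg <- backfit(recording(average_reference(dat)), st, min_corr = 0.5)
  expect_equal(seg$labels[1], 2L)
  expect_equal(seg$corr[1], 1, tolerance = 1e-9)
  # invariant mode folds polarity
  expect_equal(seg$labels[2], 1L)
  expect_equal(seg$corr[2], 1, tolerance = 1e-9)
  # orthogonal sample stays unassigned under the gate
  expect_true(is.na(seg$labels[3]))
  expect_true(is.na(seg$corr[3]))

  expect_error(backfit(recording(average_reference(dat)), st,
                       min_corr = 1.5), "min_corr")
})

test_that("backfit windows restrict the analyzed range", {
  st <- make_template_maps(8, 2, seed = 3)
  dat <- st$maps[, rep(1, 10)]
  rec <- recording(dat, sr = 250, kind = "epoched", n_epochs = 1,
                   time_zero = 5)
  seg <- backfit(rec, st, min_corr = 0.25, window = c(0, 12))
  expect_equal(which(seg$analyzed), 5:8)   # 0,4,8,12 ms
  expect_true(all(is.na(seg$labels[!seg$analyzed])))
  expect_true(all(seg$labels[seg$analyzed] == 1L))
  expect_error(backfit(rec, st, window = c(900, 1000)), "empty")
})

test_that("smoothing: besag 0 is the identity and smoothing is idempotent", {
  st <- make_template_maps(12, 3, seed = 4)
  sim <- simulate_resting(st, duration_s = 4, snr = 3, seed = 5)
  seg <- backfit(sim$recording, st, min_corr = 0.5)
  s0 <- smooth_labels(seg, besag = 0)
  expect_identical(s0$labels, seg$labels)
  s1 <- smooth_labels(seg, window_half_size = 32, besag = 10)
  s2 <- smooth_labels(s1, window_half_size = 32, besag = 10)
  expect_identical(s2$labels, s1$labels)
  # unassigned samples are frozen
  expect_identical(is.na(s1$labels), is.na(seg$labels))
})

test_that("smoothing absorbs a near-tied single-sample island", {
  # 17 samples: state A everywhere except a 1-sample island of B at t = 9,
  # with fits nearly tied between A and B at the island
  n <- 17
  fit <- rbind(rep(0.9, n), rep(0.1, n))
  fit[1, 9] <- 0.89; fit[2, 9] <- 0.90   # island barely prefers B
  labels <- rep(1L, n); labels[9] <- 2L
  seg <- make_seg(labels, fit, sr = 250)
  out <- smooth_labels(seg, window_half_size = 32, besag = 10)
  expect_equal(out$labels, rep(1L, n))
})

test_that("minimum-segment rule splits short runs per the floor convention", {
  fit <- matrix(1, 3, 46)
  seg <- make_seg(rep(c(1L, 2L, 3L), c(20, 6, 20)), fit, sr = 250)
  out <- enforce_min_segment(seg, min_dur = 32)   # 6 samples = 24 ms < 32 ms
  expect_equal(out$labels, rep(c(1L, 3L), c(23, 23)))

  seg <- make_seg(rep(c(1L, 2L, 3L), c(20, 5, 20)), fit[, 1:45], sr = 250)
  out <- enforce_min_segment(seg, min_dur = 32)
  expect_equal(out$labels, rep(c(1L, 3L), c(22, 23)))

  # identity when nothing is short
  seg <- make_seg(rep(c(1L, 2L), c(20, 20)), fit[, 1:40], sr = 250)
  expect_identical(enforce_min_segment(seg, 32)$labels, seg$labels)

  # edge runs merge wholly into their single neighbor
  seg <- make_seg(rep(c(1L, 2L), c(3, 40)), fit[, 1:43], sr = 250)
  expect_equal(enforce_min_segment(seg, 32)$labels, rep(2L, 43))

  # no interior run shorter than the floor remains, on random label noise
  labs <- withr::with_seed(8, sample(1:3, 300, replace = TRUE))
  seg <- make_seg(labs, matrix(1, 3, 300), sr = 250)
  out <- enforce_min_segment(seg, 32)
  r <- rle(out$labels)
  interior <- r$lengths[-c(1, length(r$lengths))]
  expect_true(all(interior >= ceiling(32 * 250 / 1000)))
})

test_that("temporal statistics follow their definitions", {
  # 1000 samples at 250 Hz, state A in 10 interior runs totaling 500 samples
  labs <- rep(2L, 1000)
  pos <- round(seq(51, 901, length.out = 10))
  for (p in pos) labs[p:(p + 49)] <- 1L
  seg <- make_seg(labs, matrix(1, 2, 1000), sr = 250)
  ts <- temporal_stats(seg)
  expect_equal(ts$per_state$coverage[1], 0.5)
  expect_equal(ts$per_state$occurrence[1], 2.5)
  expect_equal(ts$per_state$mean_duration_ms[1], 200)

  # recording equal to template A everywhere: GEV_A = 1
  st <- make_template_maps(8, 2, seed = 6)
  rec <- recording(st$maps[, rep(1, 100)] * rep(runif(100, 0.5, 2), each = 8))
  seg <- backfit(rec, st, min_corr = 0.5)
  ts <- temporal_stats(seg)
  expect_equal(ts$per_state$gev[1], 1, tolerance = 1e-9)
  expect_equal(ts$per_state$gev[2], 0)
  expect_equal(ts$unassigned_fraction, 0)

  # direct-summation oracle on a noisy fixture
  sim <- simulate_resting(st, duration_s = 4, snr = 2, seed = 9)
  seg <- backfit(sim$recording, st, min_corr = 0.3)
  ts <- temporal_stats(seg)
  g <- seg$gfp_trace
  denom <- sum(g^2)
  for (k in 1:2) {
    acc <- 0
    for (t in seq_along(seg$labels))
      if (!is.na(seg$labels[t]) && seg$labels[t] == k)
        acc <- acc + (g[t] * seg$corr[t])^2
    expect_equal(ts$per_state$gev[k], acc / denom)
  }
  expect_lte(ts$gev_total, 1)
  expect_equal(sum(ts$per_state$coverage) + ts$unassigned_fraction, 1,
               tolerance = 1e-9)
})

test_that("backfit pipeline is invariant to a global polarity flip", {
  st <- make_template_maps(12, 3, seed = 10)
  sim <- simulate_resting(st, duration_s = 5, snr = 5, seed = 11)
  run <- function(rec) {
    seg <- backfit(rec, st, min_corr = 0.5)
    seg <- smooth_labels(seg)
    enforce_min_segment(seg)$labels
  }
  rec_flip <- sim$recording
  rec_flip$data <- -rec_flip$data
  expect_identical(run(sim$recording), run(rec_flip))
})

test_that("planted coverages are recovered by the full backfit pipeline", {
  st <- make_template_maps(16, 4, seed = 12)
  sim <- simulate_resting(st, duration_s = 30, snr = 10,
                          coverage = c(0.4, 0.3, 0.2, 0.1), seed = 13)
  # backfit the planted templates directly (the spatial filter would distort
  # the data relative to templates that were not derived from filtered data)
  rec <- normalize_gfp_median(sim$recording)
  seg <- enforce_min_segment(smooth_labels(backfit(rec, st, 0.5)))
  ts <- temporal_stats(seg)
  expect_true(all(abs(ts$per_state$coverage - sim$truth$coverage) < 0.05))
  # GEV monotone in realized coverage for clearly separated pairs
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sim$truth$coverage[i] - sim$truth$coverage[j]
    if (abs(d) > 0.05)
      expect_equal(sign(ts$per_state$gev[i] - ts$per_state$gev[j]), sign(d))
  }
})
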