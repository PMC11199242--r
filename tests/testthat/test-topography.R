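test_that("average_reference subtracts the spatial mean", {
  expect_equal(average_reference(c(5, 5, 5)), c(0, 0, 0))
  expect_equal(average_reference(c(1, 0, -1)), c(1, 0, -1))
  expect_equal(average_reference(c(3, 1, 2)), c(1, -1, 0))
  # idempotent, also on matrices
  m <- matrix(rnorm(20), 4, 5)
  expect_equal(average_reference(average_reference(m)), average_reference(m))
  expect_error(average_reference(c(1, NA, 2)), "non-finite")
})

test_that("gfp is the spatial standard deviation", {
  expect_equal(gfp(c(0, 0, 0)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(c(3, -1, -1, -1)), sqrt(3))
  expect_error(gfp(5), "at least 2")
  # invariant to re-referencing an already referenced topography
  v <- average_reference(rnorm(16))
  expect_equal(gfp(average_reference(v)), gfp(v))
})

test_that("recording constructor validates its fields", {
  expect_error(recording(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_error(recording(matrix(1, 2, 4), sr = 0), "positive")
  r <- recording(matrix(rnorm(24), 2, 12), sr = 4, kind = "epoched",
                 n_epochs = 3, time_zero = 2)
  expect_equal(dim(epoch_array(r)), c(2, 4, 3))
  expect_equal(epoch_times(r), c(-250, 0, 250, 500))
  expect_error(recording(matrix(0, 2, 10), kind = "epoched", n_epochs = 3),
               "multiple")
})

test_that("spatial filter trims the neighborhood extremes", {
  # constant field is a fixed point
  pos <- sphere_layout(12)
  rec <- recording(matrix(7, 12, 5) + 0, channel_positions = pos)
  out <- spatial_filter(rec)
  expect_equal(out$data, average_reference(matrix(7, 12, 5)))

  # spiked channel among near-zero neighbors on a 7-channel star
  g <- complete_graph(7)
  vals <- c(1000, 0.1, 0.2, -0.1, 0, 0.05, -0.2)
  rec <- recording(matrix(vals, 7, 1))
  out <- spatial_filter(rec, g)
  raw <- microstatr:::trimmed_neighborhood_mean(matrix(vals, 7, 1), g)
  expect_lte(raw[1, 1], max(vals[-1]))
  expect_gte(raw[1, 1], min(vals[-1]))

  # symmetric neighborhoods preserve a linear gradient at interior channels
  n <- 11
  nb <- t(vapply(seq_len(n), function(i) {
    cand <- c(i - 2L, i - 1L, i + 1L, i + 2L)
    as.integer(((cand - 1L) %% n) + 1L)
  }, integer(4)))
  vals <- matrix(as.numeric(seq_len(n)), n, 1)
  raw <- microstatr:::trimmed_neighborhood_mean(vals, manual_graph(nb))
  expect_equal(raw[3:9, 1], vals[3:9, 1], tolerance = 1e-6)

  expect_error(spatial_filter(recording(matrix(0, 3, 2) + 0),
                              manual_graph(matrix(c(2, 3, 1), 3, 1))),
               "k_neighbors")
})

test_that("GFP peaks are strict local maxima", {
  # construct a 2-channel recording with GFP series [1, 3, 1, 3, 1]
  g <- c(1, 3, 1, 3, 1)
  rec <- recording(rbind(g, -g))
  pk <- extract_gfp_peaks(rec)
  expect_equal(pk$index, c(2, 4))

  mono <- recording(rbind(1:6, -(1:6)) + 0)
  expect_equal(length(extract_gfp_peaks(mono)$index), 0L)

  # plateaus are not peaks
  plat <- c(1, 2, 2, 1)
  expect_equal(length(extract_gfp_peaks(recording(rbind(plat, -plat)))$index),
               0L)

  # exhaustive scan oracle on generator output
  st <- make_template_maps(16, 3, seed = 5)
  sim <- simulate_resting(st, duration_s = 10, snr = 10, seed = 6)
  pk <- extract_gfp_peaks(sim$recording)
  g <- gfp_series(sim$recording)
  oracle <- integer(0)
  for (t in 2:(length(g) - 1))
    if (g[t] > g[t - 1] && g[t] > g[t + 1]) oracle <- c(oracle, t)
  expect_equal(pk$index, oracle)
})

test_that("trim_continuous keeps the first seconds", {
  rec <- recording(matrix(rnorm(4 * 50000), 4, 50000), sr = 250)
  out <- trim_continuous(rec, 157)
  expect_equal(ncol(out$data), 39250)
  expect_equal(trim_continuous(out, 157)$data, out$data)  # identity at full length
  short <- recording(matrix(0, 4, 25000) + 0, sr = 250)
  expect_error(trim_continuous(short, 157), "short")
})

test_that("normalize_gfp_median scales to unit median GFP", {
  m <- average_reference(matrix(rnorm(6 * 100), 6, 100))
  rec <- recording(2 * m / median(gfp_series(m)))  # constant-free scaling
  out <- normalize_gfp_median(rec)
  expect_equal(median(gfp_series(out)), 1, tolerance = 1e-9)
  expect_equal(out$data, rec$data / 2, tolerance = 1e-12)
  # idempotence
  out2 <- normalize_gfp_median(out)
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(normalize_gfp_median(recording(matrix(0, 3, 5) + 0)), "zero")
})

test_that("reject_epochs drops, repairs, or keeps epochs by channel count", {
  pos <- sphere_layout(16)
  ns <- 50; ne <- 4
  base <- withr::with_seed(11, matrix(rnorm(16 * ns * ne, sd = 5), 16))
  rec <- recording(base, sr = 250, channel_positions = pos, kind = "epoched",
                   n_epochs = ne)

  # 12 channels at 200 uV in epoch 2 -> dropped
  dat <- base
  dat[1:12, ns + seq_len(ns)] <- 200
  rec2 <- recording(dat, sr = 250, channel_positions = pos,
                    kind = "epoched", n_epochs = ne)
  res <- reject_epochs(rec2, amp_limit = 100, joint_prob_sd = Inf,
                       channel_threshold = 10)
  expect_equal(res$report$decision[2], "dropped")
  expect_equal(res$recording$n_epochs, ne - 1L)

  # 3 offending channels -> kept but interpolated
  dat <- base
  dat[c(2, 5, 9), 2 * ns + seq_len(ns)] <- 300
  rec3 <- recording(dat, sr = 250, channel_positions = pos,
                    kind = "epoched", n_epochs = ne)
  res <- reject_epochs(rec3, amp_limit = 100, joint_prob_sd = Inf)
  expect_equal(res$report$decision[3], "interpolated")
  expect_equal(res$report$channels[3], "2,5,9")
  expect_equal(res$recording$n_epochs, ne)
  arr <- epoch_array(res$recording)
  expect_lt(max(abs(arr[c(2, 5, 9), , 3])), 100)
  # untouched epochs pass through unchanged
  expect_equal(arr[, , 1], epoch_array(rec3)[, , 1])

  # thresholds at infinity: identity
  res <- reject_epochs(rec, amp_limit = Inf, p2p_limit = Inf,
                       joint_prob_sd = Inf)
  expect_equal(res$recording$data, rec$data)
  expect_true(all(res$report$decision == "kept"))

  # peak-to-peak criterion catches a high-amplitude swing
  dat <- base
  dat[1:11, 3 * ns + 1:10] <- rep(c(-80, 80), each = 5)
  rec4 <- recording(dat, sr = 250, channel_positions = pos,
                    kind = "epoched", n_epochs = ne)
  res <- reject_epochs(rec4, amp_limit = Inf, p2p_limit = 100,
                       p2p_window = 40, p2p_step = 20, joint_prob_sd = Inf)
  expect_equal(res$report$decision[4], "dropped")
  expect_error(reject_epochs(rec, p2p_limit = 100, p2p_window = 2,
                             joint_prob_sd = Inf),
               "shorter than 2 samples")
})
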