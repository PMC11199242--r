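# small epoched fixture: nc channels, per-epoch time axis -500..800 ms
gonogo_fixture <- function(nc = 8, n_trials = 25, sr = 250, fill = NULL,
                           seed = 1) {
  ns <- length(seq(-500, 800, by = 1000 / sr))
  dat <- if (is.null(fill))
    withr::with_seed(seed, matrix(rnorm(nc * ns * n_trials), nc))
  else matrix(fill, nc, ns * n_trials)
  recording(dat, sr = sr, kind = "epoched", n_epochs = n_trials,
            time_zero = which(seq(-500, 800, by = 1000 / sr) == 0))
}

test_that("filter_trials keeps the closed RT interval [100, 2000]", {
  rec <- gonogo_fixture(n_trials = 4)
  out <- filter_trials(rec, c(50, 150, 2500, 900))
  expect_equal(attr(out, "kept"), c(2L, 4L))
  expect_equal(out$n_epochs, 2L)
  expect_equal(epoch_array(out)[, , 1], epoch_array(rec)[, , 2])

  # boundary values are kept; all-in-range is the identity
  out <- filter_trials(rec, c(100, 2000, 500, 1999))
  expect_equal(attr(out, "kept"), 1:4)
  expect_equal(out$data, rec$data)
  expect_error(filter_trials(rec, c(1, 2)), "length")
})

test_that("average_condition averages and baseline-corrects with gates", {
  rec <- gonogo_fixture(n_trials = 25, seed = 2)
  one <- unname(epoch_array(rec)[, , 1])
  ident <- recording(matrix(rep(one, 25), nrow(one)), sr = rec$sr,
                     kind = "epoched", n_epochs = 25,
                     time_zero = rec$time_zero)
  avg <- average_condition(ident, "go_correct")
  bl <- avg$time_ms >= -500 & avg$time_ms <= -300
  expect_equal(avg$data, one - rowMeans(one[, bl]), tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(avg$data[, bl]))), 1e-9)

  expect_error(average_condition(gonogo_fixture(n_trials = 5), "nogo_error"),
               "at least 6")
  expect_error(average_condition(gonogo_fixture(n_trials = 20), "go_correct"),
               "at least 21")

  # averaging noise shrinks the error ~ 1/sqrt(n)
  sd_of_mean <- function(n) {
    r <- gonogo_fixture(n_trials = n, seed = 3)
    sd(average_condition(r, "nogo_error")$data)
  }
  expect_lt(sd_of_mean(96), 2.2 * sd_of_mean(24) / 2)
})

test_that("difference_wave subtracts go from nogo pointwise", {
  rec <- gonogo_fixture(n_trials = 25, seed = 4)
  a <- average_condition(rec, "go_correct")
  b <- average_condition(rec, "nogo_error")
  d <- difference_wave(b, a)
  expect_equal(d$data, matrix(0, nrow(a$data), ncol(a$data)))
  expect_equal(d$condition, "difference")

  # linearity
  b2 <- b; b2$data <- 3 * b$data
  a2 <- a; a2$data <- 3 * a$data
  expect_equal(difference_wave(b2, a2)$data, 3 * difference_wave(b, a)$data)

  short <- a; short$time_ms <- a$time_ms + 4
  expect_error(difference_wave(b, short), "axis mismatch")
})

test_that("grand-average segmentation recovers planted alternating states", {
  st <- make_template_maps(16, 2, seed = 5)
  time_ms <- seq(-500, 800, by = 4)
  ns <- length(time_ms)
  post <- which(time_ms > -300)
  dat <- matrix(0, 16, ns)
  # alternate the two maps in 100-ms blocks after the baseline (275 = 11 x 25
  # samples, so no short trailing run falls prey to the min-segment rule)
  block <- rep(rep(1:2, each = 25), length.out = length(post))
  dat[, post] <- st$maps[, block] * 5
  grand <- structure(list(condition = "difference", data = dat, sr = 250,
                          time_ms = time_ms, baseline = c(-500, -300),
                          n_trials = 30,
                          channel_names = paste0("ch", 1:16)),
                     class = "erp_average")
  res <- segment_grand_average(grand, k_range = c(1, 5), n_restarts = 20,
                               seed = 6)
  expect_equal(res$states$k, 2L)
  seg <- res$segmentation
  # every non-baseline timepoint labeled, none outside
  expect_true(all(!is.na(seg$labels[seg$analyzed])))
  expect_true(all(is.na(seg$labels[!seg$analyzed])))
  # labels switch exactly at the planted transitions (up to state identity)
  got <- seg$labels[seg$analyzed]
  expect_equal(rle(got)$lengths, rle(block)$lengths)

  # seed-fixed repeatability, bit for bit
  res2 <- segment_grand_average(grand, k_range = c(1, 5), n_restarts = 20,
                                seed = 6)
  expect_identical(res$segmentation$labels, res2$segmentation$labels)
  expect_identical(res$states$maps, res2$states$maps)
})

test_that("the error microstate is the run containing t = 0", {
  st <- make_template_maps(16, 3, seed = 7)
  fit <- matrix(0.6, 3, 100)
  labels <- rep(c(1L, 2L, 3L), c(40, 45, 15))
  seg <- make_seg(labels, fit, sr = 250, polarity = "variant")
  seg$time_ms <- seq(-160, 236, by = 4)   # t = 0 falls at sample 41 (state 2)
  ident <- identify_error_microstate(seg, st)
  expect_equal(ident$state, 2L)
  expect_equal(ident$window, c(0, 176))
  tpl <- st$maps[, 2]
  expect_equal(ident$roi, which(tpl < mean(tpl) - sd(tpl)))

  # a single-sample state at t = 0 is selected
  labels2 <- rep(c(1L, 3L, 1L), c(40, 1, 59))
  seg2 <- make_seg(labels2, fit, sr = 250, polarity = "variant")
  seg2$time_ms <- seq(-160, 236, by = 4)
  expect_equal(identify_error_microstate(seg2, st)$state, 3L)

  # unassigned at t = 0 errors with a manual-override hint
  labels3 <- labels; labels3[30:60] <- NA
  seg3 <- make_seg(labels3, fit, sr = 250, polarity = "variant")
  seg3$time_ms <- seq(-160, 236, by = 4)
  expect_error(identify_error_microstate(seg3, st), "manual")
})

test_that("score_ern is the mean over window and ROI, linear in the data", {
  rec <- gonogo_fixture(nc = 6, n_trials = 25, fill = 0)
  avg <- average_condition(rec, "go_correct")
  avg$data[2:3, avg$time_ms >= -64 & avg$time_ms <= 108] <- -5
  sc <- score_ern(avg, avg, window = c(-64, 108), roi = 2:3)
  expect_equal(sc$go_mean, -5)
  expect_equal(sc$nogo_mean, -5)

  # single sample, single channel
  sc1 <- score_ern(avg, avg, window = c(0, 0), roi = 2)
  expect_equal(sc1$go_mean, avg$data[2, avg$time_ms == 0])

  avg2 <- avg; avg2$data <- 2 * avg$data
  expect_equal(score_ern(avg2, avg2, c(-64, 108), 2:3)$go_mean,
               2 * sc$go_mean)
  expect_error(score_ern(avg, avg, c(-64, 108), integer(0)), "empty")
  expect_error(score_ern(avg, avg, c(5000, 6000), 2), "outside")
})

test_that("residualize_ern removes go-related variance", {
  sc <- data.frame(go_mean = c(1, 2, 3, 4), nogo_mean = c(1, 2, 3, 4))
  out <- residualize_ern(sc)
  expect_equal(out$residualized, rep(0, 4))

  sc <- withr::with_seed(8, {
    go <- rnorm(40)
    data.frame(go_mean = go, nogo_mean = 2 * go + rnorm(40, sd = 0.5))
  })
  out <- residualize_ern(sc)
  expect_equal(sum(out$residualized), 0, tolerance = 1e-9)
  expect_equal(sum(out$residualized * sc$go_mean), 0, tolerance = 1e-9)
  expect_error(residualize_ern(sc[1:2, ]), "at least 3")
  expect_error(residualize_ern(data.frame(go_mean = rep(1, 5),
                                          nogo_mean = rnorm(5))),
               "zero variance")
})
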