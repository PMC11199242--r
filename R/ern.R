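#' Response-locked condition average
#'
#' Averages an epoched recording across trials and baseline-corrects each
#' channel over the baseline window. Quality gates follow the minimum trial
#' counts under which the ERN is reliably quantifiable: at least 6
#' `nogo_error` trials and at least 21 `go_correct` trials.
#'
#' @param epochs post-rejection epoched recording (t = 0 at the button press).
#' @param condition `"go_correct"`, `"nogo_error"` or `"difference"`.
#' @param baseline `c(start_ms, end_ms)` baseline window (default
#'   `c(-500, -300)`), closed on both ends.
#' @return object of class `"erp_average"`.
#' @export
average_condition <- function(epochs,
                              condition = c("go_correct", "nogo_error",
                                            "difference"),
                              baseline = c(-500, -300)) {
  condition <- match.arg(condition)
  stopifnot(inherits(epochs, "recording"), epochs$kind == "epoched")
  gate <- c(go_correct = 21L, nogo_error = 6L, difference = 1L)[condition]
  if (epochs$n_epochs < gate)
    stop(sprintf("only %d trials for %s; gate requires at least %d",
                 epochs$n_epochs, condition, gate))
  arr <- epoch_array(epochs)
  avg <- apply(arr, c(1, 2), mean)
  dimnames(avg) <- NULL
  time_ms <- epoch_times(epochs)
  bl <- time_ms >= baseline[1] & time_ms <= baseline[2]
  if (!any(bl)) stop("baseline window contains no samples")
  avg <- avg - rowMeans(avg[, bl, drop = FALSE])
  structure(list(condition = condition, data = avg, sr = epochs$sr,
                 time_ms = time_ms, baseline = baseline,
                 n_trials = epochs$n_epochs,
                 channel_names = epochs$channel_names),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average: %s, %d channels, %d samples [%g..%g ms], %d trials>\n",
              x$condition, nrow(x$data), ncol(x$data),
              min(x$time_ms), max(x$time_ms), x$n_trials))
  invisible(x)
}

#' Keep trials with plausible reaction times
#'
#' Drops trials whose button press fell under 100 ms or over 2000 ms after
#' the stimulus (both bounds inclusive on the keep side).
#'
#' @param epochs epoched recording.
#' @param rt per-trial reaction times in ms.
#' @param rt_min,rt_max keep range in ms (defaults 100 and 2000).
#' @return filtered epoched recording with attribute `"kept"` (trial indices).
#' @export
filter_trials <- function(epochs, rt, rt_min = 100, rt_max = 2000) {
  stopifnot(inherits(epochs, "recording"), epochs$kind == "epoched")
  if (length(rt) != epochs$n_epochs)
    stop("rt length does not match trial count")
  keep <- which(rt >= rt_min & rt <= rt_max)
  out <- subset_epochs(epochs, keep)
  attr(out, "kept") <- keep
  out
}

subset_epochs <- function(rec, keep) {
  ns <- n_epoch_samples(rec)
  arr <- epoch_array(rec)[, , keep, drop = FALSE]
  rec$data <- matrix(arr, nrow = nrow(rec$data), ncol = ns * length(keep))
  rec$n_epochs <- length(keep)
  rec
}

#' Error-minus-correct difference wave
#'
#' @param err `nogo_error` average.
#' @param corr `go_correct` average.
#' @return `erp_average` with condition `"difference"` (nogo minus go).
#' @export
difference_wave <- function(err, corr) {
  stopifnot(inherits(err, "erp_average"), inherits(corr, "erp_average"))
  if (!isTRUE(all.equal(err$time_ms, corr$time_ms)) ||
      nrow(err$data) != nrow(corr$data))
    stop("axis mismatch between condition averages")
  out <- err
  out$condition <- "difference"
  out$data <- err$data - corr$data
  out$n_trials <- min(err$n_trials, corr$n_trials)
  out
}

#' Segment a grand-average difference wave into microstates
#'
#' Single-stage polarity-variant clustering of every non-baseline timepoint
#' (not just GFP peaks) with meta-criterion selection of k, followed by
#' sequential labeling of all non-baseline timepoints (no correlation gate),
#' temporal smoothing and the minimum-segment rule. Defaults follow the task
#' design: k 1-20, 300 restarts.
#'
#' @param grand `erp_average` of the grand-average difference wave.
#' @param k_range candidate k range (default `c(1, 20)`).
#' @param n_restarts restarts per k (default 300).
#' @param seed integer seed.
#' @param smooth_half_ms,besag,min_seg_ms smoothing/segment parameters
#'   (defaults 32 ms, 10, 32 ms).
#' @return list with `states` (`microstate_set`, polarity-variant),
#'   `segmentation` (every non-baseline sample labeled) and `profile`.
#' @export
segment_grand_average <- function(grand, k_range = c(1, 20),
                                  n_restarts = 300, seed = 1,
                                  smooth_half_ms = 32, besag = 10,
                                  min_seg_ms = 32) {
  stopifnot(inherits(grand, "erp_average"))
  post <- grand$time_ms > grand$baseline[2]
  maps <- grand$data[, post, drop = FALSE]
  sel <- select_k(maps, k_range = k_range, polarity = "variant",
                  n_restarts = n_restarts, seed = seed)
  states <- sel$best
  win <- c(min(grand$time_ms[post]), max(grand$time_ms))
  seg <- backfit(grand, states, min_corr = 0, window = win)
  # sequential labeling: no gate at this stage
  fill <- seg$analyzed & is.na(seg$labels)
  if (any(fill)) {
    lab <- max.col(t(seg$fit_corr[, fill, drop = FALSE]),
                   ties.method = "first")
    seg$labels[fill] <- lab
    seg$corr <- segment_corr(seg$labels, seg$fit_corr, FALSE)
  }
  seg <- smooth_labels(seg, window_half_size = smooth_half_ms, besag = besag)
  seg <- enforce_min_segment(seg, min_dur = min_seg_ms)
  list(states = states, segmentation = seg, profile = sel$profile)
}

#' Identify the error-related microstate
#'
#' Deterministic stand-in for visual inspection: the selected state is the
#' one whose labeled run contains t = 0 (if several candidate runs touch
#' t = 0, the one covering the most samples in [-100, 150] ms). Its run
#' extent becomes the scoring window, and the region of interest is the
#' template's maximally negative pole: channels whose template value lies
#' below (mean - 1 SD).
#'
#' @param seg `segmentation` of the grand difference average.
#' @param states the matching `microstate_set`.
#' @return list with `state` (index), `window` (`c(start_ms, end_ms)`),
#'   `roi` (channel indices) and `template` (the state's map, for
#'   inspection).
#' @export
identify_error_microstate <- function(seg, states) {
  stopifnot(inherits(seg, "segmentation"), inherits(states, "microstate_set"))
  idx <- which(seg$analyzed)
  lab <- seg$labels[idx]
  tms <- seg$time_ms[idx]
  code <- ifelse(is.na(lab), 0L, lab)
  r <- rle(code)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  cand <- which(tms[starts] <= 0 & tms[ends] >= 0 & r$values > 0L)
  if (length(cand) == 0L)
    stop("no labeled run contains t = 0; select the error microstate manually (CLI --window/--roi override)")
  if (length(cand) > 1L) {
    span <- vapply(cand, function(s) {
      t_run <- tms[starts[s]:ends[s]]
      sum(t_run >= -100 & t_run <= 150)
    }, numeric(1))
    cand <- cand[which.max(span)]
  }
  state <- r$values[cand]
  window <- c(tms[starts[cand]], tms[ends[cand]])
  tpl <- states$maps[, state]
  roi <- which(tpl < mean(tpl) - stats::sd(tpl))
  list(state = state, window = window, roi = roi, template = tpl)
}

#' Microstate-guided ERN score
#'
#' Mean activity over the microstate-identified window and channel pool,
#' separately per condition average.
#'
#' @param avg_go,avg_nogo per-participant condition averages.
#' @param window `c(start_ms, end_ms)` (closed on both ends).
#' @param roi channel indices (non-empty).
#' @return one-row data.frame: `go_mean`, `nogo_mean` (microvolts).
#' @export
score_ern <- function(avg_go, avg_nogo, window, roi) {
  stopifnot(inherits(avg_go, "erp_average"), inherits(avg_nogo, "erp_average"))
  if (length(roi) == 0L) stop("empty ROI")
  if (any(roi < 1L) || any(roi > nrow(avg_go$data))) stop("ROI out of range")
  score1 <- function(avg) {
    s <- avg$time_ms >= window[1] & avg$time_ms <= window[2]
    if (!any(s)) stop("scoring window outside the epoch")
    mean(avg$data[roi, s, drop = FALSE])
  }
  data.frame(go_mean = score1(avg_go), nogo_mean = score1(avg_nogo))
}

#' Residualized ERN scores
#'
#' Regresses no-go scores on go scores (OLS with intercept) across
#' participants and returns the unstandardized residuals, isolating
#' error-specific variance from generic response-locked activity.
#'
#' @param scores data.frame with columns `go_mean` and `nogo_mean`, one row
#'   per participant (at least 3).
#' @return the input with a `residualized` column appended; residuals sum to
#'   zero.
#' @export
residualize_ern <- function(scores) {
  if (nrow(scores) < 3L) stop("need at least 3 participants")
  if (stats::sd(scores$go_mean) == 0)
    stop("zero variance in go scores; cannot residualize")
  fit <- stats::lm(nogo_mean ~ go_mean, data = scores)
  scores$residualized <- as.numeric(stats::residuals(fit))
  scores
}
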