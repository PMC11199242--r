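#' Backfit microstate templates to a recording
#'
#' Labels every sample (inside the analysis window, if any) with the template
#' of highest spatial correlation — absolute correlation in invariant mode,
#' signed in variant mode — subject to a minimum-correlation gate: samples
#' whose winning correlation falls below `min_corr` stay unassigned. Rest
#' analysis uses the invariant gate 0.50; task analysis the variant gate 0.25
#' restricted to the window of the microstate of interest.
#'
#' @param rec a recording (continuous, or single-epoch/averaged with a time
#'   axis) whose channels match the templates.
#' @param states a `microstate_set`.
#' @param min_corr gate in [0, 1] (default 0.50).
#' @param window optional `c(start_ms, end_ms)` restriction (closed on both
#'   ends); requires a time axis (epoched/averaged input).
#' @return object of class `"segmentation"`: per-sample `labels` (NA =
#'   unassigned), `corr` (with the assigned template; absolute in invariant
#'   mode, signed in variant), `gfp_trace`, `sr`, `time_ms`, `analyzed`
#'   (logical), plus the full template-correlation matrix `fit_corr` (k x n,
#'   signed) used by smoothing and statistics.
#' @export
backfit <- function(rec, states, min_corr = 0.50, window = NULL) {
  stopifnot(inherits(states, "microstate_set"))
  if (min_corr < 0 || min_corr > 1) stop("min_corr must be in [0, 1]")
  if (inherits(rec, c("recording", "erp_average"))) {
    dat <- rec$data
    sr <- rec$sr
  } else {
    dat <- as.matrix(rec)
    sr <- attr(rec, "sr")
    if (is.null(sr)) sr <- 250
  }
  if (nrow(dat) != nrow(states$maps)) stop("channel counts differ")
  n <- ncol(dat)
  time_ms <- segmentation_times(rec, n, sr)

  analyzed <- rep(TRUE, n)
  if (!is.null(window)) {
    analyzed <- time_ms >= window[1] & time_ms <= window[2]
    if (!any(analyzed)) stop("empty analysis window")
  }

  Xc <- sweep(dat, 2L, colMeans(dat))
  nrm <- sqrt(colSums(Xc^2))
  ok <- nrm > 0
  C <- matrix(0, states$k, n)
  C[, ok] <- crossprod(states$maps, sweep(Xc[, ok, drop = FALSE], 2L,
                                          nrm[ok], "/"))
  invariant <- states$polarity == "invariant"
  score <- if (invariant) abs(C) else C
  labels <- max.col(t(score), ties.method = "first")
  win <- score[cbind(labels, seq_len(n))]
  labels[win < min_corr | !ok | !analyzed] <- NA_integer_
  corr <- ifelse(is.na(labels), NA_real_,
                 if (invariant) abs(C[cbind(labels, seq_len(n))])
                 else C[cbind(labels, seq_len(n))])
  corr[is.na(labels)] <- NA_real_

  structure(list(labels = labels, corr = corr,
                 gfp_trace = gfp_series(dat), sr = sr, time_ms = time_ms,
                 analyzed = analyzed, window = window,
                 fit_corr = C, polarity = states$polarity, k = states$k,
                 min_corr = min_corr),
            class = "segmentation")
}

segmentation_times <- function(rec, n, sr) {
  if (inherits(rec, "erp_average")) return(rec$time_ms)
  if (inherits(rec, "recording") && rec$kind == "epoched" &&
      identical(rec$n_epochs, 1L))
    return(epoch_times(rec))
  if (!is.null(attr(rec, "time_ms"))) return(attr(rec, "time_ms"))
  (seq_len(n) - 1L) * 1000 / sr
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf(
    "<segmentation: %d samples, k = %d, polarity-%s, %.1f%% unassigned>\n",
    length(x$labels), x$k, x$polarity,
    100 * mean(is.na(x$labels[x$analyzed]))))
  invisible(x)
}

# k x n windowed count of same-label assigned neighbors within +/- w samples,
# excluding the sample itself.
neighbor_counts <- function(labels, k, w) {
  n <- length(labels)
  N <- matrix(0, k, n)
  lo <- pmax(seq_len(n) - w, 1L)
  hi <- pmin(seq_len(n) + w, n)
  for (j in seq_len(k)) {
    ind <- as.numeric(!is.na(labels) & labels == j)
    cs <- c(0, cumsum(ind))
    N[j, ] <- cs[hi + 1L] - cs[lo] - ind
  }
  N
}

#' Besag-penalized temporal smoothing of a segmentation
#'
#' Iteratively relabels assigned samples: sample t takes the label k
#' minimizing (1 - fit[t,k]) - (besag / (2 * w)) * N[t,k], where fit is the
#' squared (invariant) or signed (variant) correlation with template k, w is
#' the half-window in samples, and N counts same-label assigned samples
#' within +/- w (the sample itself excluded). Unassigned samples are frozen
#' and never counted. Iterates to a label fixed point (at most `max_passes`
#' synchronous passes). `besag = 0` reduces to the unpenalized backfit
#' labeling.
#'
#' @param seg a `segmentation`.
#' @param window_half_size half-window in ms (default 32, i.e. 8 samples at
#'   250 Hz).
#' @param besag smoothing strength (default 10).
#' @param max_passes iteration cap (default 100).
#' @return smoothed `segmentation`.
#' @export
smooth_labels <- function(seg, window_half_size = 32, besag = 10,
                          max_passes = 100) {
  stopifnot(inherits(seg, "segmentation"))
  w <- round(window_half_size * seg$sr / 1000)
  if (w < 1L) stop("window_half_size is under one sample at this rate")
  C <- seg$fit_corr
  invariant <- seg$polarity == "invariant"
  fit <- if (invariant) C^2 else C
  lam <- besag / (2 * w)
  labels <- seg$labels
  movable <- which(!is.na(labels))
  if (length(movable) == 0L) return(seg)
  for (pass in seq_len(max_passes)) {
    N <- neighbor_counts(labels, seg$k, w)
    cost <- (1 - fit) - lam * N
    new_lab <- max.col(t(-cost), ties.method = "first")
    changed <- labels[movable] != new_lab[movable]
    labels[movable] <- new_lab[movable]
    if (!any(changed)) break
  }
  seg$labels <- labels
  seg$corr <- segment_corr(labels, C, invariant)
  seg
}

segment_corr <- function(labels, C, invariant) {
  n <- length(labels)
  corr <- rep(NA_real_, n)
  ok <- !is.na(labels)
  v <- C[cbind(labels[ok], which(ok))]
  corr[ok] <- if (invariant) abs(v) else v
  corr
}

#' Remove improbably small segments
#'
#' Any maximal run shorter than `min_dur` (in samples: fewer than
#' `ceiling(min_dur * sr / 1000)`) is divided in half: the first
#' `floor(len/2)` samples join the preceding run, the remainder the
#' following run. Runs at the edges of the analyzed range are merged wholly
#' into their single neighbor. Runs are fixed shortest-first, re-scanning
#' after each fix, until no short run remains. Unassigned stretches are
#' treated as ordinary runs: they may absorb split halves and may themselves
#' be divided.
#'
#' @param seg a `segmentation`.
#' @param min_dur minimum segment duration in ms (default 32).
#' @return `segmentation` without interior runs shorter than `min_dur`.
#' @export
enforce_min_segment <- function(seg, min_dur = 32) {
  stopifnot(inherits(seg, "segmentation"))
  min_len <- ceiling(min_dur * seg$sr / 1000)
  idx <- which(seg$analyzed)
  lab <- seg$labels[idx]
  code <- ifelse(is.na(lab), 0L, lab)      # 0 = unassigned sentinel
  repeat {
    r <- rle(code)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) break
    s <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    span <- starts[s]:ends[s]
    if (s == 1L) {
      code[span] <- r$values[s + 1L]
    } else if (s == length(r$lengths)) {
      code[span] <- r$values[s - 1L]
    } else {
      len <- r$lengths[s]
      first <- floor(len / 2)
      if (first > 0L) code[span[seq_len(first)]] <- r$values[s - 1L]
      code[span[(first + 1L):len]] <- r$values[s + 1L]
    }
  }
  lab <- ifelse(code == 0L, NA_integer_, code)
  seg$labels[idx] <- lab
  seg$corr <- segment_corr(seg$labels, seg$fit_corr,
                           seg$polarity == "invariant")
  seg
}

#' Per-state temporal statistics of a finalized segmentation
#'
#' GEV of state k is the GFP-weighted squared correlation of its samples with
#' its template, normalized by the total squared GFP over the analyzed range:
#' sum over labeled samples of (gfp_t * corr_t)^2 / sum over analyzed samples
#' of gfp_t^2. Coverage is the fraction of analyzed samples labeled k;
#' occurrence the number of maximal runs of k per analyzed second; mean
#' duration the average run length in ms. Runs touching the edges of the
#' analyzed range are censored: excluded from occurrence and duration but
#' included in coverage and GEV.
#'
#' @param seg a smoothed, min-segment-enforced `segmentation`.
#' @return object of class `"temporal_stats"`: list with `per_state`
#'   (data.frame: state, gev, coverage, occurrence, mean_duration_ms),
#'   `unassigned_fraction` and `gev_total`.
#' @export
temporal_stats <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  idx <- which(seg$analyzed)
  if (length(idx) == 0L) stop("no analyzed samples")
  lab <- seg$labels[idx]
  corr <- seg$corr[idx]
  g <- seg$gfp_trace[idx]
  denom <- sum(g^2)
  dur_s <- length(idx) / seg$sr

  code <- ifelse(is.na(lab), 0L, lab)
  r <- rle(code)
  nrun <- length(r$lengths)
  edge <- c(TRUE, rep(FALSE, max(0L, nrun - 2L)),
            if (nrun > 1L) TRUE)

  per <- data.frame(state = seq_len(seg$k), gev = 0, coverage = 0,
                    occurrence = 0, mean_duration_ms = NA_real_)
  for (k in seq_len(seg$k)) {
    m <- !is.na(lab) & lab == k
    per$gev[k] <- if (denom > 0) sum((g[m] * corr[m])^2) / denom else 0
    per$coverage[k] <- mean(m)
    interior <- which(r$values == k & !edge)
    per$occurrence[k] <- length(interior) / dur_s
    if (length(interior))
      per$mean_duration_ms[k] <- mean(r$lengths[interior]) * 1000 / seg$sr
  }
  structure(list(per_state = per,
                 unassigned_fraction = mean(is.na(lab)),
                 gev_total = sum(per$gev)),
            class = "temporal_stats")
}

#' @export
print.temporal_stats <- function(x, ...) {
  print(x$per_state, row.names = FALSE)
  cat(sprintf("unassigned fraction: %.3f, total GEV: %.3f\n",
              x$unassigned_fraction, x$gev_total))
  invisible(x)
}
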