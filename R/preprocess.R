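#' Spatial filter (outlier-trimmed neighborhood mean)
#'
#' Smooths topographies and removes topographic outliers: for each sample and
#' channel, the output value is the mean of the set {channel value, its k
#' neighbors' values} after discarding that set's single maximum and single
#' minimum. The average reference is re-applied afterwards.
#'
#' @param rec a recording (continuous or epoched).
#' @param graph a `neighbor_graph` whose channel count matches the recording;
#'   built from `rec$channel_positions` (k = 6) when omitted.
#' @return filtered recording.
#' @export
spatial_filter <- function(rec, graph = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(graph)) {
    if (is.null(rec$channel_positions))
      stop("no neighbor graph supplied and recording has no channel positions")
    graph <- neighbor_graph(rec$channel_positions)
  }
  if (nrow(graph$neighbors) != nrow(rec$data))
    stop("graph channel count does not match recording")
  if (graph$k < 2L)
    stop("spatial_filter requires k_neighbors >= 2 (trimming would empty the set)")
  rec$data <- trimmed_neighborhood_mean(rec$data, graph, include_self = TRUE)
  average_reference(rec)
}

# Min/max-trimmed mean over each channel's neighborhood, all samples at once.
# include_self = FALSE averages over neighbors only (epoch-wise interpolation
# of a known-bad channel).
trimmed_neighborhood_mean <- function(data, graph, include_self = TRUE,
                                      channels = seq_len(nrow(data))) {
  out <- data
  for (i in channels) {
    idx <- if (include_self) c(i, graph$neighbors[i, ]) else graph$neighbors[i, ]
    rows <- lapply(idx, function(j) data[j, ])
    tot <- Reduce(`+`, rows)
    hi <- Reduce(pmax, rows)
    lo <- Reduce(pmin, rows)
    out[i, ] <- (tot - hi - lo) / (length(idx) - 2L)
  }
  out
}

#' Extract topographies at GFP peaks
#'
#' Returns topographies at strict local maxima of the GFP time series
#' (GFP[t-1] < GFP[t] > GFP[t+1]); plateaus and endpoints never qualify.
#'
#' @param rec a continuous recording with at least 3 samples.
#' @return list with `maps` (channels x n_peaks matrix) and `index`
#'   (1-based sample indices of the peaks, in temporal order).
#' @export
extract_gfp_peaks <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$kind != "continuous") stop("extract_gfp_peaks expects a continuous recording")
  n <- ncol(rec$data)
  if (n < 3L) stop("need at least 3 samples")
  g <- gfp_series(rec)
  mid <- 2:(n - 1L)
  idx <- mid[g[mid] > g[mid - 1L] & g[mid] > g[mid + 1L]]
  list(maps = rec$data[, idx, drop = FALSE], index = idx)
}

#' Trim a continuous recording to its first seconds
#'
#' @param rec continuous recording.
#' @param seconds duration to keep (157 by default, the common study length).
#' @return recording with the first `seconds * sr` samples.
#' @export
trim_continuous <- function(rec, seconds = 157) {
  stopifnot(inherits(rec, "recording"), rec$kind == "continuous")
  keep <- round(seconds * rec$sr)
  have <- ncol(rec$data)
  if (have < keep)
    stop(sprintf("recording too short: has %.3f s, need %g s (short by %.3f s)",
                 have / rec$sr, seconds, (keep - have) / rec$sr))
  rec$data <- rec$data[, seq_len(keep), drop = FALSE]
  rec
}

#' Normalize a recording by its median GFP
#'
#' Divides every sample by the median of the per-sample GFP series so the
#' output's median GFP is 1; removes between-participant differences in
#' overall scalp potential (skull conductivity etc.).
#'
#' @param rec a recording.
#' @return normalized recording.
#' @export
normalize_gfp_median <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  med <- stats::median(gfp_series(rec))
  if (med <= 0) stop("median GFP is zero; cannot normalize")
  rec$data <- rec$data / med
  rec
}

#' Reject or repair artifacted epochs
#'
#' Flags, per epoch, channels that (1) exceed `amp_limit` in absolute
#' amplitude, (2) exceed `p2p_limit` peak-to-peak within sliding windows of
#' `p2p_window` ms stepped by `p2p_step` ms, or (3) are improbable under a
#' kernel estimate of the channel's amplitude distribution across epochs
#' (local) or of all channels pooled (global), beyond `joint_prob_sd` SDs.
#' Epochs with at least `channel_threshold` offending channels are dropped;
#' epochs with fewer have just those channels replaced, for that epoch only,
#' by the trimmed neighborhood mean of their neighbors.
#'
#' @param rec epoched recording.
#' @param amp_limit absolute amplitude limit in uV (100 rest / 150 task).
#' @param p2p_limit peak-to-peak limit in uV (`Inf` disables; rest default).
#' @param p2p_window,p2p_step sliding-window length and step, ms.
#' @param joint_prob_sd SD threshold for the joint-probability criterion
#'   (`Inf` disables).
#' @param channel_threshold minimum offending-channel count that drops the
#'   whole epoch (default 10).
#' @param graph neighbor graph used for channel repair; from positions if
#'   omitted.
#' @return list with `recording` (epochs kept, bad channels repaired) and
#'   `report` (data.frame: epoch, n_offending, decision, channels).
#' @export
reject_epochs <- function(rec, amp_limit = 100, p2p_limit = Inf,
                          p2p_window = 200, p2p_step = 20,
                          joint_prob_sd = 3, channel_threshold = 10,
                          graph = NULL) {
  stopifnot(inherits(rec, "recording"), rec$kind == "epoched")
  arr <- epoch_array(rec)
  nc <- dim(arr)[1]; ns <- dim(arr)[2]; ne <- dim(arr)[3]
  offend <- matrix(FALSE, nc, ne)

  # (1) absolute amplitude
  if (is.finite(amp_limit))
    offend <- offend | apply(abs(arr), c(1, 3), max) > amp_limit

  # (2) sliding-window peak-to-peak
  if (is.finite(p2p_limit)) {
    w <- round(p2p_window * rec$sr / 1000)
    if (w < 2L) stop("p2p_window shorter than 2 samples")
    s <- max(1L, round(p2p_step * rec$sr / 1000))
    starts <- seq(1L, max(1L, ns - w + 1L), by = s)
    for (e in seq_len(ne)) {
      x <- arr[, , e]
      p2p <- rep(0, nc)
      for (st in starts) {
        seg <- x[, st:min(ns, st + w - 1L), drop = FALSE]
        p2p <- pmax(p2p, apply(seg, 1L, max) - apply(seg, 1L, min))
      }
      offend[, e] <- offend[, e] | p2p > p2p_limit
    }
  }

  # (3) joint probability, local (per channel) and global (pooled)
  if (is.finite(joint_prob_sd) && ne >= 3L) {
    logp <- function(values, pooled) {
      d <- stats::density(pooled, n = 512)
      px <- stats::approx(d$x, d$y, xout = values, rule = 2)$y
      mean(log(pmax(px, 1e-12)))
    }
    lp_local <- matrix(0, nc, ne)
    for (i in seq_len(nc)) {
      pooled <- as.vector(arr[i, , ])
      for (e in seq_len(ne)) lp_local[i, e] <- logp(arr[i, , e], pooled)
    }
    pooled_all <- as.vector(arr)
    lp_global <- matrix(0, nc, ne)
    dg <- stats::density(pooled_all, n = 512)
    for (e in seq_len(ne)) for (i in seq_len(nc)) {
      px <- stats::approx(dg$x, dg$y, xout = arr[i, , e], rule = 2)$y
      lp_global[i, e] <- mean(log(pmax(px, 1e-12)))
    }
    zflag <- function(lp) {
      mu <- rowMeans(lp); sd <- apply(lp, 1L, stats::sd)
      sd[sd == 0] <- Inf
      (mu - lp) / sd > joint_prob_sd   # improbably low probability
    }
    offend <- offend | zflag(lp_local) | zflag(lp_global)
  }

  n_off <- colSums(offend)
  drop <- n_off >= channel_threshold
  fix <- n_off > 0L & !drop

  if (any(fix)) {
    if (is.null(graph)) {
      if (is.null(rec$channel_positions))
        stop("channel repair needs a neighbor graph or channel positions")
      graph <- neighbor_graph(rec$channel_positions)
    }
    for (e in which(fix)) {
      bad <- which(offend[, e])
      arr[, , e] <- trimmed_neighborhood_mean(arr[, , e], graph,
                                              include_self = FALSE,
                                              channels = bad)
    }
  }

  report <- data.frame(
    epoch = seq_len(ne),
    n_offending = n_off,
    decision = ifelse(drop, "dropped", ifelse(fix, "interpolated", "kept")),
    channels = vapply(seq_len(ne), function(e)
      paste(which(offend[, e]), collapse = ","), character(1)),
    stringsAsFactors = FALSE)

  keep <- !drop
  out <- rec
  out$data <- matrix(arr[, , keep, drop = FALSE],
                     nrow = nc, ncol = ns * sum(keep))
  out$n_epochs <- sum(keep)
  list(recording = out, report = report)
}
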