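#' Construct a Recording
#'
#' A `Recording` holds a channels x samples matrix of scalp potentials (in
#' microvolts) together with its sampling rate, channel metadata and, for
#' epoched data, the epoch structure. Continuous recordings store samples in
#' acquisition order; epoched recordings store trials concatenated along the
#' sample axis with a shared within-epoch time axis.
#'
#' @param data numeric matrix, channels x samples (continuous) or
#'   channels x (samples_per_epoch * n_epochs) (epoched).
#' @param sr sampling rate in Hz (default 250).
#' @param channel_names optional character vector of channel identifiers.
#' @param channel_positions optional n_channels x 3 matrix of unit-sphere
#'   sensor coordinates (rows are normalized to unit norm within 1e-6).
#' @param kind `"continuous"` or `"epoched"`.
#' @param n_epochs number of epochs (epoched only).
#' @param time_zero 1-based within-epoch sample index of the response event
#'   (epoched only); defines the epoch time axis in ms relative to that sample.
#' @return object of class `"recording"`.
#' @export
recording <- function(data, sr = 250, channel_names = NULL,
                      channel_positions = NULL,
                      kind = c("continuous", "epoched"),
                      n_epochs = NULL, time_zero = NULL) {
  kind <- match.arg(kind)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("recording data contains non-finite values")
  if (!is.numeric(sr) || length(sr) != 1L || sr <= 0)
    stop("sr must be a positive scalar")
  nc <- nrow(data)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nc))
  if (length(channel_names) != nc)
    stop("channel_names length does not match channel count")
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    if (nrow(channel_positions) != nc || ncol(channel_positions) != 3L)
      stop("channel_positions must be n_channels x 3")
    nrm <- sqrt(rowSums(channel_positions^2))
    if (any(abs(nrm - 1) > 1e-6))
      channel_positions <- channel_positions / nrm
  }
  if (kind == "epoched") {
    if (is.null(n_epochs) || n_epochs < 1L)
      stop("epoched recording requires n_epochs")
    n_epochs <- as.integer(n_epochs)
    if (ncol(data) %% n_epochs != 0L)
      stop("sample count is not a multiple of n_epochs")
    if (is.null(time_zero)) time_zero <- 1L
  } else {
    n_epochs <- NULL
    time_zero <- NULL
  }
  structure(list(data = data, sr = sr, channel_names = channel_names,
                 channel_positions = channel_positions, kind = kind,
                 n_epochs = n_epochs,
                 time_zero = if (!is.null(time_zero)) as.integer(time_zero)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d channels, %d samples, %g Hz, %s%s>\n",
              nrow(x$data), ncol(x$data), x$sr, x$kind,
              if (x$kind == "epoched")
                sprintf(", %d epochs of %d", x$n_epochs, n_epoch_samples(x))
              else ""))
  invisible(x)
}

n_epoch_samples <- function(rec) {
  stopifnot(rec$kind == "epoched")
  ncol(rec$data) %/% rec$n_epochs
}

#' Within-epoch time axis in ms
#'
#' @param rec an epoched recording.
#' @return numeric vector, one value per within-epoch sample, t = 0 at
#'   `time_zero`.
#' @export
epoch_times <- function(rec) {
  ns <- n_epoch_samples(rec)
  (seq_len(ns) - rec$time_zero) * 1000 / rec$sr
}

#' Split an epoched recording into a 3-d array
#'
#' @param rec an epoched recording.
#' @return array channels x samples_per_epoch x epochs.
#' @export
epoch_array <- function(rec) {
  ns <- n_epoch_samples(rec)
  array(rec$data, dim = c(nrow(rec$data), ns, rec$n_epochs),
        dimnames = list(rec$channel_names, NULL, NULL))
}

#' Average reference a topography or recording
#'
#' Subtracts the instantaneous mean over channels, so every topography (column)
#' becomes zero-mean.
#'
#' @param x numeric vector (one topography), numeric matrix
#'   (channels x samples), or a recording.
#' @return same shape as the input, re-referenced.
#' @export
average_reference <- function(x) {
  if (inherits(x, "recording")) {
    x$data <- average_reference(x$data)
    return(x)
  }
  if (!all(is.finite(x))) stop("non-finite values in input")
  if (is.matrix(x)) {
    return(sweep(x, 2L, colMeans(x)))
  }
  x - mean(x)
}

#' Global field power of one topography
#'
#' GFP is the spatial standard deviation of an average-referenced topography:
#' sqrt(mean(v^2)) for a zero-mean potential vector v.
#'
#' @param values numeric vector of per-channel potentials (average-referenced).
#' @return non-negative scalar (same units as the input, microvolts).
#' @export
gfp <- function(values) {
  if (length(values) < 2L) stop("gfp needs at least 2 channels")
  if (!all(is.finite(values))) stop("non-finite values in topography")
  sqrt(mean(values^2))
}

#' Per-sample GFP series of a recording
#'
#' @param rec a recording (or channels x samples matrix).
#' @return numeric vector, one GFP value per sample.
#' @export
gfp_series <- function(rec) {
  m <- if (inherits(rec, "recording")) rec$data else rec
  if (nrow(m) < 2L) stop("gfp needs at least 2 channels")
  sqrt(colMeans(m^2))
}
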