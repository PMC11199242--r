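#' Write a recording in the plain-matrix format
#'
#' Tab-separated text: one row per channel (first column the channel name),
#' one column per sample, header row giving the sample index. A YAML sidecar
#' (`<path>.yaml`) stores the sampling rate, kind, epoch structure and sensor
#' positions. Values round-trip exactly through [read_recording_matrix()].
#'
#' @param rec a recording.
#' @param path output file (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_recording_matrix <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  vals <- sprintf("%.17g", rec$data)      # full double precision
  dim(vals) <- dim(rec$data)
  lines <- c(paste(c("channel", paste0("s", seq_len(ncol(rec$data)))),
                   collapse = "\t"),
             vapply(seq_len(nrow(vals)), function(i)
               paste(c(rec$channel_names[i], vals[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  meta <- list(sr = rec$sr, kind = rec$kind,
               channel_names = as.list(rec$channel_names))
  if (!is.null(rec$n_epochs)) meta$n_epochs <- rec$n_epochs
  if (!is.null(rec$time_zero)) meta$time_zero <- rec$time_zero
  if (!is.null(rec$channel_positions))
    meta$channel_positions <- lapply(seq_len(nrow(rec$channel_positions)),
                                     function(i) as.list(unname(rec$channel_positions[i, ])))
  yaml::write_yaml(meta, paste0(path, ".yaml"), precision = 17)
  invisible(path)
}

#' Read a plain-matrix recording
#'
#' @param path file written by [write_recording_matrix()] (the `.yaml`
#'   sidecar must sit next to it).
#' @return a recording.
#' @export
read_recording_matrix <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  dt <- data.table::fread(path, sep = "\t")
  ch <- dt[[1L]]
  dat <- as.matrix(dt[, -1L])
  dimnames(dat) <- NULL
  pos <- if (!is.null(meta$channel_positions))
    do.call(rbind, lapply(meta$channel_positions, unlist))
  recording(dat, sr = meta$sr, channel_names = as.character(ch),
            channel_positions = pos, kind = meta$kind,
            n_epochs = meta$n_epochs, time_zero = meta$time_zero)
}

#' Write microstate template maps as TSV
#'
#' First line is a comment carrying the polarity mode and level; then a
#' header and one row per channel, one column per microstate.
#'
#' @param set a `microstate_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_maps_tsv <- function(set, path) {
  stopifnot(inherits(set, "microstate_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# polarity=%s level=%s", set$polarity, set$level), con)
  header <- c("channel", paste0("ms", seq_len(set$k)))
  writeLines(paste(header, collapse = "\t"), con)
  for (i in seq_len(nrow(set$maps)))
    writeLines(paste(c(paste0("ch", i),
                       format(set$maps[i, ], digits = 17, trim = TRUE,
                              scientific = TRUE)),
                     collapse = "\t"), con)
  invisible(path)
}

#' Read microstate template maps from TSV
#'
#' @param path file written by [write_maps_tsv()].
#' @return a `microstate_set`.
#' @export
read_maps_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  polarity <- sub(".*polarity=(\\w+).*", "\\1", first)
  level <- sub(".*level=(\\w+).*", "\\1", first)
  dt <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  maps <- as.matrix(dt[, -1L, drop = FALSE])
  dimnames(maps) <- NULL
  microstate_set(maps, polarity = polarity, level = level)
}

#' Write a segmentation as TSV
#'
#' Columns: sample (1-based), time_ms, label (NA = unassigned), corr, gfp.
#'
#' @param seg a `segmentation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(seg, path) {
  stopifnot(inherits(seg, "segmentation"))
  dt <- data.table::data.table(sample = seq_along(seg$labels),
                               time_ms = seg$time_ms, label = seg$labels,
                               corr = seg$corr, gfp = seg$gfp_trace)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Write temporal statistics as JSON
#'
#' @param ts a `temporal_stats` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stats_json <- function(ts, path) {
  stopifnot(inherits(ts, "temporal_stats"))
  jsonlite::write_json(list(per_state = ts$per_state,
                            unassigned_fraction = ts$unassigned_fraction,
                            gev_total = ts$gev_total),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

pad_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

#' Write a continuous recording as EDF
#'
#' European Data Format: 16-bit samples with per-channel physical scaling,
#' one-second data records. Amplitude resolution is bounded by the int16
#' quantization, so the round trip is close but not bit-exact.
#'
#' @param rec continuous recording; the sample count must be a multiple of
#'   `sr` (whole seconds).
#' @param path output `.edf` file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"), rec$kind == "continuous")
  nc <- nrow(rec$data); n <- ncol(rec$data)
  spr <- as.integer(round(rec$sr))
  if (n %% spr != 0L) stop("sample count must be a whole number of seconds")
  n_rec <- n %/% spr
  pmin_ <- apply(rec$data, 1L, min); pmax_ <- apply(rec$data, 1L, max)
  pad <- pmax(1e-6, (pmax_ - pmin_) * 0.001)
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wr("0", 8); wr("synthetic", 80); wr("microstatr export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (1L + nc), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(nc, 4)
  for (f in list(list(rec$channel_names, 16), list(rep("", nc), 80),
                 list(rep("uV", nc), 8),
                 list(formatC(pmin_, format = "g", digits = 6), 8),
                 list(formatC(pmax_, format = "g", digits = 6), 8),
                 list(rep(dmin, nc), 8), list(rep(dmax, nc), 8),
                 list(rep("", nc), 80), list(rep(spr, nc), 8),
                 list(rep("", nc), 32)))
    for (i in seq_len(nc)) wr(f[[1]][i], f[[2]])
  # physical min/max as re-read from the ASCII header, for exact scaling
  pmin_r <- as.numeric(formatC(pmin_, format = "g", digits = 6))
  pmax_r <- as.numeric(formatC(pmax_, format = "g", digits = 6))
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr + seq_len(spr)
    for (i in seq_len(nc)) {
      x <- rec$data[i, cols]
      dig <- round((x - pmin_r[i]) / (pmax_r[i] - pmin_r[i]) *
                     (dmax - dmin) + dmin)
      writeBin(as.integer(pmin(dmax, pmax(dmin, dig))), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a continuous EDF recording
#'
#' @param path `.edf` file.
#' @param channel_positions optional n x 3 montage to attach.
#' @return a recording.
#' @export
read_edf <- function(path, channel_positions = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)          # transducer
  for (i in seq_len(nc)) rd(8)           # phys dim
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)          # prefiltering
  spr <- vapply(seq_len(nc), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nc)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-signal sampling rates are not supported")
  sr <- spr[1L] / dur
  dat <- matrix(0, nc, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    cols <- (r - 1L) * spr[1L] + seq_len(spr[1L])
    for (i in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      dat[i, cols] <- (dig - dmin[i]) / (dmax[i] - dmin[i]) *
        (pmax_[i] - pmin_[i]) + pmin_[i]
    }
  }
  recording(dat, sr = sr, channel_names = labels,
            channel_positions = channel_positions)
}

#' Write a continuous recording in BrainVision format
#'
#' Produces `.vhdr` (text header), `.vmrk` (minimal marker file) and `.eeg`
#' (IEEE float32, multiplexed) next to each other.
#'
#' @param rec continuous recording.
#' @param path path of the `.vhdr` file.
#' @return `path`, invisibly.
#' @export
write_brainvision <- function(rec, path) {
  stopifnot(inherits(rec, "recording"), rec$kind == "continuous")
  base <- sub("\\.vhdr$", "", path)
  stem <- basename(base)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", stem, ".eeg"),
           paste0("MarkerFile=", stem, ".vmrk"),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nrow(rec$data)),
           paste0("SamplingInterval=", format(1e6 / rec$sr, digits = 12)),
           "[Binary Infos]",
           "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)),
                   rec$channel_names))
  writeLines(hdr, path)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]", paste0("DataFile=", stem, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), paste0(base, ".vmrk"))
  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a BrainVision recording
#'
#' Supports binary IEEE float32 / int16 data in multiplexed or vectorized
#' orientation.
#'
#' @param path `.vhdr` file (`.eeg` must sit next to it).
#' @param channel_positions optional montage to attach.
#' @return a recording.
#' @export
read_brainvision <- function(path, channel_positions = NULL) {
  lines <- readLines(path, warn = FALSE)
  get <- function(key, default = NULL) {
    hit <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (length(hit) == 0L) return(default)
    sub(paste0("^", key, "="), "", hit[1L])
  }
  nc <- as.integer(get("NumberOfChannels"))
  si <- as.numeric(get("SamplingInterval"))
  fmt <- get("BinaryFormat", "IEEE_FLOAT_32")
  orient <- get("DataOrientation", "MULTIPLEXED")
  data_file <- file.path(dirname(path), get("DataFile"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  names_ <- vapply(parts, `[`, character(1), 1L)
  res <- vapply(parts, function(p)
    if (length(p) >= 3L && nzchar(p[3L])) as.numeric(p[3L]) else 1,
    numeric(1))
  sz <- file.size(data_file)
  if (fmt == "IEEE_FLOAT_32") {
    n_vals <- sz %/% 4L
    raw <- readBin(data_file, "numeric", n = n_vals, size = 4L,
                   endian = "little")
  } else if (fmt == "INT_16") {
    n_vals <- sz %/% 2L
    raw <- readBin(data_file, "integer", n = n_vals, size = 2L,
                   signed = TRUE, endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt)
  ns <- n_vals %/% nc
  dat <- if (orient == "MULTIPLEXED") matrix(raw, nc, ns)
  else t(matrix(raw, ns, nc))
  dat <- dat * res
  recording(dat, sr = 1e6 / si, channel_names = names_,
            channel_positions = channel_positions)
}

#' Write per-participant ERN scores as CSV
#'
#' @param scores data.frame (id, go_mean, nogo_mean, residualized).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ern_scores_csv <- function(scores, path) {
  data.table::fwrite(data.table::as.data.table(scores), path)
  invisible(path)
}
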