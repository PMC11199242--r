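#' Generate planted microstate template maps
#'
#' Draws K spatially smooth scalp maps on a synthetic unit-sphere montage
#' (sums of spherical Gaussian bumps), average-referenced and unit-normalized,
#' mutually near-orthogonal: pairwise |spatial correlation| <= 0.3. Candidates
#' violating the bound are rejected and redrawn; generation is deterministic
#' per seed.
#'
#' @param n_channels montage size (default 32; 104 mirrors the study's
#'   retained high-density montage).
#' @param K number of maps (<= n_channels - 1).
#' @param smoothness angular width (radians) of the spatial bumps
#'   (default 0.9; larger = smoother, more global maps).
#' @param seed integer seed.
#' @param max_corr orthogonality bound (default 0.3).
#' @return `microstate_set` with attributes `positions` (the montage) and
#'   `graph` (its k = 6 neighbor graph).
#' @export
make_template_maps <- function(n_channels = 32, K, smoothness = 0.9,
                               seed = 1, max_corr = 0.3) {
  if (K > n_channels - 1) stop("K must be at most n_channels - 1")
  pos <- sphere_layout(n_channels)
  draw_map <- function() {
    m <- numeric(n_channels)
    n_bumps <- 3L
    centers <- pos[sample.int(n_channels, n_bumps), , drop = FALSE]
    w <- stats::rnorm(n_bumps)
    for (b in seq_len(n_bumps)) {
      ang <- acos(pmin(1, pmax(-1, pos %*% centers[b, ])))
      m <- m + w[b] * exp(-(ang / smoothness)^2)
    }
    m <- m - mean(m)
    nrm <- sqrt(sum(m^2))
    if (nrm == 0) return(NULL)
    m / nrm
  }
  maps <- local_seed(seed, {
    acc <- matrix(0, n_channels, 0)
    fails <- 0L
    while (ncol(acc) < K) {
      cand <- draw_map()
      if (is.null(cand)) next
      if (ncol(acc) > 0L && max(abs(crossprod(acc, cand))) > max_corr) {
        fails <- fails + 1L
        if (fails <= 50L) next
        # fall back to Gram-Schmidt: a projected combination of smooth
        # fields is still smooth
        cand <- cand - acc %*% crossprod(acc, cand)
        cand <- cand - mean(cand)
        nrm <- sqrt(sum(cand^2))
        if (nrm < 1e-6)
          stop("could not achieve pairwise |r| <= ", max_corr,
               " for K = ", K, " maps (infeasible orthogonality)")
        cand <- cand / nrm
        if (max(abs(crossprod(acc, cand))) > max_corr) next
      }
      acc <- cbind(acc, cand)
      fails <- 0L
    }
    acc
  })
  out <- microstate_set(maps, polarity = "invariant")
  attr(out, "positions") <- pos
  attr(out, "graph") <- neighbor_graph(pos)
  out
}

# Hidden state sequence with truncated-normal dwell times (floor in ms).
# Per-state mean dwell is scaled by K * coverage so that time shares
# approximate the requested coverages.
make_label_sequence <- function(n, sr, K, mean_dwell_ms, coverage,
                                dwell_sd_frac = 0.4, floor_ms = 40) {
  labels <- integer(n)
  seg_state <- integer(0)
  seg_len <- integer(0)
  t <- 1L
  cur <- sample.int(K, 1L, prob = coverage)
  while (t <= n) {
    mu <- mean_dwell_ms * K * coverage[cur]
    dwell_ms <- max(floor_ms, stats::rnorm(1L, mu, dwell_sd_frac * mu))
    len <- min(n - t + 1L, max(1L, round(dwell_ms * sr / 1000)))
    labels[t:(t + len - 1L)] <- cur
    seg_state <- c(seg_state, cur); seg_len <- c(seg_len, len)
    t <- t + len
    if (K > 1L) {
      p <- rep(1, K); p[cur] <- 0    # uniform next-state; time share set by dwell
      cur <- sample.int(K, 1L, prob = p)
    }
  }
  list(labels = labels, seg_state = seg_state, seg_len = seg_len)
}

# Positive, slowly wiggling GFP envelope (many local maxima): rectified
# Gaussian-smoothed white noise plus a floor.
gfp_envelope <- function(n, sr, kernel_ms = 20, floor_level = 0.25) {
  sd_samp <- max(1, round(kernel_ms * sr / 1000 / 4))
  half <- 4L * sd_samp
  kern <- stats::dnorm(-half:half, sd = sd_samp)
  kern <- kern / sum(kern)
  x <- stats::rnorm(n + 2L * half)
  s <- stats::filter(x, kern, sides = 2L)
  s <- s[(half + 1L):(half + n)]
  s <- s / stats::sd(s)
  floor_level + abs(s)
}

#' Simulate a resting-state recording with known ground truth
#'
#' A hidden state sequence (truncated-normal dwell times, floor 40 ms) emits
#' the corresponding template topography scaled by a positive GFP envelope,
#' with a random polarity per segment, plus spatially white sensor noise at
#' the stated amplitude-to-noise ratio. Output is average-referenced.
#'
#' @param states a `microstate_set` of planted maps (e.g. from
#'   [make_template_maps()]), with the montage attached.
#' @param duration_s recording length (default 157 s, the study's trim).
#' @param sr sampling rate (default 250 Hz).
#' @param mean_dwell_ms mean microstate dwell (default 100 ms; quasi-stable
#'   periods are typically under ~150 ms). Must be >= 40.
#' @param snr amplitude-to-noise ratio: mean signal GFP over noise GFP
#'   (default 10).
#' @param coverage length-K target time shares (default uniform).
#' @param base_gfp_uV mean signal GFP in microvolts (default 10).
#' @param seed integer seed.
#' @return list with `recording` and `truth` (planted maps, per-sample
#'   `label_sequence`, realized coverage, segment table, polarity signs,
#'   dwell/noise parameters, seed).
#' @export
simulate_resting <- function(states, duration_s = 157, sr = 250,
                             mean_dwell_ms = 100, snr = 10,
                             coverage = NULL, base_gfp_uV = 10, seed = 1) {
  stopifnot(inherits(states, "microstate_set"))
  if (mean_dwell_ms < 40) stop("mean_dwell_ms must be >= 40")
  K <- states$k
  nc <- nrow(states$maps)
  if (is.null(coverage)) coverage <- rep(1 / K, K)
  coverage <- coverage / sum(coverage)
  n <- round(duration_s * sr)
  sim <- local_seed(seed, {
    sq <- make_label_sequence(n, sr, K, mean_dwell_ms, coverage)
    env <- gfp_envelope(n, sr)
    pol <- sample(c(-1, 1), length(sq$seg_len), replace = TRUE)
    pol_t <- rep(pol, sq$seg_len)
    amp <- base_gfp_uV * sqrt(nc)     # unit-norm map -> GFP 1/sqrt(nc)
    signal <- states$maps[, sq$labels, drop = FALSE] *
      rep(amp * env * pol_t, each = nc)
    noise_sd <- base_gfp_uV * mean(env) / snr
    noise <- matrix(stats::rnorm(nc * n, sd = noise_sd), nc, n)
    list(sq = sq, pol = pol, data = signal + noise, noise_sd = noise_sd)
  })
  rec <- recording(average_reference(sim$data), sr = sr,
                   channel_positions = attr(states, "positions"))
  truth <- list(true_maps = states,
                label_sequence = sim$sq$labels,
                coverage = as.numeric(table(factor(sim$sq$labels,
                                                   levels = seq_len(K))) / n),
                segments = data.frame(state = sim$sq$seg_state,
                                      length = sim$sq$seg_len,
                                      polarity = sim$pol),
                mean_dwell_ms = mean_dwell_ms, snr = snr,
                noise_sd = sim$noise_sd, seed = seed)
  list(recording = rec, truth = truth)
}

# Spatially smooth map with a focal negative pole at the vertex sensor;
# scaled so the mean over its own (mean - 1 SD) pole channels is -1.
make_ern_map <- function(positions, width = 0.8) {
  ang <- acos(pmin(1, pmax(-1, positions %*% positions[1L, ])))
  m <- -exp(-(ang / width)^2)
  m <- m - mean(m)
  pole <- m < mean(m) - stats::sd(m)
  m / abs(mean(m[pole]))
}

#' Simulate go/no-go response-locked epochs with a planted error component
#'
#' Both conditions share the same background generative process (microstate
#' sequence plus sensor noise, epoch by epoch); erroneous no-go trials
#' additionally carry a central-negative component of the given amplitude
#' over `ern_window_ms`. The component map is scaled so that the mean over
#' its negative-pole channels equals `ern_amplitude_uV`. Reaction times are
#' uniform on [300, 900] ms with a configurable fraction pushed out of the
#' 100-2000 ms plausibility range to exercise trial filtering.
#'
#' @param states background `microstate_set` (montage attached).
#' @param n_go,n_nogo trial counts (defaults 120 and 80, the task design).
#' @param ern_amplitude_uV planted component amplitude (default -5).
#' @param ern_window_ms component window (default `c(-64, 108)`).
#' @param snr amplitude-to-noise ratio of the background (default 10).
#' @param sr sampling rate (default 250).
#' @param out_of_range_frac fraction of trials with implausible RTs
#'   (default 0.05).
#' @param base_gfp_uV background signal scale (default 10).
#' @param seed integer seed.
#' @return list with `epochs_go`, `epochs_nogo` (epoched recordings,
#'   t = 0 at the button press), `rt` (data.frame: condition, trial, rt_ms,
#'   out_of_range) and `truth` (component map, pole channels, amplitude,
#'   window, seed).
#' @export
simulate_gonogo <- function(states, n_go = 120, n_nogo = 80,
                            ern_amplitude_uV = -5,
                            ern_window_ms = c(-64, 108), snr = 10, sr = 250,
                            out_of_range_frac = 0.05, base_gfp_uV = 10,
                            seed = 1) {
  stopifnot(inherits(states, "microstate_set"))
  if (ern_window_ms[1] < -500 || ern_window_ms[2] > 800)
    stop("ern_window_ms must lie within [-500, 800]")
  pos <- attr(states, "positions")
  if (is.null(pos)) stop("states carries no montage (positions attribute)")
  nc <- nrow(states$maps)
  time_ms <- seq(-500, 800, by = 1000 / sr)
  ns <- length(time_ms)
  t0 <- which(time_ms == 0)
  K <- states$k

  ern_map <- make_ern_map(pos)
  in_win <- time_ms >= ern_window_ms[1] & time_ms <= ern_window_ms[2]

  sim <- local_seed(seed, {
    gen_epochs <- function(n_trials, with_ern) {
      out <- matrix(0, nc, ns * n_trials)
      for (tr in seq_len(n_trials)) {
        sq <- make_label_sequence(ns, sr, K, 100, rep(1 / K, K))
        env <- gfp_envelope(ns, sr)
        pol <- rep(sample(c(-1, 1), length(sq$seg_len), replace = TRUE),
                   sq$seg_len)
        amp <- base_gfp_uV * sqrt(nc)
        bg <- states$maps[, sq$labels, drop = FALSE] *
          rep(amp * env * pol, each = nc)
        noise_sd <- base_gfp_uV * mean(env) / snr
        x <- bg + matrix(stats::rnorm(nc * ns, sd = noise_sd), nc, ns)
        # pole mean of ern_map is -1, so this puts ern_amplitude_uV (a
        # negative value) at the pole
        if (with_ern)
          x[, in_win] <- x[, in_win] - ern_map * ern_amplitude_uV
        out[, (tr - 1L) * ns + seq_len(ns)] <- x
      }
      out
    }
    go <- gen_epochs(n_go, FALSE)
    nogo <- gen_epochs(n_nogo, TRUE)
    n_all <- n_go + n_nogo
    rt <- stats::runif(n_all, 300, 900)
    n_bad <- round(out_of_range_frac * n_all)
    bad <- if (n_bad > 0) sample.int(n_all, n_bad) else integer(0)
    if (length(bad))
      rt[bad] <- ifelse(stats::runif(length(bad)) < 0.5,
                        stats::runif(length(bad), 0, 99),
                        stats::runif(length(bad), 2001, 3000))
    list(go = go, nogo = nogo, rt = rt, bad = bad)
  })

  mk <- function(dat, n_trials)
    recording(average_reference(dat), sr = sr, channel_positions = pos,
              kind = "epoched", n_epochs = n_trials, time_zero = t0)
  rt_tab <- data.frame(
    condition = rep(c("go_correct", "nogo_error"), c(n_go, n_nogo)),
    trial = c(seq_len(n_go), seq_len(n_nogo)),
    rt_ms = sim$rt,
    out_of_range = seq_len(n_go + n_nogo) %in% sim$bad)
  truth <- list(ern_map = ern_map,
                pole_channels = which(ern_map < mean(ern_map) -
                                        stats::sd(ern_map)),
                ern_amplitude_uV = ern_amplitude_uV,
                ern_window_ms = ern_window_ms, snr = snr, seed = seed)
  list(epochs_go = mk(sim$go, n_go), epochs_nogo = mk(sim$nogo, n_nogo),
       rt = rt_tab, truth = truth)
}

#' Simulate a participant-level cohort table with planted couplings
#'
#' Draws a per-participant latent error-processing strength and imposes the
#' requested linear couplings (correlations with the latent) on the
#' residualized ERN amplitude, the error-related microstate GEV and the
#' resting-state GEV of a designated state, plus age/sex covariates,
#' questionnaire totals and independent noise. With all effect sizes zero the
#' table's variables are mutually independent (null cohort).
#'
#' @param n_participants at least 20 (default 90, the study sample).
#' @param effect_sizes named numeric: `ern`, `error_gev`, `rest_gev`
#'   correlations (in [-1, 1]) with the latent strength (defaults all 0.5).
#' @param seed integer seed.
#' @return list with `table` (data.frame: id, age, sex, ern_residualized,
#'   error_gev, rest_gev, pas, bis, effortful_control) and `truth`
#'   (latent values, effect sizes, seed).
#' @export
simulate_cohort <- function(n_participants = 90,
                            effect_sizes = c(ern = 0.5, error_gev = 0.5,
                                             rest_gev = 0.5),
                            seed = 1) {
  if (n_participants < 20) stop("n_participants must be >= 20")
  es <- effect_sizes
  for (nm in c("ern", "error_gev", "rest_gev"))
    if (is.na(es[nm])) es[nm] <- 0
  couple <- function(z, r) r * z + sqrt(1 - r^2) * stats::rnorm(length(z))
  sim <- local_seed(seed, {
    n <- n_participants
    z <- stats::rnorm(n)
    list(z = z,
         age = stats::runif(n, 4.5, 9),
         sex = sample(c("F", "M"), n, replace = TRUE),
         ern = -4 - 2.5 * couple(z, es[["ern"]]),   # stronger processing -> more negative
         error_gev = 0.35 + 0.10 * couple(z, es[["error_gev"]]),
         rest_gev = 0.25 + 0.08 * couple(z, es[["rest_gev"]]),
         pas = round(pmax(0, 25 + 10 * stats::rnorm(n))),
         bis = round(pmax(0, 12 + 4 * stats::rnorm(n))),
         ec = 90 + 15 * stats::rnorm(n))
  })
  tab <- data.frame(id = sprintf("p%03d", seq_len(n_participants)),
                    age = sim$age, sex = sim$sex,
                    ern_residualized = sim$ern,
                    error_gev = sim$error_gev, rest_gev = sim$rest_gev,
                    pas = sim$pas, bis = sim$bis,
                    effortful_control = sim$ec,
                    stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(latent = sim$z, effect_sizes = es, seed = seed))
}
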