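#' Synthetic record configuration
#'
#' Parameters of the annotated ECG + accelerometer generator. Beats are
#' synthesized as concatenated subwave segments (ISO1, P, ISO2, QRS, ISO3,
#' T) with durations drawn from truncated normals, so the generator's state
#' path is exact ground truth for the segmentation HMM. Ectopic beats follow
#' the classical morphology criteria: a PVC has no P wave, a QRS wider than
#' 120 ms, a premature R-R interval (0.6-0.8 of the running mean) and a
#' large inverted T wave; an APC has a small early P wave with a prolonged
#' P-R interval and a premature R-R interval.
#'
#' @param duration_s record length in seconds.
#' @param fs ECG sampling rate in Hz (default 360).
#' @param hr_bpm mean heart rate in beats per minute.
#' @param rr_jitter_sd_ms R-R jitter standard deviation in ms.
#' @param pvc_rate,apc_rate per-beat ectopy probabilities in `[0, 1]`.
#' @param amp_mv named amplitudes in mV for `p`, `qrs`, `t` (defaults 0.15,
#'   1.0, 0.3, inside the 0.5-5.0 mV peak-to-peak range of skin ECG).
#' @param width_ms named mean subwave durations in ms.
#' @param powerline_mv,powerline_hz additive mains sinusoid.
#' @param baseline_mv,baseline_hz additive baseline wander sinusoid.
#' @param noise_sd_mv additive white noise.
#' @param motion_schedule data frame (`activity`, `start_s`, `end_s`)
#'   partitioning `[0, duration_s]`; default all standing.
#' @param motion_gain_mv amplitude (sd) of the band-limited 1-10 Hz motion
#'   artifact added to the ECG during walking entries.
#' @param accel_fs accelerometer sampling rate in Hz (default 50).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 60, fs = 360, hr_bpm = 75,
                         rr_jitter_sd_ms = 30,
                         pvc_rate = 0, apc_rate = 0,
                         amp_mv = c(p = 0.15, qrs = 1.0, t = 0.3),
                         width_ms = c(p = 90, iso2 = 60, qrs = 90,
                                      iso3 = 100, t = 160),
                         powerline_mv = 0, powerline_hz = 50,
                         baseline_mv = 0, baseline_hz = 0.25,
                         noise_sd_mv = 0,
                         motion_schedule = NULL,
                         motion_gain_mv = 0.8,
                         accel_fs = 50, seed = NULL) {
  if (pvc_rate < 0 || pvc_rate > 1 || apc_rate < 0 || apc_rate > 1 ||
      pvc_rate + apc_rate > 1)
    stop_input("ectopy rates must lie in [0, 1] and sum to at most 1")
  if (any(c(amp_mv, powerline_mv, baseline_mv, noise_sd_mv,
            motion_gain_mv) < 0))
    stop_input("amplitudes must be non-negative")
  if (is.null(motion_schedule))
    motion_schedule <- data.frame(activity = "standing", start_s = 0,
                                  end_s = duration_s)
  sched <- motion_schedule[order(motion_schedule$start_s), , drop = FALSE]
  if (abs(sched$start_s[1]) > 1e-9 ||
      abs(sched$end_s[nrow(sched)] - duration_s) > 1e-9 ||
      (nrow(sched) > 1 &&
         any(abs(sched$start_s[-1] - sched$end_s[-nrow(sched)]) > 1e-9)))
    stop_input("motion schedule must partition [0, duration_s]")
  if (!all(sched$activity %in% c("standing", "walking", "lying")))
    stop_input("unknown activity in motion schedule")
  structure(list(duration_s = duration_s, fs = fs, hr_bpm = hr_bpm,
                 rr_jitter_sd_ms = rr_jitter_sd_ms, pvc_rate = pvc_rate,
                 apc_rate = apc_rate, amp_mv = amp_mv, width_ms = width_ms,
                 powerline_mv = powerline_mv, powerline_hz = powerline_hz,
                 baseline_mv = baseline_mv, baseline_hz = baseline_hz,
                 noise_sd_mv = noise_sd_mv, motion_schedule = sched,
                 motion_gain_mv = motion_gain_mv, accel_fs = accel_fs,
                 seed = seed),
            class = "synth_config")
}

# truncated normal via inverse cdf, truncation at +-2 sd and a hard floor
rtnorm1 <- function(mean, sd, lo = mean - 2 * sd, hi = mean + 2 * sd,
                    floor_val = 20) {
  lo <- max(lo, floor_val)
  p <- runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

# raised-cosine bump over n samples peaking at amp; the exponent < 1
# steepens the flanks so the deflection occupies most of its nominal
# duration (keeps decoded run widths close to the true subwave widths)
bump <- function(n, amp, steep = 0.3) {
  if (n <= 0) return(numeric(0))
  t <- seq_len(n) - 0.5
  amp * (0.5 * (1 - cos(2 * pi * t / n)))^steep
}

# QRS morphology: steep monophasic deflection with a short plateau
qrs_shape <- function(n, amp) bump(n, amp, steep = 0.15)

# one beat: returns list(samples, states, segs) where segs holds per-segment
# sample counts in order ISO1,P,ISO2,QRS,ISO3,T (0 = absent)
synth_beat <- function(cfg, type, rr_target_ms) {
  w <- cfg$width_ms; a <- cfg$amp_mv
  ms2n <- function(ms) max(1L, as.integer(round(ms * cfg$fs / 1000)))
  if (type == "PVC") {
    p_ms <- 0
    iso2_ms <- rtnorm1(40, 6)
    qrs_ms <- runif(1, 130, 170)
    iso3_ms <- rtnorm1(80, 8)
    t_ms <- rtnorm1(190, 12)
    qrs_amp <- 1.2 * a[["qrs"]]; t_amp <- -1.5 * a[["t"]]; p_amp <- 0
  } else if (type == "APC") {
    p_ms <- rtnorm1(0.85 * w[["p"]], 6)
    iso2_ms <- rtnorm1(170, 10)  # prolonged P-R: early, displaced P
    qrs_ms <- rtnorm1(w[["qrs"]], 8)
    iso3_ms <- rtnorm1(w[["iso3"]], 10)
    t_ms <- rtnorm1(w[["t"]], 12)
    qrs_amp <- a[["qrs"]]; t_amp <- a[["t"]]; p_amp <- 0.7 * a[["p"]]
  } else {
    p_ms <- rtnorm1(w[["p"]], 8)
    iso2_ms <- rtnorm1(w[["iso2"]], 8)
    qrs_ms <- rtnorm1(w[["qrs"]], 8, hi = min(w[["qrs"]] + 16, 112),
                      floor_val = 70)
    iso3_ms <- rtnorm1(w[["iso3"]], 10)
    t_ms <- rtnorm1(w[["t"]], 12)
    qrs_amp <- a[["qrs"]]; t_amp <- a[["t"]]; p_amp <- a[["p"]]
  }
  iso1_ms <- max(40, rr_target_ms - (p_ms + iso2_ms + qrs_ms + iso3_ms + t_ms))
  n <- c(ISO1 = ms2n(iso1_ms), P = if (p_ms > 0) ms2n(p_ms) else 0L,
         ISO2 = ms2n(iso2_ms), QRS = ms2n(qrs_ms), ISO3 = ms2n(iso3_ms),
         T = ms2n(t_ms))
  samples <- c(numeric(n[["ISO1"]]), bump(n[["P"]], p_amp),
               numeric(n[["ISO2"]]), qrs_shape(n[["QRS"]], qrs_amp),
               numeric(n[["ISO3"]]), bump(n[["T"]], t_amp))
  states <- rep.int(1:6, n)
  list(samples = samples, states = states, segs = n)
}

#' Generate an annotated synthetic ECG + accelerometer record
#'
#' Produces a millivolt ECG, a tri-axial accelerometer stream following the
#' motion schedule (constant gravity with small noise while standing or
#' lying, oscillatory while walking), and complete ground truth: the
#' per-sample subwave state path, per-beat labels and subwave boundaries,
#' and a motion-corruption flag for beats inside walking intervals. Additive
#' disturbances (mains sinusoid, baseline wander, white noise, band-limited
#' motion artifact during walking) are applied after the clean waveform is
#' built, so the truth is exact. With a non-`NULL` seed the record is fully
#' deterministic.
#'
#' @param cfg a [synth_config].
#' @return List of class `synth_record` with `ecg` ([ecg_signal], mV),
#'   `accel` ([accel_signal]), `truth` (list: `state_path`, `beats` data
#'   frame with `label`, subwave boundaries, `fiducial`, `motion`), and
#'   `cfg`.
#' @export
generate_record <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n_total <- as.integer(round(cfg$duration_s * cfg$fs))
  rr_nominal <- 60000 / cfg$hr_bpm
  samples <- numeric(0); states <- integer(0)
  beats <- list(); rr_hist <- numeric(0)
  pos <- 0L
  while (pos < n_total) {
    u <- runif(1)
    type <- if (u < cfg$pvc_rate) "PVC"
    else if (u < cfg$pvc_rate + cfg$apc_rate) "APC"
    else "Normal"
    run_mean <- if (length(rr_hist)) mean(tail(rr_hist, 8)) else rr_nominal
    rr_target <- switch(type,
      Normal = rtnorm1(rr_nominal, cfg$rr_jitter_sd_ms, floor_val = 400),
      PVC = runif(1, 0.6, 0.8) * run_mean,
      APC = runif(1, 0.6, 0.75) * run_mean)
    b <- synth_beat(cfg, type, rr_target)
    segs <- b$segs
    on <- pos + cumsum(c(0L, unname(segs[-6L])))  # segment onsets, 0-based
    beats[[length(beats) + 1L]] <- data.frame(
      label = type,
      p_on = if (segs[["P"]] > 0) on[2L] else NA_integer_,
      p_off = if (segs[["P"]] > 0) on[3L] else NA_integer_,
      qrs_on = on[4L], qrs_off = on[4L] + segs[["QRS"]],
      t_on = on[6L], t_off = on[6L] + segs[["T"]],
      fiducial = on[4L])
    rr_hist <- c(rr_hist, length(b$samples) * 1000 / cfg$fs)
    samples <- c(samples, b$samples)
    states <- c(states, b$states)
    pos <- pos + length(b$samples)
  }
  samples <- samples[seq_len(n_total)]
  states <- states[seq_len(n_total)]
  beats <- do.call(rbind, beats)
  beats <- beats[beats$qrs_off <= n_total &
                   (is.na(beats$t_off) | beats$t_off <= n_total), ,
                 drop = FALSE]
  rownames(beats) <- NULL
  tt <- (seq_len(n_total) - 1) / cfg$fs
  if (cfg$powerline_mv > 0)
    samples <- samples + cfg$powerline_mv *
      sin(2 * pi * cfg$powerline_hz * tt)
  if (cfg$baseline_mv > 0)
    samples <- samples + cfg$baseline_mv *
      sin(2 * pi * cfg$baseline_hz * tt)
  if (cfg$noise_sd_mv > 0)
    samples <- samples + rnorm(n_total, 0, cfg$noise_sd_mv)

  # motion artifact on the ECG during walking entries
  sched <- cfg$motion_schedule
  walk <- sched[sched$activity == "walking", , drop = FALSE]
  if (nrow(walk) && cfg$motion_gain_mv > 0) {
    bf <- signal::butter(2, c(1, 10) / (cfg$fs / 2), type = "pass")
    for (k in seq_len(nrow(walk))) {
      i0 <- max(1L, as.integer(round(walk$start_s[k] * cfg$fs)) + 1L)
      i1 <- min(n_total, as.integer(round(walk$end_s[k] * cfg$fs)))
      if (i1 <= i0) next
      art <- signal::filtfilt(bf, rnorm(i1 - i0 + 1L))
      art <- art / max(sd(art), 1e-12) * cfg$motion_gain_mv
      samples[i0:i1] <- samples[i0:i1] + art
    }
  }

  accel <- synth_accel(sched, cfg$accel_fs, cfg$duration_s)
  in_walk <- function(t)
    any(walk$start_s <= t & t < walk$end_s)
  beats$motion <- vapply(beats$fiducial / cfg$fs, in_walk, logical(1))

  structure(list(
    ecg = ecg_signal(samples, cfg$fs, unit = "mv"),
    accel = accel,
    truth = list(state_path = states, beats = beats),
    cfg = cfg), class = "synth_record")
}

# accelerometer synthesis per schedule entry; z points down so standing
# reads ~1 g on z, lying moves gravity onto x
synth_accel <- function(sched, fs, duration_s) {
  n <- as.integer(round(duration_s * fs))
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  for (k in seq_len(nrow(sched))) {
    i0 <- max(1L, as.integer(round(sched$start_s[k] * fs)) + 1L)
    i1 <- min(n, as.integer(round(sched$end_s[k] * fs)))
    if (i1 < i0) next
    idx <- i0:i1
    t <- (idx - 1) / fs
    m <- length(idx)
    if (sched$activity[k] == "walking") {
      # ~2 Hz step cadence: rectified-sine vertical bounce (heel strikes
      # raise the magnitude above one g) plus lateral sway
      az[idx] <- 1 + 0.7 * abs(sin(2 * pi * 2 * t)) + rnorm(m, 0, 0.05)
      ax[idx] <- 0.4 * sin(2 * pi * 2 * t + 1.1) + rnorm(m, 0, 0.05)
      ay[idx] <- 0.25 * sin(2 * pi * 1 * t + 0.4) + rnorm(m, 0, 0.05)
    } else if (sched$activity[k] == "lying") {
      ax[idx] <- 1 + rnorm(m, 0, 0.02)
      ay[idx] <- rnorm(m, 0, 0.02)
      az[idx] <- rnorm(m, 0, 0.02)
    } else {
      ax[idx] <- rnorm(m, 0, 0.02)
      ay[idx] <- rnorm(m, 0, 0.02)
      az[idx] <- 1 + rnorm(m, 0, 0.02)
    }
  }
  accel_signal(ax, ay, az, fs)
}

#' Replay a signal as timestamped chunks
#'
#' Deterministic chunking of a sample stream, optionally paced in real
#' time, emulating a sensor node streaming packets at its native rate.
#'
#' @param samples numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param chunk_ms chunk length in ms (> 0).
#' @param paced when `TRUE`, sleep so chunks are delivered at the true
#'   sending rate.
#' @param callback optional function called as `callback(chunk)` as each
#'   chunk is produced.
#' @return List of chunks, each a list with `t0_s` (chunk start time) and
#'   `samples`. Concatenating the chunk samples restores the input exactly.
#' @export
replay_record <- function(samples, fs, chunk_ms, paced = FALSE,
                          callback = NULL) {
  if (chunk_ms <= 0) stop_input("'chunk_ms' must be positive")
  n <- length(samples)
  per <- max(1L, as.integer(round(chunk_ms * fs / 1000)))
  starts <- seq(1L, n, by = per)
  t_start <- Sys.time()
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- min(n, i0 + per - 1L)
    if (paced) {
      due <- t_start + (i0 - 1L) / fs
      wait <- as.numeric(due - Sys.time(), units = "secs")
      if (wait > 0) Sys.sleep(wait)
    }
    ch <- list(t0_s = (i0 - 1L) / fs, samples = samples[i0:i1])
    if (!is.null(callback)) callback(ch)
    out[[k]] <- ch
  }
  out
}
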