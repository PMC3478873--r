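#' Layer-2 state space
#' @export
HMM2_STATES <- c("Normal", "PVC", "APC", "Invalid")

#' Beat feature codebook
#'
#' Discretizes per-beat clinical features into the 36-symbol product
#' alphabet of the beat-classification HMM:
#' * QRS duration: normal (`<= qrs_wide_ms`) / wide — the 120 ms cut-off is
#'   the classical PVC width criterion;
#' * R-R interval relative to the running median: premature
#'   (`< rr_premature * median`) / normal / long (`> rr_long * median`);
#' * P wave: present-normal / present-abnormal (P-R interval outside
#'   `pr_normal_ms`) / absent;
#' * activity: reliable (standing or lying) / motion (walking).
#'
#' @param qrs_wide_ms QRS width threshold in ms (default 120).
#' @param rr_premature,rr_long prematurity bands relative to the running
#'   median R-R interval (defaults 0.85 and 1.15).
#' @param pr_normal_ms length-2 normal P-R band in ms (default 100-200).
#' @param rr_window number of preceding R-R intervals in the running median
#'   (default 8).
#' @return An object of class `feature_codebook` with `n_symbols = 36`.
#' @export
feature_codebook <- function(qrs_wide_ms = 120, rr_premature = 0.85,
                             rr_long = 1.15, pr_normal_ms = c(100, 200),
                             rr_window = 8L) {
  if (rr_premature >= rr_long) stop_input("'rr_premature' must be < 'rr_long'")
  structure(list(qrs_wide_ms = qrs_wide_ms, rr_premature = rr_premature,
                 rr_long = rr_long, pr_normal_ms = pr_normal_ms,
                 rr_window = as.integer(rr_window), n_symbols = 36L),
            class = "feature_codebook")
}

#' Encode one beat as a discrete observation symbol
#'
#' Deterministic map from beat features to `1..36`. Absent R-R intervals
#' (first beat) take the normal R-R code; an absent P wave takes the
#' dedicated absent code regardless of the P-R field.
#'
#' @param cb a [feature_codebook].
#' @param qrs_ms QRS duration in ms.
#' @param pr_ms P-R interval in ms (`NA` when no P).
#' @param rr_ms R-R interval in ms (`NA` for the first beat).
#' @param p_present logical P-present flag.
#' @param activity `"standing"`, `"walking"` or `"lying"`.
#' @param rr_median running-median R-R in ms (`NA` allowed).
#' @return Integer symbol in `1..36`.
#' @export
encode_beat <- function(cb, qrs_ms, pr_ms, rr_ms, p_present, activity,
                        rr_median) {
  qrs_code <- if (qrs_ms > cb$qrs_wide_ms) 2L else 1L
  rr_code <- if (is.na(rr_ms) || is.na(rr_median) || rr_median <= 0) 2L
  else if (rr_ms < cb$rr_premature * rr_median) 1L
  else if (rr_ms > cb$rr_long * rr_median) 3L
  else 2L
  p_code <- if (!isTRUE(p_present)) 3L
  else if (is.na(pr_ms) || pr_ms < cb$pr_normal_ms[1] ||
           pr_ms > cb$pr_normal_ms[2]) 2L
  else 1L
  act_code <- if (identical(activity, "walking")) 2L else 1L
  qrs_code + 2L * (rr_code - 1L) + 6L * (p_code - 1L) + 18L * (act_code - 1L)
}

#' Extract clinical features from a segmentation
#'
#' Per-beat QRS duration, P-R interval (P onset to QRS onset), R-R interval
#' (spacing of consecutive QRS onsets), P-present flag and activity label.
#'
#' @param seg an `ecg_segmentation` from [path_to_beats()].
#' @param activity_windows optional data frame from
#'   [classify_activity_stream()]; when `NULL`, every beat is labeled
#'   `"standing"` (reliable).
#' @return Data frame of class `beat_features` with one row per beat.
#' @export
extract_beat_features <- function(seg, activity_windows = NULL) {
  b <- seg$beats
  ms <- 1000 / seg$fs
  qrs_ms <- (b$qrs_off - b$qrs_on) * ms
  pr_ms <- (b$qrs_on - b$p_on) * ms
  rr_ms <- c(NA_real_, diff(b$fiducial)) * ms
  act <- activity_at(activity_windows, b$fiducial / seg$fs)
  out <- data.frame(fiducial = b$fiducial, qrs_ms = qrs_ms, pr_ms = pr_ms,
                    rr_ms = rr_ms, p_present = !is.na(b$p_on),
                    activity = act, stringsAsFactors = FALSE)
  class(out) <- c("beat_features", "data.frame")
  out
}

#' Encode a sequence of beats
#'
#' Applies [encode_beat()] to each row of a beat-feature table, computing
#' the running median R-R over the preceding `rr_window` intervals.
#'
#' @param cb a [feature_codebook].
#' @param features data frame with columns `qrs_ms`, `pr_ms`, `rr_ms`,
#'   `p_present`, `activity`.
#' @return Integer vector of symbols in `1..36`.
#' @export
encode_beats <- function(cb, features) {
  n <- nrow(features)
  syms <- integer(n)
  rr_seen <- numeric(0)
  for (i in seq_len(n)) {
    rr <- features$rr_ms[i]
    med <- if (length(rr_seen)) median(tail(rr_seen, cb$rr_window))
    else rr  # first interval: compare with itself -> normal
    syms[i] <- encode_beat(cb, features$qrs_ms[i], features$pr_ms[i], rr,
                           features$p_present[i], features$activity[i],
                           if (is.null(med)) NA_real_ else med)
    if (!is.na(rr)) rr_seen <- c(rr_seen, rr)
  }
  syms
}

#' Construct and validate Layer-2 HMM parameters
#'
#' A fully connected (ergodic) four-state HMM over Normal, PVC, APC and
#' Invalid beats; Invalid absorbs beats recorded under strong motion
#' artifacts.
#'
#' @param trans 4x4 row-stochastic transition matrix, strictly positive.
#' @param emis 4xK row-stochastic emission matrix over the codebook symbols.
#' @param init length-4 initial distribution.
#' @return An object of class `hmm2_params`.
#' @export
hmm2_params <- function(trans, emis, init) {
  n <- length(HMM2_STATES)
  trans <- as.matrix(trans); emis <- as.matrix(emis)
  if (!all(dim(trans) == c(n, n))) stop_input("'trans' must be 4x4")
  if (nrow(emis) != n) stop_input("'emis' must have 4 rows")
  if (length(init) != n) stop_input("'init' must have length 4")
  if (any(abs(rowSums(trans) - 1) > 1e-9) ||
      any(abs(rowSums(emis) - 1) > 1e-9) || abs(sum(init) - 1) > 1e-9)
    stop_input("rows of 'trans'/'emis' and 'init' must sum to 1")
  if (any(trans <= 0))
    stop_input("the ergodic model admits no structural zeros in 'trans'")
  dimnames(trans) <- list(HMM2_STATES, HMM2_STATES)
  rownames(emis) <- HMM2_STATES
  names(init) <- HMM2_STATES
  structure(list(states = HMM2_STATES, trans = trans, emis = emis,
                 init = init), class = "hmm2_params")
}

#' Supervised estimation of Layer-2 parameters
#'
#' Add-one-smoothed relative-frequency estimates of the transition and
#' emission matrices from labeled beat sequences; deterministic.
#'
#' @param labels list of integer label sequences (values `1..4`), or a
#'   single integer vector.
#' @param symbols list of integer symbol sequences aligned with `labels`.
#' @param n_symbols alphabet size (default 36).
#' @return An `hmm2_params` object.
#' @export
train_hmm2 <- function(labels, symbols, n_symbols = 36L) {
  if (!is.list(labels)) { labels <- list(labels); symbols <- list(symbols) }
  if (!length(labels) || !sum(lengths(labels)))
    stop_input("empty training corpus")
  n <- length(HMM2_STATES)
  tc <- matrix(0, n, n); ec <- matrix(0, n, n_symbols); ic <- numeric(n)
  for (i in seq_along(labels)) {
    l <- as.integer(labels[[i]]); o <- as.integer(symbols[[i]])
    if (length(l) != length(o))
      stop_input("labels and symbols of sequence ", i, " differ in length")
    if (any(l < 1L | l > n)) stop_input("labels outside the 4-state set")
    if (length(l) > 1L)
      for (k in seq_len(length(l) - 1L))
        tc[l[k], l[k + 1L]] <- tc[l[k], l[k + 1L]] + 1
    for (k in seq_along(l)) ec[l[k], o[k]] <- ec[l[k], o[k]] + 1
    ic[l[1L]] <- ic[l[1L]] + 1
  }
  hmm2_params((tc + 1) / (rowSums(tc) + n),
              (ec + 1) / (rowSums(ec) + n_symbols),
              (ic + 1) / (sum(ic) + n))
}

#' Force motion-coded symbols onto the Invalid state
#'
#' Floors the emission probability of every motion-coded symbol (activity
#' code "walking", symbols 19..36) to `floor_p` under the Normal, PVC and
#' APC states and renormalizes the rows, so a beat observed during walking
#' can only decode as Invalid. This is the activity gate of the layered
#' model: motion-distorted morphology must not raise an arrhythmia alarm.
#'
#' @param params an `hmm2_params`.
#' @param floor_p emission floor for motion symbols under non-Invalid
#'   states (default `1e-9`).
#' @return The gated `hmm2_params`.
#' @export
gate_motion <- function(params, floor_p = 1e-9) {
  emis <- params$emis
  motion <- 19:36
  for (s in seq_len(nrow(emis))[-4L]) {
    emis[s, motion] <- floor_p
    emis[s, ] <- emis[s, ] / sum(emis[s, ])
  }
  hmm2_params(params$trans, emis, params$init)
}

#' Classify a beat sequence
#'
#' Viterbi decoding of the encoded beat sequence under the four-state
#' ergodic model. `mode = "batch"` decodes the whole record at once;
#' `mode = "online"` is a fixed-lag variant for streaming use: the label of
#' beat t is committed from the Viterbi decode of the prefix `1..min(t+lag,
#' n)`.
#'
#' @param params an `hmm2_params`.
#' @param symbols integer symbols from [encode_beats()].
#' @param mode `"batch"` or `"online"`.
#' @param lag fixed lag in beats for the online mode (default 3).
#' @return Integer vector of state labels (`1..4`); see [HMM2_STATES].
#' @export
classify_beats <- function(params, symbols, mode = c("batch", "online"),
                           lag = 3L) {
  mode <- match.arg(mode)
  symbols <- as.integer(symbols)
  if (!length(symbols)) stop_input("empty beat sequence")
  if (any(symbols < 1L | symbols > ncol(params$emis)))
    stop_input("symbols outside the emission alphabet")
  flat <- list(trans = params$trans, emis = params$emis, init = params$init,
               min_duration = rep(1L, 4L),
               mask = matrix(TRUE, 4L, 4L))
  if (mode == "batch") return(viterbi_min_duration(flat, symbols)$path)
  n <- length(symbols)
  out <- integer(n)
  for (t in seq_len(n)) {
    upto <- min(n, t + lag)
    out[t] <- viterbi_min_duration(flat, symbols[seq_len(upto)])$path[t]
  }
  out
}
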