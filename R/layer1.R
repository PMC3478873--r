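#' Layer-1 state space
#'
#' The six characteristic subwave states of one cardiac cycle, in temporal
#' order: the first isoelectric segment, the P wave, the P-R isoelectric
#' segment, the QRS complex, the S-T isoelectric segment, and the T wave.
#' @export
HMM1_STATES <- c("ISO1", "P", "ISO2", "QRS", "ISO3", "T")

#' Four-level amplitude quantizer
#'
#' Partitions the ADC range `[0, adc_max]` into `n_levels` equal-width bins;
#' bin k emits observation symbol k (`O1..O4` by default). With the default
#' 12-bit range, readings 0..1023 map to O1, 1024..2047 to O2, and so on.
#'
#' @param adc_max full-scale ADC count (default 4095).
#' @param n_levels number of observation symbols (default 4).
#' @return An object of class `quantizer` with the bin `thresholds`
#'   (upper bin edges, excluded, except the last).
#' @export
quantizer <- function(adc_max = 4095L, n_levels = 4L) {
  adc_max <- as.integer(adc_max); n_levels <- as.integer(n_levels)
  if (adc_max < n_levels) stop_input("'adc_max' too small for 'n_levels'")
  width <- (adc_max + 1) / n_levels
  structure(list(adc_max = adc_max, n_levels = n_levels,
                 thresholds = width * seq_len(n_levels - 1L)),
            class = "quantizer")
}

#' Quantize an ECG signal into observation symbols
#'
#' @param q a [quantizer].
#' @param x an [ecg_signal]. Millivolt inputs are first mapped onto the ADC
#'   scale with [mv_to_adc()] defaults.
#' @return Integer vector of symbols in `1..n_levels`, one per sample.
#' @examples
#' q <- quantizer()
#' quantize(q, ecg_signal(c(0, 1023, 1024, 4095), 360, unit = "adc"))
#' @export
quantize <- function(q, x) {
  stopifnot(inherits(q, "quantizer"), inherits(x, "ecg_signal"))
  if (x$unit == "mv") x <- mv_to_adc(x, adc_max = q$adc_max)
  s <- x$samples
  if (length(s) && (any(s < 0) || any(s > q$adc_max)))
    stop_input("ADC counts outside [0, ", q$adc_max, "]")
  findInterval(s, q$thresholds) + 1L
}

#' Layer-1 topology mask
#'
#' Allowed transitions of the six-state segmentation chain: self-loops, the
#' cyclic order ISO1 -> P -> ISO2 -> QRS -> ISO3 -> T -> ISO1, plus the
#' added ISO1 -> ISO2 edge that lets a beat skip a missing P wave.
#'
#' @return A 6x6 logical matrix with state-name dimnames.
#' @export
hmm1_topology <- function() {
  n <- length(HMM1_STATES)
  mask <- diag(n) > 0
  for (i in seq_len(n)) mask[i, i %% n + 1L] <- TRUE
  mask[1L, 3L] <- TRUE  # P-skip edge
  dimnames(mask) <- list(HMM1_STATES, HMM1_STATES)
  mask
}

#' Construct and validate Layer-1 HMM parameters
#'
#' @param trans 6x6 row-stochastic transition matrix; entries outside the
#'   topology mask must be zero.
#' @param emis 6xK row-stochastic emission matrix over the quantizer symbols.
#' @param init length-6 initial state distribution.
#' @param min_duration integer vector of per-state minimum dwell times in
#'   samples (all >= 1).
#' @param mask topology mask (default [hmm1_topology()]).
#' @return An object of class `hmm1_params`.
#' @export
hmm1_params <- function(trans, emis, init,
                        min_duration = rep(1L, length(HMM1_STATES)),
                        mask = hmm1_topology()) {
  n <- length(HMM1_STATES)
  trans <- as.matrix(trans); emis <- as.matrix(emis)
  min_duration <- as.integer(min_duration)
  if (!all(dim(trans) == c(n, n))) stop_input("'trans' must be 6x6")
  if (nrow(emis) != n) stop_input("'emis' must have 6 rows")
  if (length(init) != n) stop_input("'init' must have length 6")
  if (length(min_duration) != n || any(min_duration < 1L))
    stop_input("'min_duration' must be 6 integers >= 1")
  if (any(abs(rowSums(trans) - 1) > 1e-9) ||
      any(abs(rowSums(emis) - 1) > 1e-9) || abs(sum(init) - 1) > 1e-9)
    stop_input("rows of 'trans'/'emis' and 'init' must sum to 1")
  if (any(trans[!mask] != 0))
    stop_input("'trans' has probability mass outside the topology mask")
  dimnames(trans) <- list(HMM1_STATES, HMM1_STATES)
  rownames(emis) <- HMM1_STATES
  names(init) <- names(min_duration) <- HMM1_STATES
  structure(list(states = HMM1_STATES, trans = trans, emis = emis,
                 init = init, min_duration = min_duration, mask = mask),
            class = "hmm1_params")
}

# dwell lengths of every run of each state across a list of paths
state_dwells <- function(paths, n_states) {
  out <- vector("list", n_states)
  for (p in paths) {
    r <- rle(p)
    for (s in unique(r$values))
      out[[s]] <- c(out[[s]], r$lengths[r$values == s])
  }
  out
}

#' Supervised estimation of Layer-1 parameters
#'
#' Transition and emission probabilities are add-one-smoothed relative
#' frequencies, with smoothing applied only inside the topology mask. The
#' per-state minimum dwell is set to `floor(0.6 * minimum observed dwell)`
#' (at least 1 sample), the rule used to suppress double-beat segmentation.
#'
#' @param paths list of integer state paths (values `1..6`).
#' @param symbols list of integer observation sequences, aligned with
#'   `paths`.
#' @param n_symbols size of the observation alphabet (default 4).
#' @param mask topology mask.
#' @param duration_frac fraction of the minimum observed dwell used as the
#'   hard minimum duration (default 0.6).
#' @return An `hmm1_params` object.
#' @export
train_hmm1 <- function(paths, symbols, n_symbols = 4L,
                       mask = hmm1_topology(), duration_frac = 0.6) {
  if (!length(paths)) stop_input("empty training set")
  if (length(paths) != length(symbols))
    stop_input("'paths' and 'symbols' must be aligned lists")
  n <- length(HMM1_STATES)
  tc <- matrix(0, n, n); ec <- matrix(0, n, n_symbols); ic <- numeric(n)
  for (i in seq_along(paths)) {
    p <- as.integer(paths[[i]]); o <- as.integer(symbols[[i]])
    if (length(p) != length(o))
      stop_input("path and symbol sequence ", i, " differ in length")
    if (length(p) == 0L) next
    if (any(p < 1L | p > n)) stop_input("path ", i, " has invalid states")
    if (length(p) > 1L) {
      from <- p[-length(p)]; to <- p[-1L]
      if (any(!mask[cbind(from, to)]))
        stop_input("path ", i, " violates the topology mask")
      for (k in seq_along(from)) tc[from[k], to[k]] <- tc[from[k], to[k]] + 1
    }
    for (k in seq_along(p)) ec[p[k], o[k]] <- ec[p[k], o[k]] + 1
    ic[p[1L]] <- ic[p[1L]] + 1
  }
  trans <- matrix(0, n, n)
  for (s in seq_len(n)) {
    allowed <- which(mask[s, ])
    trans[s, allowed] <- (tc[s, allowed] + 1) / (sum(tc[s, allowed]) +
                                                   length(allowed))
  }
  emis <- (ec + 1) / (rowSums(ec) + n_symbols)
  init <- (ic + 1) / (sum(ic) + n)
  dw <- state_dwells(paths, n)
  mindur <- vapply(dw, function(d)
    if (is.null(d)) 1L else max(1L, as.integer(floor(duration_frac * min(d)))),
    integer(1))
  hmm1_params(trans, emis, init, mindur, mask)
}

# Expand (state, phase) pairs so a plain Viterbi pass enforces minimum
# dwells: state s is replicated min_duration[s] times; phases 1..d-1 can only
# advance within the run, phase d self-loops or exits to another state's
# phase 1. Entering, staying and leaving carry the ordinary HMM transition
# weights, so the decoded score is the path's unconstrained log-probability.
expand_duration_graph <- function(trans, init, min_duration, mask) {
  n <- length(init)
  d <- pmax(1L, as.integer(min_duration))
  off <- cumsum(c(0L, d))  # block offset per state
  n_exp <- off[n + 1L]
  state_of <- rep.int(seq_len(n), d)
  phase <- unlist(lapply(d, seq_len), use.names = FALSE)
  lt <- suppressWarnings(log(trans))
  log_init <- rep(-Inf, n_exp)
  log_init[off[seq_len(n)] + 1L] <- suppressWarnings(log(init))
  preds <- vector("list", n_exp); predw <- vector("list", n_exp)
  for (s in seq_len(n)) {
    entry <- off[s] + 1L; exit <- off[s] + d[s]
    # chain within the run
    if (d[s] > 1L)
      for (i in 2L:d[s]) {
        preds[[off[s] + i]] <- off[s] + i - 1L
        predw[[off[s] + i]] <- lt[s, s]
      }
    # stay beyond the minimum dwell
    preds[[exit]] <- c(preds[[exit]], exit)
    predw[[exit]] <- c(predw[[exit]], lt[s, s])
    # entries from other states' exits
    from <- setdiff(which(mask[, s]), s)
    if (length(from)) {
      preds[[entry]] <- c(preds[[entry]], off[from] + d[from])
      predw[[entry]] <- c(predw[[entry]], lt[cbind(from, s)])
    }
  }
  # ascending predecessor order => deterministic lowest-index tie-break
  for (j in seq_len(n_exp)) {
    ord <- order(preds[[j]])
    preds[[j]] <- preds[[j]][ord]; predw[[j]] <- predw[[j]][ord]
  }
  lens <- lengths(preds)
  list(n_exp = n_exp, state_of = state_of,
       pred_ptr = as.integer(cumsum(c(0L, lens))),
       pred_idx = as.integer(unlist(preds, use.names = FALSE) - 1L),
       pred_logw = as.numeric(unlist(predw, use.names = FALSE)),
       log_init = log_init,
       final_ok = phase == d[state_of])
}

#' Minimum-duration-constrained Viterbi decoding
#'
#' Returns the maximum-probability state path among paths that follow the
#' topology mask and dwell at least `min_duration[s]` samples in every run
#' of state s (including the first and last run). Computation is in the log
#' domain over an expanded state space (each state replicated
#' `min_duration` times), which is exact; ties are broken deterministically
#' towards the lowest state index. With all minimum durations equal to 1
#' this is classical Viterbi.
#'
#' @param params an `hmm1_params` (or any list with `trans`, `emis`, `init`,
#'   `min_duration`, `mask`).
#' @param obs integer vector of observation symbols (`1..ncol(emis)`).
#' @return List with `path` (integer states per sample) and `logp`, the
#'   unconstrained log-probability of that path.
#' @export
viterbi_min_duration <- function(params, obs) {
  obs <- as.integer(obs)
  if (!length(obs)) stop_input("empty observation sequence")
  if (any(obs < 1L | obs > ncol(params$emis)))
    stop_input("observation symbols outside the emission alphabet")
  g <- expand_duration_graph(params$trans, params$init,
                             params$min_duration, params$mask)
  res <- viterbi_core(g$log_init, g$pred_ptr, g$pred_idx, g$pred_logw,
                      as.integer(g$state_of - 1L),
                      suppressWarnings(log(params$emis)),
                      obs - 1L, g$final_ok)
  if (!length(res$path) || !is.finite(res$logp))
    stop_input("no duration-feasible state path for this observation length")
  list(path = g$state_of[res$path], logp = res$logp)
}

#' Log-probability of a given state path
#'
#' Joint log-probability of a state path and an observation sequence under
#' the (unconstrained) HMM; used for decoder self-consistency checks.
#'
#' @param params HMM parameter list with `trans`, `emis`, `init`.
#' @param path integer state path.
#' @param obs integer observation symbols.
#' @return Scalar log-probability.
#' @export
path_logprob <- function(params, path, obs) {
  lp <- suppressWarnings(log(params$init[path[1L]])) +
    sum(suppressWarnings(log(params$emis[cbind(path, obs)])))
  if (length(path) > 1L)
    lp <- lp + sum(suppressWarnings(
      log(params$trans[cbind(path[-length(path)], path[-1L])])))
  unname(lp)
}

#' Derive per-beat subwave boundaries from a decoded state path
#'
#' One beat per QRS run. The P wave attached to a beat is the last P run
#' between the previous QRS run (or the start of the record) and this QRS;
#' the T wave is the first T run before the next QRS. All intervals are
#' 0-based half-open `[onset, offset)` sample indices.
#'
#' @param path integer state path (values `1..6`).
#' @param fs sampling rate in Hz.
#' @return An object of class `ecg_segmentation`: list with the `state_path`,
#'   `fs`, and a `beats` data frame (columns `p_on`, `p_off`, `qrs_on`,
#'   `qrs_off`, `t_on`, `t_off`, `fiducial`; `NA` where a subwave is absent).
#' @export
path_to_beats <- function(path, fs) {
  path <- as.integer(path)
  empty <- data.frame(p_on = integer(0), p_off = integer(0),
                      qrs_on = integer(0), qrs_off = integer(0),
                      t_on = integer(0), t_off = integer(0),
                      fiducial = integer(0))
  if (!length(path))
    return(structure(list(state_path = path, fs = fs, beats = empty),
                     class = "ecg_segmentation"))
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based onsets
  qrs_runs <- which(r$values == 4L)
  beats <- lapply(seq_along(qrs_runs), function(k) {
    i <- qrs_runs[k]
    lo <- if (k == 1L) 0L else qrs_runs[k - 1L]
    p_candidates <- which(r$values == 2L & seq_along(r$values) > lo &
                            seq_along(r$values) < i)
    p <- if (length(p_candidates)) max(p_candidates) else NA_integer_
    hi <- if (k == length(qrs_runs)) length(r$values) + 1L else qrs_runs[k + 1L]
    t_candidates <- which(r$values == 6L & seq_along(r$values) > i &
                            seq_along(r$values) < hi)
    tt <- if (length(t_candidates)) min(t_candidates) else NA_integer_
    data.frame(
      p_on = if (is.na(p)) NA_integer_ else starts[p],
      p_off = if (is.na(p)) NA_integer_ else ends[p],
      qrs_on = starts[i], qrs_off = ends[i],
      t_on = if (is.na(tt)) NA_integer_ else starts[tt],
      t_off = if (is.na(tt)) NA_integer_ else ends[tt],
      fiducial = starts[i])
  })
  beats <- if (length(beats)) do.call(rbind, beats) else empty
  structure(list(state_path = path, fs = fs, beats = beats),
            class = "ecg_segmentation")
}

#' @export
print.ecg_segmentation <- function(x, ...) {
  cat(sprintf("<ecg_segmentation> %d samples @ %g Hz, %d beats\n",
              length(x$state_path), x$fs, nrow(x$beats)))
  invisible(x)
}
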