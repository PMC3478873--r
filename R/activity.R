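#' Activity classifier parameters
#'
#' Thresholds of the heuristic standing/walking/lying classifier. A window
#' is Walking when the mean acceleration magnitude exceeds `delta1` (above
#' one g) and its variance exceeds `delta2`; otherwise it is Lying when the
#' mean z component is within `epsilon` of zero, else Standing.
#'
#' @param delta1 magnitude threshold in g (> 1).
#' @param delta2 variance threshold in g^2 (> 0).
#' @param epsilon near-zero bound on the z component in g.
#' @param window_s sliding-window length in seconds (default 3).
#' @param hop_s window hop in seconds (default 1).
#' @return An object of class `activity_params`.
#' @export
activity_params <- function(delta1 = 1.15, delta2 = 0.01, epsilon = 0.2,
                            window_s = 3, hop_s = 1) {
  if (delta1 <= 1) stop_input("'delta1' must exceed one g")
  if (delta2 <= 0) stop_input("'delta2' must be positive")
  if (epsilon <= 0 || epsilon >= 1)
    stop_input("'epsilon' must be a small positive number below 1")
  if (window_s <= 0 || hop_s <= 0) stop_input("window and hop must be positive")
  structure(list(delta1 = delta1, delta2 = delta2, epsilon = epsilon,
                 window_s = window_s, hop_s = hop_s),
            class = "activity_params")
}

#' Per-window accelerometer features
#'
#' The acceleration magnitude per sample is `A = sqrt(ax^2 + ay^2 + az^2)`;
#' the features are the window mean and (population) variance of `A`, plus
#' the window mean of the z component used by the lying test.
#'
#' @param w an [accel_signal] covering one window.
#' @return Named numeric vector `c(a_mean, a_var, az_mean)`.
#' @export
accel_features <- function(w) {
  stopifnot(inherits(w, "accel_signal"))
  if (!length(w$ax)) stop_input("empty accelerometer window")
  a <- sqrt(w$ax^2 + w$ay^2 + w$az^2)
  c(a_mean = mean(a), a_var = mean((a - mean(a))^2), az_mean = mean(w$az))
}

#' Classify one accelerometer window
#'
#' @param p an [activity_params].
#' @param w an [accel_signal] window.
#' @return One of `"walking"`, `"lying"`, `"standing"`.
#' @examples
#' p <- activity_params()
#' classify_activity(p, accel_signal(0, 0, 1, 50))   # standing
#' classify_activity(p, accel_signal(1, 0, 0, 50))   # lying
#' @export
classify_activity <- function(p, w) {
  stopifnot(inherits(p, "activity_params"))
  f <- accel_features(w)
  if (f[["a_mean"]] >= p$delta1 && f[["a_var"]] >= p$delta2) "walking"
  else if (abs(f[["az_mean"]]) <= p$epsilon) "lying"
  else "standing"
}

#' Sliding-window activity classification of a stream
#'
#' Windows of `window_s` seconds advance by `hop_s`; each is classified with
#' [classify_activity()]. A trailing partial window (at least one sample) is
#' classified too so the whole stream is covered.
#'
#' @param p an [activity_params].
#' @param x an [accel_signal].
#' @return Data frame with `start_s`, `end_s`, `center_s`, `activity`.
#' @export
classify_activity_stream <- function(p, x) {
  stopifnot(inherits(x, "accel_signal"))
  n <- length(x$ax)
  wlen <- max(1L, round(p$window_s * x$fs))
  hop <- max(1L, round(p$hop_s * x$fs))
  starts <- seq(1L, max(1L, n - wlen + 1L), by = hop)
  last_end <- starts[length(starts)] + wlen - 1L
  if (last_end < n) starts <- c(starts, n - wlen + 1L)
  out <- lapply(starts, function(s) {
    e <- min(n, s + wlen - 1L)
    w <- accel_signal(x$ax[s:e], x$ay[s:e], x$az[s:e], x$fs)
    data.frame(start_s = (s - 1) / x$fs, end_s = e / x$fs,
               center_s = (s - 1 + (e - s) / 2) / x$fs,
               activity = classify_activity(p, w))
  })
  do.call(rbind, out)
}

#' Look up the activity label at given times
#'
#' Each query time gets the label of the window whose center is nearest.
#'
#' @param windows data frame from [classify_activity_stream()].
#' @param times_s numeric vector of query times in seconds.
#' @return Character vector of activity labels.
#' @export
activity_at <- function(windows, times_s) {
  if (is.null(windows) || !nrow(windows))
    return(rep("standing", length(times_s)))
  idx <- vapply(times_s, function(t) which.min(abs(windows$center_s - t)),
                integer(1))
  windows$activity[idx]
}
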