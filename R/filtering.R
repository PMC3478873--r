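#' Powerline notch filter specification
#'
#' Parameters of the second-order IIR notch used to reject 50/60 Hz mains
#' interference on the sensor node.
#'
#' @param notch_freq_hz notch (mains) frequency in Hz, typically 50 or 60.
#' @param sample_rate_hz sampling rate in Hz.
#' @param bw3db_hz 3 dB notch bandwidth in Hz (default 6).
#' @return An object of class `notch_spec`.
#' @export
notch_spec <- function(notch_freq_hz, sample_rate_hz, bw3db_hz = 6) {
  if (!is.finite(notch_freq_hz) || notch_freq_hz <= 0 ||
      notch_freq_hz >= sample_rate_hz / 2)
    stop_input("notch frequency must lie strictly between 0 and Nyquist")
  if (!is.finite(bw3db_hz) || bw3db_hz <= 0 || bw3db_hz >= sample_rate_hz / 2)
    stop_input("3 dB bandwidth must lie strictly between 0 and Nyquist")
  structure(list(notch_freq_hz = notch_freq_hz,
                 sample_rate_hz = sample_rate_hz,
                 bw3db_hz = bw3db_hz),
            class = "notch_spec")
}

#' Design the second-order IIR notch filter
#'
#' Constrained pole-zero design: the numerator zeros are placed exactly on
#' the unit circle at the normalized angular notch frequency
#' `w0 = 2*pi*f0/fs`, so the steady-state gain at the notch frequency is
#' exactly zero, and the pole pair shares the zero angle at radius `r` with
#' `r^2 = (1 - tan(bw/2)) / (1 + tan(bw/2))`, where `bw` is the normalized
#' angular 3 dB bandwidth. The numerator is left unnormalized (leading
#' coefficient 1), so the passband gain is close to but not exactly 1.
#'
#' For a 50 Hz notch at 360 Hz sampling with a 6 Hz bandwidth this yields
#' `b = (1, -1.2856, 1)`, `a = (1, -1.2199, 0.9004)`.
#'
#' @param spec a [notch_spec].
#' @return An object of class `biquad_coeffs`: list with numerator `b`
#'   (length 3) and denominator `a` (length 3, `a[1] == 1`).
#' @examples
#' design_notch(notch_spec(50, 360, 6))
#' @export
design_notch <- function(spec) {
  stopifnot(inherits(spec, "notch_spec"))
  w0 <- 2 * pi * spec$notch_freq_hz / spec$sample_rate_hz
  bw <- 2 * pi * spec$bw3db_hz / spec$sample_rate_hz
  r2 <- (1 - tan(bw / 2)) / (1 + tan(bw / 2))
  r <- sqrt(r2)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r2)
  structure(list(b = b, a = a), class = "biquad_coeffs")
}

#' @export
print.biquad_coeffs <- function(x, ...) {
  cat("<biquad_coeffs>\n")
  cat(sprintf("  b: %.6f %+.6f z^-1 %+.6f z^-2\n", x$b[1], x$b[2], x$b[3]))
  cat(sprintf("  a: %.6f %+.6f z^-1 %+.6f z^-2\n", x$a[1], x$a[2], x$a[3]))
  invisible(x)
}

#' Frequency response magnitude of a biquad
#'
#' @param coeffs a `biquad_coeffs`.
#' @param freq_hz frequencies at which to evaluate, Hz.
#' @param fs sampling rate in Hz.
#' @return `|H(e^{j 2 pi f / fs})|` at each frequency.
#' @export
biquad_gain <- function(coeffs, freq_hz, fs) {
  z <- exp(-1i * 2 * pi * freq_hz / fs)
  num <- coeffs$b[1] + coeffs$b[2] * z + coeffs$b[3] * z^2
  den <- coeffs$a[1] + coeffs$a[2] * z + coeffs$a[3] * z^2
  Mod(num / den)
}

#' Apply a biquad IIR filter to an ECG signal
#'
#' Causal direct-form difference equation with zero initial conditions:
#' `y[n] = b0 x[n] + b1 x[n-1] + b2 x[n-2] - a1 y[n-1] - a2 y[n-2]`.
#' Output length equals input length.
#'
#' @param coeffs a `biquad_coeffs` from [design_notch()].
#' @param x an [ecg_signal] (any unit; output keeps the unit as floats).
#' @return The filtered [ecg_signal].
#' @export
apply_iir <- function(coeffs, x) {
  stopifnot(inherits(coeffs, "biquad_coeffs"), inherits(x, "ecg_signal"))
  if (length(x$samples) && any(!is.finite(x$samples)))
    stop_input("input samples must be finite")
  if (!length(x$samples)) return(x)
  y <- as.numeric(signal::filter(signal::Arma(b = coeffs$b, a = coeffs$a),
                                 x$samples))
  out <- x  # unit tag kept; ADC inputs come back as floats on the count scale
  out$samples <- y
  out
}

#' Savitzky-Golay smoother specification
#'
#' @param window_len odd window length in samples (default 15).
#' @param poly_order polynomial order of the local least-squares fit
#'   (default 0, i.e. a centered moving average).
#' @return An object of class `sg_spec`.
#' @export
sg_spec <- function(window_len = 15L, poly_order = 0L) {
  window_len <- as.integer(window_len)
  poly_order <- as.integer(poly_order)
  if (window_len < 1L || window_len %% 2L == 0L)
    stop_input("'window_len' must be odd and positive")
  if (poly_order < 0L || poly_order >= window_len)
    stop_input("'poly_order' must satisfy 0 <= poly_order < window_len")
  structure(list(window_len = window_len, poly_order = poly_order),
            class = "sg_spec")
}

#' Savitzky-Golay smoothing
#'
#' Each output sample is the least-squares polynomial fit over the window
#' centered at it, evaluated at the center. At `poly_order = 0` this is the
#' centered moving average. Edges are handled by reflection padding (the
#' first/last sample is not repeated).
#'
#' @param spec an [sg_spec].
#' @param x an [ecg_signal] with at least `window_len` samples.
#' @return The smoothed [ecg_signal].
#' @export
sg_smooth <- function(spec, x) {
  stopifnot(inherits(spec, "sg_spec"), inherits(x, "ecg_signal"))
  n <- spec$window_len
  if (length(x$samples) < n)
    stop_input("signal shorter than the smoothing window")
  h <- (n - 1L) %/% 2L
  kern <- signal::sgolay(p = spec$poly_order, n = n)[h + 1L, ]
  s <- x$samples
  padded <- c(s[(h + 1L):2L], s, s[(length(s) - 1L):(length(s) - h)])
  y <- as.numeric(stats::filter(padded, rev(kern), sides = 2L))
  out <- x
  out$samples <- y[(h + 1L):(h + length(s))]
  out
}

#' Standard conditioning cascade: notch then Savitzky-Golay
#'
#' @param x an [ecg_signal].
#' @param notch a [notch_spec]; `NULL` skips the notch stage.
#' @param sg an [sg_spec]; `NULL` skips the smoothing stage.
#' @return The conditioned [ecg_signal].
#' @export
condition_ecg <- function(x, notch = notch_spec(50, x$fs, 6), sg = sg_spec()) {
  if (!is.null(notch)) x <- apply_iir(design_notch(notch), x)
  if (!is.null(sg)) x <- sg_smooth(sg, x)
  x
}
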