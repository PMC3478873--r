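#' ECG signal container
#'
#' A uniformly sampled single-lead ECG, either in millivolts (`unit = "mv"`)
#' or as raw ADC counts (`unit = "adc"`, integers in `0..adc_max`).
#'
#' @param samples numeric vector of samples.
#' @param fs sampling rate in Hz (positive scalar).
#' @param unit `"mv"` or `"adc"`.
#' @param adc_max full-scale ADC count; the default 4095 corresponds to a
#'   12-bit converter.
#' @return An object of class `ecg_signal`: a list with elements `samples`,
#'   `fs`, `unit` and `adc_max`.
#' @examples
#' x <- ecg_signal(sin(2 * pi * 1.2 * seq(0, 2, by = 1 / 360)), fs = 360)
#' x
#' @export
ecg_signal <- function(samples, fs, unit = c("mv", "adc"), adc_max = 4095L) {
  unit <- match.arg(unit)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_input("'fs' must be a positive scalar (Hz)")
  if (length(samples) && any(!is.finite(samples)))
    stop_input("ECG samples must be finite")
  if (unit == "adc") {
    if (length(samples) && (any(samples < 0) || any(samples > adc_max)))
      stop_input("ADC counts must lie in [0, ", adc_max, "]")
    if (length(samples) && any(samples != round(samples)))
      stop_input("ADC counts must be integers")
  }
  structure(list(samples = samples, fs = fs, unit = unit,
                 adc_max = as.integer(adc_max)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %d samples @ %g Hz (%.2f s), unit=%s\n",
              length(x$samples), x$fs, length(x$samples) / x$fs, x$unit))
  invisible(x)
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' Tri-axial accelerometer signal container
#'
#' @param ax,ay,az acceleration components in g (equal lengths). The z axis
#'   is taken perpendicular to the ground, pointing down, so a device worn by
#'   a standing subject reads close to one g on z.
#' @param fs sampling rate in Hz.
#' @return An object of class `accel_signal`.
#' @export
accel_signal <- function(ax, ay, az, fs) {
  if (length(ax) != length(ay) || length(ay) != length(az))
    stop_input("accelerometer components must have equal length")
  if (any(!is.finite(c(ax, ay, az))))
    stop_input("accelerometer samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_input("'fs' must be a positive scalar (Hz)")
  structure(list(ax = as.numeric(ax), ay = as.numeric(ay),
                 az = as.numeric(az), fs = fs),
            class = "accel_signal")
}

#' @export
print.accel_signal <- function(x, ...) {
  cat(sprintf("<accel_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$ax), x$fs, length(x$ax) / x$fs))
  invisible(x)
}

#' Map a millivolt ECG onto the ADC count scale
#'
#' Affine conversion from millivolts to ADC counts, clamped to the converter
#' range. The defaults center the isoelectric line inside the second of the
#' four quantizer levels (count 1535, about 1.1 V on the node's 3.0 V rail)
#' with 7200 counts per millivolt, so that downward deflections (e.g. the
#' inverted T wave of a PVC) reach the bottom level while the P and T waves
#' reach the third level and the QRS complex saturates into the top one —
#' each characteristic subwave is visible to the four-level quantizer.
#'
#' @param x an [ecg_signal] in millivolts.
#' @param baseline ADC count corresponding to 0 mV.
#' @param counts_per_mv scale factor in counts per millivolt.
#' @param adc_max full-scale count.
#' @return An [ecg_signal] with `unit = "adc"`.
#' @export
mv_to_adc <- function(x, baseline = 1535, counts_per_mv = 7200,
                      adc_max = 4095L) {
  stopifnot(inherits(x, "ecg_signal"))
  if (x$unit == "adc") return(x)
  counts <- round(baseline + counts_per_mv * x$samples)
  counts <- pmin(pmax(counts, 0), adc_max)
  ecg_signal(counts, x$fs, unit = "adc", adc_max = adc_max)
}
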