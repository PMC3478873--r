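#' Write / read an ECG signal as CSV
#'
#' Two-column CSV with header `t,ecg_mv` (or `t,ecg_adc` for count data);
#' `t` in seconds. Values are written with full double precision, so the
#' round trip is lossless. The sampling rate is recovered from the time
#' column unless declared.
#'
#' @param x an [ecg_signal].
#' @param path file path.
#' @return `write_signal_csv` returns `path` invisibly; `read_signal_csv`
#'   returns an [ecg_signal].
#' @export
write_signal_csv <- function(x, path) {
  stopifnot(inherits(x, "ecg_signal"))
  col <- if (x$unit == "mv") "ecg_mv" else "ecg_adc"
  df <- data.frame(t = (seq_along(x$samples) - 1) / x$fs, v = x$samples)
  names(df)[2] <- col
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @param fs sampling rate in Hz; `NULL` infers it from the time column.
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_missing_data("no such signal file: ", path)
  df <- read.csv(path)
  vcol <- intersect(c("ecg_mv", "ecg_adc"), names(df))
  if (!length(vcol) || !"t" %in% names(df))
    stop_input("signal CSV must have columns 't' and 'ecg_mv' or 'ecg_adc'")
  if (is.null(fs)) {
    if (nrow(df) < 2) stop_input("cannot infer fs from fewer than 2 samples")
    fs <- 1 / median(diff(df$t))
  }
  ecg_signal(df[[vcol[1]]], fs,
             unit = if (vcol[1] == "ecg_mv") "mv" else "adc")
}

#' Write / read an accelerometer stream as CSV
#'
#' Four-column CSV with header `t,ax,ay,az` (time in s, components in g).
#'
#' @param x an [accel_signal].
#' @param path file path.
#' @export
write_accel_csv <- function(x, path) {
  stopifnot(inherits(x, "accel_signal"))
  df <- data.frame(t = (seq_along(x$ax) - 1) / x$fs,
                   ax = x$ax, ay = x$ay, az = x$az)
  utils::write.table(format(df, digits = 17, scientific = FALSE,
                            trim = TRUE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_accel_csv
#' @param fs sampling rate in Hz; `NULL` infers it from the time column.
#' @export
read_accel_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_missing_data("no such accel file: ", path)
  df <- read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(df)))
    stop_input("accel CSV must have columns t, ax, ay, az")
  if (is.null(fs)) fs <- 1 / median(diff(df$t))
  accel_signal(df$ax, df$ay, df$az, fs)
}

json_schema <- list(hmm1_params = "lhmmecg/hmm1@1",
                    hmm2_params = "lhmmecg/hmm2@1")

#' Serialize / restore HMM models as JSON
#'
#' Schema-versioned JSON for both model layers (matrices, topology mask,
#' minimum durations where applicable). Numeric values are written at full
#' precision; the round trip restores an identical model. A malformed file
#' is rejected with an error naming the offending field.
#'
#' @param model an `hmm1_params` or `hmm2_params`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  cls <- intersect(class(model), names(json_schema))
  if (!length(cls)) stop_input("not a serializable model: ",
                               paste(class(model), collapse = "/"))
  obj <- list(schema = json_schema[[cls]],
              states = model$states,
              trans = unclass(model$trans),
              emis = unclass(model$emis),
              init = as.numeric(model$init))
  if (cls == "hmm1_params") {
    obj$min_duration <- as.integer(model$min_duration)
    obj$mask <- unclass(model$mask)
  }
  jsonlite::write_json(obj, path, digits = NA, matrix = "rowmajor",
                       auto_unbox = TRUE)
  invisible(path)
}

need_field <- function(obj, field, path) {
  if (is.null(obj[[field]]))
    stop_input("model JSON ", path, ": missing field '", field, "'")
  obj[[field]]
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop_missing_data("no such model file: ", path)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_input("model JSON ", path, ": parse error: ",
                               conditionMessage(e)))
  schema <- need_field(obj, "schema", path)
  trans <- as.matrix(need_field(obj, "trans", path))
  emis <- as.matrix(need_field(obj, "emis", path))
  init <- need_field(obj, "init", path)
  if (identical(schema, json_schema$hmm1_params)) {
    mask <- as.matrix(need_field(obj, "mask", path)) > 0
    dimnames(mask) <- list(HMM1_STATES, HMM1_STATES)
    hmm1_params(trans, emis, init,
                need_field(obj, "min_duration", path), mask)
  } else if (identical(schema, json_schema$hmm2_params)) {
    hmm2_params(trans, emis, init)
  } else stop_input("model JSON ", path, ": unknown field 'schema' value '",
                    schema, "'")
}

#' Write / read per-beat classification output as JSON
#'
#' Records are `{fiducial, label}` pairs with 0-based sample indices.
#'
#' @param beats data frame with columns `fiducial` and `label`.
#' @param path file path.
#' @param meta optional named list stored under `"meta"` (e.g. the seed).
#' @export
write_beats_json <- function(beats, path, meta = NULL) {
  obj <- list(schema = "lhmmecg/beats@1",
              beats = beats[, c("fiducial", "label")])
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_beats_json
#' @export
read_beats_json <- function(path) {
  if (!file.exists(path)) stop_missing_data("no such beats file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beats <- need_field(obj, "beats", path)
  if (!all(c("fiducial", "label") %in% names(beats)))
    stop_input("beats JSON ", path, ": field 'beats' needs ",
               "'fiducial' and 'label'")
  beats
}
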