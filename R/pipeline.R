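#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end flow: conditioning specs,
#' quantizer, both HMM layers, codebook, activity thresholds and the
#' beat-matching tolerance used for evaluation.
#'
#' @param hmm1 an `hmm1_params`.
#' @param hmm2 an `hmm2_params`.
#' @param codebook a [feature_codebook].
#' @param notch a [notch_spec] or `NULL` to skip the notch stage.
#' @param sg an [sg_spec] or `NULL` to skip smoothing.
#' @param quantizer_spec a [quantizer].
#' @param activity an [activity_params].
#' @param gate_motion force motion-coded beats to decode Invalid (default
#'   `TRUE`); see [gate_motion()].
#' @param tol_ms beat-matching tolerance for evaluation, ms.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(hmm1, hmm2, codebook = feature_codebook(),
                            notch = NULL, sg = sg_spec(),
                            quantizer_spec = quantizer(),
                            activity = activity_params(),
                            gate_motion = TRUE, tol_ms = 150) {
  structure(list(hmm1 = hmm1, hmm2 = hmm2, codebook = codebook,
                 notch = notch, sg = sg, quantizer_spec = quantizer_spec,
                 activity = activity, gate_motion = gate_motion,
                 tol_ms = tol_ms),
            class = "pipeline_config")
}

#' Run the full classification pipeline on one record
#'
#' Conditioning (notch + smoothing), quantization, duration-constrained
#' segmentation, clinical feature extraction, activity classification of
#' the accelerometer stream, feature encoding and beat classification.
#' Without an accelerometer stream every beat is treated as reliable
#' (standing) and a message says so. Deterministic: no randomness is used
#' at inference time.
#'
#' @param cfg a [pipeline_config].
#' @param ecg an [ecg_signal].
#' @param accel optional [accel_signal] aligned with `ecg`.
#' @param verbose emit per-stage messages (default `FALSE`).
#' @return List of class `pipeline_result`: `beats` (data frame `fiducial`,
#'   `label`), `features`, `segmentation`, `activity_windows`, `symbols`.
#' @export
run_pipeline <- function(cfg, ecg, accel = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"), inherits(ecg, "ecg_signal"))
  say <- function(...) if (verbose) message(...)
  empty <- data.frame(fiducial = integer(0), label = character(0))
  if (!length(ecg$samples))
    return(structure(list(beats = empty, features = NULL,
                          segmentation = path_to_beats(integer(0), ecg$fs),
                          activity_windows = NULL, symbols = integer(0)),
                     class = "pipeline_result"))
  notch <- if (is.null(cfg$notch)) notch_spec(50, ecg$fs, 6) else cfg$notch
  cond <- condition_ecg(ecg, notch = notch, sg = cfg$sg)
  say("conditioned ", length(cond$samples), " samples")
  syms <- quantize(cfg$quantizer_spec, cond)
  seg <- path_to_beats(viterbi_min_duration(cfg$hmm1, syms)$path, ecg$fs)
  say("segmented ", nrow(seg$beats), " beats")
  aw <- NULL
  if (is.null(accel)) {
    say("no accelerometer stream: treating all beats as reliable (standing)")
  } else {
    aw <- classify_activity_stream(cfg$activity, accel)
  }
  feats <- extract_beat_features(seg, aw)
  if (!nrow(feats))
    return(structure(list(beats = empty, features = feats,
                          segmentation = seg, activity_windows = aw,
                          symbols = integer(0)),
                     class = "pipeline_result"))
  obs <- encode_beats(cfg$codebook, feats)
  hmm2 <- if (isTRUE(cfg$gate_motion)) gate_motion(cfg$hmm2) else cfg$hmm2
  labels <- classify_beats(hmm2, obs)
  say("classified ", length(labels), " beats")
  structure(list(beats = data.frame(fiducial = feats$fiducial,
                                    label = HMM2_STATES[labels],
                                    stringsAsFactors = FALSE),
                 features = feats, segmentation = seg,
                 activity_windows = aw, symbols = obs),
            class = "pipeline_result")
}

#' Fit both HMM layers from an annotated synthetic record
#'
#' Layer-by-layer supervised training against a generated record's ground
#' truth, under the same conditioning the pipeline applies at inference
#' time. The ECG is conditioned and quantized, and the Layer-1 HMM is
#' estimated from the symbol stream and the true state path. The Layer-2
#' HMM is then estimated on the output of the trained Layer 1: the record
#' is re-segmented by duration-constrained decoding, per-beat features are
#' extracted from the decoded boundaries, and decoded beats are matched to
#' the true beats (within `tol_ms`) to inherit their labels, with beats
#' flagged motion-corrupted training the Invalid state. Training the upper
#' layer on the lower layer's decoded output (rather than on the true
#' boundaries) makes the emission estimates reflect the features the
#' classifier will actually see.
#'
#' @param rec a `synth_record` from [generate_record()].
#' @param codebook a [feature_codebook].
#' @param notch,sg,quantizer_spec conditioning stages, as in
#'   [pipeline_config()].
#' @param tol_ms truth-matching tolerance for label transfer, ms.
#' @return A [pipeline_config] holding the fitted models.
#' @export
train_pipeline_models <- function(rec, codebook = feature_codebook(),
                                  notch = NULL, sg = sg_spec(),
                                  quantizer_spec = quantizer(),
                                  tol_ms = 150) {
  stopifnot(inherits(rec, "synth_record"))
  fs <- rec$ecg$fs
  notch <- if (is.null(notch)) notch_spec(50, fs, 6) else notch
  cond <- condition_ecg(rec$ecg, notch = notch, sg = sg)
  syms <- quantize(quantizer_spec, cond)
  hmm1 <- train_hmm1(list(rec$truth$state_path), list(syms))
  seg <- path_to_beats(viterbi_min_duration(hmm1, syms)$path, fs)
  tb <- rec$truth$beats
  feats <- extract_beat_features(seg)
  feats$activity <- "standing"
  m <- match_beats(data.frame(sample = feats$fiducial, label = "?"),
                   data.frame(sample = tb$fiducial, label = tb$label),
                   fs, tol_ms)
  keep <- sort(m$pairs$pred_i)
  truth_i <- m$pairs$ref_i[match(keep, m$pairs$pred_i)]
  feats <- feats[keep, , drop = FALSE]
  feats$activity <- ifelse(tb$motion[truth_i], "walking", "standing")
  obs <- encode_beats(codebook, feats)
  labels <- match(ifelse(tb$motion[truth_i], "Invalid",
                         tb$label[truth_i]), HMM2_STATES)
  hmm2 <- train_hmm2(labels, obs, n_symbols = codebook$n_symbols)
  pipeline_config(hmm1 = hmm1, hmm2 = hmm2, codebook = codebook,
                  notch = notch, sg = sg, quantizer_spec = quantizer_spec)
}

#' Evaluate pipeline output against reference beats
#'
#' Pairs predicted and reference fiducials with [match_beats()] and scores
#' the record with [score_record()].
#'
#' @param pred data frame `fiducial`, `label` (pipeline output).
#' @param ref reference data frame `fiducial`, `label`.
#' @param fs sampling rate in Hz.
#' @param tol_ms matching tolerance in ms.
#' @return A `record_score`.
#' @export
evaluate_beats <- function(pred, ref, fs, tol_ms = 150) {
  p <- data.frame(sample = pred$fiducial, label = pred$label)
  r <- data.frame(sample = ref$fiducial, label = ref$label)
  score_record(match_beats(p, r, fs, tol_ms), p, r)
}
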