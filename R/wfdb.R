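# Minimal WFDB (PhysioNet) support: .hea headers, .dat signals in formats
# 212 and 16, and MIT-format .atr beat annotations. Enough to ingest
# MIT-BIH Arrhythmia Database records (360 Hz, format 212) and to
# round-trip this package's own synthetic records. Ingestion is read-only
# and optional: nothing in the package requires external WFDB files.

# MIT annotation codes for the beat types this package distinguishes,
# plus common others so foreign records parse cleanly.
WFDB_ANN_CODES <- c("N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L,
                    "F" = 6L, "J" = 7L, "A" = 8L, "S" = 9L, "E" = 10L,
                    "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L, "+" = 28L,
                    "x" = 37L, "f" = 38L, "!" = 31L, "e" = 34L, "\"" = 39L,
                    "|" = 40L)

# strict three-class mapping; everything else is "other" and excluded
# from scoring downstream
wfdb_symbol_to_label <- function(sym) {
  ifelse(sym == "N", "Normal",
         ifelse(sym == "V", "PVC", ifelse(sym == "A", "APC", "other")))
}

parse_hea <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.numeric(top[4]) else NA_real_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "\\s+")[[1]]
    gain_spec <- if (length(f) >= 3) f[3] else "200"
    units <- sub("^[^/]*/?", "", gain_spec)
    gb <- sub("/.*", "", gain_spec)
    baseline <- if (grepl("\\(", gb))
      as.numeric(sub(".*\\((-?[0-9]+)\\).*", "\\1", gb)) else NA_real_
    gain <- as.numeric(sub("\\(.*", "", gb))
    if (is.na(gain) || gain == 0) gain <- 200
    adc_zero <- if (length(f) >= 5) as.numeric(f[5]) else 0
    if (is.na(baseline)) baseline <- adc_zero
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else
      paste0("sig", i)
    list(file = f[1], format = as.integer(sub("x.*|:.*|\\+.*", "", f[2])),
         gain = gain, baseline = baseline,
         units = if (nzchar(units)) units else "mV", desc = desc)
  })
  list(record = rec, nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_212 <- function(path, nsig, nsamp) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n3 <- (length(raw) %/% 3L) * 3L
  b <- matrix(as.integer(raw[seq_len(n3)]), nrow = 3L)
  s1 <- b[1L, ] + bitwShiftL(bitwAnd(b[2L, ], 15L), 8L)
  s2 <- b[3L, ] + bitwShiftL(bitwShiftR(b[2L, ], 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  all <- as.vector(rbind(s1, s2))
  matrix(all[seq_len((length(all) %/% nsig) * nsig)], ncol = nsig,
         byrow = TRUE)
}

read_dat_16 <- function(path, nsig) {
  v <- readBin(path, "integer", size = 2L, signed = TRUE, endian = "little",
               n = file.info(path)$size %/% 2L)
  matrix(v[seq_len((length(v) %/% nsig) * nsig)], ncol = nsig, byrow = TRUE)
}

#' Read a WFDB record with beat annotations
#'
#' Reads the selected lead of a WFDB record (formats 212 and 16) into a
#' millivolt [ecg_signal] and, when present, its MIT-format beat
#' annotations. Annotation symbols are mapped strictly: `N` to Normal, `V`
#' to PVC, `A` to APC, everything else to `other` (excluded from scoring
#' downstream).
#'
#' @param record record name (e.g. `"119"`).
#' @param dir directory holding `record.hea`, the `.dat` file(s) and
#'   optionally `record.atr`.
#' @param lead signal description to select (default `"MLII"`, the modified
#'   Lead II of the MIT-BIH recordings).
#' @param annotator annotation file extension (default `"atr"`); `NULL`
#'   skips annotations.
#' @return List of class `annotated_record`: `record`, `signal`
#'   ([ecg_signal], mV), `annotations` (data frame `sample`, `symbol`,
#'   `label`, strictly increasing samples).
#' @export
read_wfdb <- function(record, dir = ".", lead = "MLII", annotator = "atr") {
  hea <- file.path(dir, paste0(record, ".hea"))
  if (!file.exists(hea))
    stop_missing_data("external data required: WFDB header not found: ", hea)
  h <- parse_hea(hea)
  descs <- vapply(h$signals, `[[`, "", "desc")
  sel <- which(descs == lead)
  if (!length(sel))
    stop_input("record ", record, " has no lead '", lead,
               "' (available: ", paste(descs, collapse = ", "), ")")
  sel <- sel[1]
  datfile <- file.path(dir, h$signals[[sel]]$file)
  if (!file.exists(datfile))
    stop_missing_data("external data required: WFDB signal file not found: ",
                      datfile)
  fmt <- h$signals[[sel]]$format
  mat <- switch(as.character(fmt),
                "212" = read_dat_212(datfile, h$nsig, h$nsamp),
                "16" = read_dat_16(datfile, h$nsig),
                stop_input("unsupported WFDB format ", fmt))
  if (!is.na(h$nsamp) && nrow(mat) > h$nsamp)
    mat <- mat[seq_len(h$nsamp), , drop = FALSE]
  adc <- mat[, sel]
  mv <- (adc - h$signals[[sel]]$baseline) / h$signals[[sel]]$gain
  ann <- NULL
  if (!is.null(annotator)) {
    af <- file.path(dir, paste0(record, ".", annotator))
    if (file.exists(af)) ann <- read_wfdb_annotations(af)
  }
  structure(list(record = record,
                 signal = ecg_signal(mv, h$fs, unit = "mv"),
                 annotations = ann),
            class = "annotated_record")
}

#' Read an MIT-format annotation file
#'
#' @param path path to the `.atr` (or other annotator) file.
#' @return Data frame with `sample`, `symbol`, `label`.
#' @export
read_wfdb_annotations <- function(path) {
  if (!file.exists(path))
    stop_missing_data("external data required: annotation file not found: ",
                      path)
  raw <- as.integer(readBin(path, "raw", n = file.info(path)$size))
  i <- 1L; t <- 0
  samples <- numeric(0); codes <- integer(0)
  code_names <- stats::setNames(names(WFDB_ANN_CODES), WFDB_ANN_CODES)
  while (i + 1L <= length(raw)) {
    lo <- raw[i]; hi <- raw[i + 1L]; i <- i + 2L
    code <- bitwShiftR(hi, 2L)
    inc <- bitwShiftL(bitwAnd(hi, 3L), 8L) + lo
    if (code == 0L && inc == 0L) break
    if (code == 59L) {            # SKIP: 4 bytes, high word first
      if (i + 3L > length(raw)) stop_input("corrupt annotation stream")
      high <- raw[i] + bitwShiftL(raw[i + 1L], 8L)
      low <- raw[i + 2L] + bitwShiftL(raw[i + 3L], 8L)
      i <- i + 4L
      t <- t + high * 65536 + low
    } else if (code == 63L) {     # AUX: skip payload (padded to even)
      i <- i + inc + (inc %% 2L)
    } else if (code %in% c(60L, 61L, 62L)) {
      # NUM/SUB/CHN attribute words: no time advance
    } else {
      t <- t + inc
      samples <- c(samples, t)
      codes <- c(codes, code)
    }
  }
  sym <- code_names[as.character(codes)]
  sym[is.na(sym)] <- "Q"
  data.frame(sample = samples, symbol = unname(sym),
             label = wfdb_symbol_to_label(unname(sym)),
             stringsAsFactors = FALSE)
}

#' Write a WFDB record (format 16) with beat annotations
#'
#' Writes `record.hea`, a single-signal format-16 `.dat` file and, when
#' annotations are given, an MIT-format `record.atr`. Millivolt samples are
#' digitized as `round(mv * gain) + baseline`.
#'
#' @param x an [ecg_signal] in mV.
#' @param record record name.
#' @param dir output directory.
#' @param annotations optional data frame with `sample` and either `symbol`
#'   or `label` (Normal/PVC/APC) columns.
#' @param gain ADC units per mV (default 200).
#' @param baseline ADC value at 0 mV (default 0).
#' @param lead signal description written to the header (default "MLII").
#' @return The record name, invisibly.
#' @export
write_wfdb <- function(x, record, dir = ".", annotations = NULL,
                       gain = 200, baseline = 0, lead = "MLII") {
  stopifnot(inherits(x, "ecg_signal"))
  if (x$unit != "mv") stop_input("write_wfdb expects a millivolt signal")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adc <- as.integer(round(x$samples * gain) + baseline)
  if (any(adc < -32768L | adc > 32767L))
    stop_input("digitized samples overflow format 16")
  datname <- paste0(record, ".dat")
  writeLines(c(sprintf("%s 1 %g %d", record, x$fs, length(adc)),
               sprintf("%s 16 %g(%g)/mV 16 %g 0 0 0 %s",
                       datname, gain, baseline, baseline, lead)),
             file.path(dir, paste0(record, ".hea")))
  writeBin(adc, file.path(dir, datname), size = 2L, endian = "little")
  if (!is.null(annotations))
    write_wfdb_annotations(annotations, file.path(dir,
                                                  paste0(record, ".atr")))
  invisible(record)
}

#' Write an MIT-format annotation file
#'
#' @param annotations data frame with `sample` and `symbol` or `label`.
#' @param path output path.
#' @export
write_wfdb_annotations <- function(annotations, path) {
  sym <- if ("symbol" %in% names(annotations)) annotations$symbol
  else c(Normal = "N", PVC = "V", APC = "A",
         other = "Q")[annotations$label]
  codes <- WFDB_ANN_CODES[sym]
  if (any(is.na(codes))) stop_input("unknown annotation symbol")
  ord <- order(annotations$sample)
  samples <- annotations$sample[ord]; codes <- as.integer(codes[ord])
  con <- file(path, "wb"); on.exit(close(con))
  t <- 0
  word <- function(code, inc)
    writeBin(as.integer(c(bitwAnd(inc, 255L),
                          bitwShiftL(code, 2L) + bitwShiftR(inc, 8L))),
             con, size = 1L)
  for (k in seq_along(samples)) {
    inc <- samples[k] - t
    if (inc > 1023) {
      word(59L, 0L)   # SKIP carries the whole interval
      writeBin(as.integer(c(bitwAnd(inc %/% 65536, 255L),
                            bitwAnd(inc %/% 65536, 65535L) %/% 256L,
                            bitwAnd(inc, 255L),
                            bitwAnd(inc, 65535L) %/% 256L)),
               con, size = 1L)
      word(codes[k], 0L)
    } else {
      word(codes[k], as.integer(inc))
    }
    t <- samples[k]
  }
  word(0L, 0L)  # EOF
  invisible(path)
}
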