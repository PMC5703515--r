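#' Construct an SpO2 recording
#'
#' Container for an overnight pulse-oximetry saturation series sampled at a
#' fixed rate (1 Hz for the portable devices this package targets). Missing
#' or unreadable samples are kept in place as `NA` so that downstream
#' preprocessing can account for them; they are never silently dropped.
#'
#' @param samples Numeric vector of saturation values in percent. Non-missing
#'   values must lie in \[0, 100\]; missing samples are `NA`.
#' @param subject_id Subject identifier.
#' @param setting Recording setting, `"lab"` (supervised, simultaneous to
#'   polysomnography) or `"home"` (unattended).
#' @param sample_rate Sampling rate in Hz (default 1).
#' @param start_time Optional `POSIXct` start time.
#' @return An object of class `spo2_recording`.
#' @export
spo2_recording <- function(samples, subject_id = "anon", setting = c("lab", "home"),
                           sample_rate = 1, start_time = NULL) {
  setting <- match.arg(setting)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("recording must contain at least one sample")
  if (!is.numeric(sample_rate) || sample_rate <= 0) stop("sample_rate must be > 0")
  ok <- samples[!is.na(samples)]
  if (any(ok < 0 | ok > 100)) stop("non-missing saturation values must lie in [0, 100]")
  structure(
    list(subject_id = as.character(subject_id), setting = setting,
         sample_rate = sample_rate, samples = samples, start_time = start_time),
    class = "spo2_recording"
  )
}

#' @export
print.spo2_recording <- function(x, ...) {
  hrs <- (length(x$samples) - 1L) / x$sample_rate / 3600
  cat(sprintf("<spo2_recording> subject %s [%s], %d samples at %g Hz (%.2f h), %d missing\n",
              x$subject_id, x$setting, length(x$samples), x$sample_rate,
              hrs, sum(is.na(x$samples))))
  invisible(x)
}

#' Read an SpO2 recording from CSV or EDF
#'
#' The CSV dialect is one sample per row with columns `t_seconds,spo2`
#' (header required); an empty `spo2` cell encodes a missing sample. EDF
#' (European Data Format) files are read by a minimal built-in parser that
#' locates an SpO2-labelled channel; the series must be sampled at 1 Hz.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"edf"`; guessed from the file extension when
#'   omitted.
#' @param subject_id,setting Passed to [spo2_recording()]; `subject_id`
#'   defaults to the file name without extension.
#' @return An [spo2_recording()].
#' @export
read_spo2 <- function(path, format = c("auto", "csv", "edf"),
                      subject_id = NULL, setting = "lab") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- utils::read.csv(path, header = TRUE, colClasses = "character",
                          strip.white = TRUE)
    col <- grep("spo2|sat", names(df), ignore.case = TRUE)
    if (length(col) == 0L) stop("CSV has no saturation (spo2) column")
    raw <- df[[col[1L]]]
    samples <- suppressWarnings(as.numeric(raw))
    samples[!nzchar(raw)] <- NA_real_   # empty cell = missing
    spo2_recording(samples, subject_id = subject_id, setting = setting)
  } else {
    read_spo2_edf(path, subject_id = subject_id, setting = setting)
  }
}

#' Write an SpO2 recording to CSV
#'
#' Inverse of the CSV branch of [read_spo2()]: columns `t_seconds,spo2`,
#' missing samples written as empty cells, so a read/write/read round-trip
#' preserves sample values and the missing mask exactly.
#'
#' @param rec An [spo2_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spo2_csv <- function(rec, path) {
  stopifnot(inherits(rec, "spo2_recording"))
  t <- seq_along(rec$samples) - 1L
  s <- ifelse(is.na(rec$samples), "", format(rec$samples, trim = TRUE, digits = 10))
  writeLines(c("t_seconds,spo2", paste(t, s, sep = ",")), path)
  invisible(path)
}

# Minimal EDF reader: standard 256-byte header + 256 bytes per signal,
# 16-bit little-endian samples, digital-to-physical linear mapping. Only the
# SpO2-labelled channel is extracted and it must be stored at 1 Hz.
read_spo2_edf <- function(path, subject_id, setting) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_records <- as.integer(substr(hdr, 237, 244))
  rec_dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  fld <- function(w) {
    vapply(seq_len(ns), function(i) trimws(readChar(con, w, useBytes = TRUE)), "")
  }
  labels <- fld(16); fld(80); fld(8)                 # label, transducer, unit
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)                                            # prefiltering
  nsamp <- as.integer(fld(8)); fld(32)               # samples/record, reserved
  ch <- grep("spo2", labels, ignore.case = TRUE)
  if (length(ch) == 0L) stop("EDF has no SpO2-labelled channel")
  ch <- ch[1L]
  fs <- nsamp[ch] / rec_dur
  if (abs(fs - 1) > 1e-9) {
    stop("SpO2 channel is sampled at ", fs, " Hz; only 1 Hz recordings are supported")
  }
  out <- numeric(n_records * nsamp[ch])
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = nsamp[s], size = 2, signed = TRUE,
                      endian = "little")
      if (s == ch) {
        out[pos + seq_along(vals)] <- vals
        pos <- pos + length(vals)
      }
    }
  }
  scale <- (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
  phys <- phys_min[ch] + (out - dig_min[ch]) * scale
  phys[phys < 0 | phys > 100] <- NA_real_
  spo2_recording(phys, subject_id = subject_id, setting = setting)
}

#' Check recording validity
#'
#' Portable oximetry recordings with a total recording time (TRT) below 4 h
#' (signal loss, premature battery depletion or voluntary termination) are
#' not analysable and are marked invalid. TRT is computed on the raw
#' recording, before any artifact removal, as `(n_samples - 1) / sample_rate`;
#' exactly 4 h is valid (the exclusion rule is a strict `<`).
#'
#' @param rec An [spo2_recording()].
#' @param setting Optional override of the recording's setting.
#' @param min_hours Minimum TRT in hours (default 4).
#' @return A list with `valid`, `trt_hours` and `reason` (`NA` when valid).
#' @export
check_validity <- function(rec, setting = rec$setting, min_hours = 4) {
  stopifnot(inherits(rec, "spo2_recording"))
  trt <- (length(rec$samples) - 1L) / rec$sample_rate / 3600
  if (trt < min_hours) {
    list(valid = FALSE, trt_hours = trt, reason = sprintf("TRT<%gh", min_hours))
  } else {
    list(valid = TRUE, trt_hours = trt, reason = NA_character_)
  }
}

#' Read a per-subject cohort table
#'
#' Reads a CSV with one row per subject and the columns used throughout the
#' evaluation layer: `subject_id`, `group` (`nonCOPD`, `COPD` or
#' `training`), `ahi_psg`, and optionally `ahi_ox_lab`, `ahi_ox_home`,
#' `odi3`, `odi4` (all in events/h). This mirrors the layout of per-subject
#' test-set tables released with diagnostic-agreement studies.
#'
#' @param path CSV path.
#' @return A data.frame of subject records.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("subject_id", "ahi_psg")
  if (!all(need %in% names(df))) {
    stop("cohort table must contain columns: ", paste(need, collapse = ", "))
  }
  idx <- intersect(c("ahi_psg", "ahi_ox_lab", "ahi_ox_home", "odi3", "odi4"),
                   names(df))
  for (cl in idx) {
    df[[cl]] <- as.numeric(df[[cl]])
    if (any(df[[cl]] < 0, na.rm = TRUE)) stop("index column ", cl, " has negative values")
  }
  df
}
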