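#' @importFrom stats sd rnorm runif predict coef lm
#' @importFrom utils head tail
NULL

# Canonical channel names. Pulse sensors follow the device's numeric codes
# 1 = temple, 2 = carotid, 3 = pointer finger; temperatures are thermistor
# sites. All on-disk column names derive from these.
PM_PULSE_SENSORS <- c("temple", "carotid", "finger")
PM_TEMP_SITES <- c("forehead", "temple", "wrist_top", "wrist_bottom", "finger")
PM_FS_DEFAULT <- 66.67

pm_pulse_cols <- function() paste0("pulse_", PM_PULSE_SENSORS)
pm_temp_cols <- function() paste0("temp_", PM_TEMP_SITES)

#' Construct a raw multichannel recording
#'
#' A recording is one 10-minute (by default) session: three pulse channels
#' (temple, carotid, pointer finger), five skin-temperature channels
#' (forehead, temple, wrist top, wrist bottom, finger), all sampled at a
#' common rate, plus a start and end self-reported pain score (integers
#' 0--10) and subject/recording identifiers.
#'
#' @param subject_id,recording_id opaque identifier strings.
#' @param fs sampling rate in Hz (default 66.67).
#' @param pulse named list of numeric vectors, one per pulse sensor
#'   (`temple`, `carotid`, `finger`).
#' @param temperature named list of numeric vectors, one per temperature
#'   site (`forehead`, `temple`, `wrist_top`, `wrist_bottom`, `finger`).
#' @param pain_start,pain_end integer pain scores in 0--10 reported at the
#'   start and end of the session.
#' @param duration_s recording duration in seconds; every channel must have
#'   `round(fs * duration_s)` samples.
#' @param validate if `TRUE` (default) stop on any invariant violation.
#' @return an object of class `pm_recording`.
#' @export
pm_recording <- function(subject_id, recording_id, fs = PM_FS_DEFAULT,
                         pulse, temperature, pain_start, pain_end,
                         duration_s, validate = TRUE) {
  rec <- structure(
    list(
      subject_id = as.character(subject_id),
      recording_id = as.character(recording_id),
      fs = as.numeric(fs),
      duration_s = as.numeric(duration_s),
      pain_start = pain_start,
      pain_end = pain_end,
      pulse = pulse,
      temperature = temperature
    ),
    class = "pm_recording"
  )
  if (validate) {
    issues <- pm_validate_recording(rec)
    if (length(issues)) {
      stop("invalid recording: ", paste(issues, collapse = "; "), call. = FALSE)
    }
  }
  rec
}

#' Number of samples in a recording
#' @param rec a `pm_recording`.
#' @return integer sample count, `round(fs * duration_s)`.
#' @export
pm_n_samples <- function(rec) as.integer(round(rec$fs * rec$duration_s))

#' Validate a recording against its invariants
#'
#' Checks, without stopping: sampling rate positive; pain scores integer and
#' in 0--10; all eight channels present; every channel of length
#' `round(fs * duration_s)`.
#'
#' @param rec a `pm_recording` (or structurally similar list).
#' @return character vector of human-readable issues; empty iff valid.
#' @export
pm_validate_recording <- function(rec) {
  issues <- character()
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || is.na(rec$fs) || rec$fs <= 0) {
    issues <- c(issues, "fs: sampling rate must be a single positive number")
  }
  if (!is.numeric(rec$duration_s) || length(rec$duration_s) != 1 ||
      is.na(rec$duration_s) || rec$duration_s <= 0) {
    issues <- c(issues, "duration_s: must be a single positive number")
  }
  for (fld in c("pain_start", "pain_end")) {
    v <- rec[[fld]]
    ok <- is.numeric(v) && length(v) == 1 && !is.na(v) && v == round(v) &&
      v >= 0 && v <= 10
    if (!ok) issues <- c(issues, paste0(fld, ": must be an integer in [0, 10]"))
  }
  n_expect <- if (is.numeric(rec$fs) && is.numeric(rec$duration_s) &&
                  length(rec$fs) == 1 && length(rec$duration_s) == 1 &&
                  !anyNA(c(rec$fs, rec$duration_s))) {
    as.integer(round(rec$fs * rec$duration_s))
  } else {
    NA_integer_
  }
  for (s in PM_PULSE_SENSORS) {
    sig <- rec$pulse[[s]]
    if (is.null(sig)) {
      issues <- c(issues, paste0("pulse_", s, ": channel missing"))
    } else if (!is.na(n_expect) && length(sig) != n_expect) {
      issues <- c(issues, sprintf(
        "pulse_%s: length %d != round(fs * duration_s) = %d", s, length(sig), n_expect))
    }
  }
  for (s in PM_TEMP_SITES) {
    sig <- rec$temperature[[s]]
    if (is.null(sig)) {
      issues <- c(issues, paste0("temp_", s, ": channel missing"))
    } else if (!is.na(n_expect) && length(sig) != n_expect) {
      issues <- c(issues, sprintf(
        "temp_%s: length %d != round(fs * duration_s) = %d", s, length(sig), n_expect))
    }
  }
  issues
}

#' @export
print.pm_recording <- function(x, ...) {
  cat(sprintf(
    "<pm_recording> %s / %s: %.0f s @ %.2f Hz (%d samples), pain %d -> %d\n",
    x$subject_id, x$recording_id, x$duration_s, x$fs, pm_n_samples(x),
    x$pain_start, x$pain_end))
  invisible(x)
}

#' Write a recording to its plain-text on-disk format
#'
#' UTF-8 text: `#key<TAB>value` header lines (subject_id, recording_id, fs,
#' pain_start, pain_end, duration_s) followed by a TSV body with columns
#' `t`, `pulse_temple`, `pulse_carotid`, `pulse_finger`, `temp_forehead`,
#' `temp_temple`, `temp_wrist_top`, `temp_wrist_bottom`, `temp_finger`, one
#' row per sample tick. Numeric values are written with 15 significant
#' digits, comfortably above the 6 the format guarantees.
#'
#' @param rec a valid `pm_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
pm_write_recording <- function(rec, path) {
  issues <- pm_validate_recording(rec)
  if (length(issues)) {
    stop("refusing to write invalid recording: ",
         paste(issues, collapse = "; "), call. = FALSE)
  }
  n <- pm_n_samples(rec)
  header <- c(
    paste0("#subject_id\t", rec$subject_id),
    paste0("#recording_id\t", rec$recording_id),
    paste0("#fs\t", format(rec$fs, digits = 15)),
    paste0("#pain_start\t", as.integer(rec$pain_start)),
    paste0("#pain_end\t", as.integer(rec$pain_end)),
    paste0("#duration_s\t", format(rec$duration_s, digits = 15))
  )
  body <- data.table::data.table(t = (seq_len(n) - 1) / rec$fs)
  for (s in PM_PULSE_SENSORS) body[[paste0("pulse_", s)]] <- rec$pulse[[s]]
  for (s in PM_TEMP_SITES) body[[paste0("temp_", s)]] <- rec$temperature[[s]]
  con <- file(path, open = "wb")
  writeLines(header, con, sep = "\n")
  close(con)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = TRUE,
                     eol = "\n")
  invisible(path)
}

#' Read a recording written by [pm_write_recording()]
#'
#' @param path path to a recording file.
#' @return a validated `pm_recording`.
#' @export
pm_read_recording <- function(path) {
  if (!file.exists(path)) stop("no such recording file: ", path, call. = FALSE)
  hdr_lines <- character()
  con <- file(path, open = "r")
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr_lines <- c(hdr_lines, ln)
  }
  close(con)
  kv <- strsplit(sub("^#", "", hdr_lines), "\t", fixed = TRUE)
  meta <- stats::setNames(
    vapply(kv, `[`, character(1), 2L),
    vapply(kv, `[`, character(1), 1L))
  need <- c("subject_id", "recording_id", "fs", "pain_start", "pain_end",
            "duration_s")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    stop("recording header missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (fld in c("pain_start", "pain_end")) {
    v <- suppressWarnings(as.numeric(meta[[fld]]))
    if (is.na(v) || v != round(v) || v < 0 || v > 10) {
      stop(fld, ": must be an integer in [0, 10], got '", meta[[fld]], "'",
           call. = FALSE)
    }
  }
  body <- data.table::fread(path, sep = "\t", skip = length(hdr_lines),
                            header = TRUE, data.table = FALSE)
  for (col in c(pm_pulse_cols(), pm_temp_cols())) {
    if (!col %in% names(body)) {
      stop("recording body missing channel column: ", col, call. = FALSE)
    }
  }
  rec <- pm_recording(
    subject_id = meta[["subject_id"]],
    recording_id = meta[["recording_id"]],
    fs = as.numeric(meta[["fs"]]),
    pulse = stats::setNames(
      lapply(PM_PULSE_SENSORS, function(s) body[[paste0("pulse_", s)]]),
      PM_PULSE_SENSORS),
    temperature = stats::setNames(
      lapply(PM_TEMP_SITES, function(s) body[[paste0("temp_", s)]]),
      PM_TEMP_SITES),
    pain_start = as.integer(as.numeric(meta[["pain_start"]])),
    pain_end = as.integer(as.numeric(meta[["pain_end"]])),
    duration_s = as.numeric(meta[["duration_s"]]),
    validate = FALSE
  )
  issues <- pm_validate_recording(rec)
  if (length(issues)) {
    stop("recording file fails validation: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  rec
}

#' Write a cohort manifest
#'
#' TSV with columns `subject_id`, `recording_id`, `path`. `recording_id`s
#' must be unique.
#'
#' @param manifest data.frame with those three columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
pm_write_manifest <- function(manifest, path) {
  stopifnot(all(c("subject_id", "recording_id", "path") %in% names(manifest)))
  if (anyDuplicated(manifest$recording_id)) {
    stop("manifest recording_ids must be unique", call. = FALSE)
  }
  data.table::fwrite(
    manifest[, c("subject_id", "recording_id", "path")], path,
    sep = "\t", eol = "\n")
  invisible(path)
}

#' Read a cohort manifest
#'
#' @param path manifest TSV path.
#' @param check_paths verify every referenced recording file exists.
#' @return data.frame with columns `subject_id`, `recording_id`, `path`.
#' @export
pm_read_manifest <- function(path, check_paths = TRUE) {
  m <- data.table::fread(path, sep = "\t", data.table = FALSE,
                         colClasses = "character")
  stopifnot(all(c("subject_id", "recording_id", "path") %in% names(m)))
  if (anyDuplicated(m$recording_id)) {
    stop("manifest recording_ids must be unique", call. = FALSE)
  }
  if (check_paths) {
    missing <- m$path[!file.exists(m$path)]
    if (length(missing)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
  }
  m
}
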