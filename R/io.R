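#' Read an ECG recording and its per-minute annotations
#'
#' Reads either the WFDB-style layout written by [write_recording()]
#' (`.hea` header, 16-bit little-endian `.dat`, optional `.apn` annotation
#' file) or the CSV fallback (one sample per line, optional `.labels`
#' sidecar). Annotation files may hold one character per line or a single
#' string of characters; both dialects are accepted. A trailing partial
#' minute of signal is discarded with a warning so that labels and minutes
#' stay aligned.
#'
#' @param path Base path without extension.
#' @param format `"wfdb"` or `"csv"`.
#' @param fs Sampling rate in Hz, needed for `"csv"` (the WFDB header carries
#'   its own).
#' @param record_id Identifier; defaults to the base file name.
#' @return A list of class `ecg_recording`: `record_id`, `signal`, `fs`,
#'   `minute_labels` (or `NULL`), `ahi_class` (or `NA`).
#' @export
read_recording <- function(path, format = c("wfdb", "csv"), fs = 100,
                           record_id = basename(path)) {
  format <- match.arg(format)
  if (format == "wfdb") {
    hea <- paste0(path, ".hea")
    if (!file.exists(hea)) {
      abort(sprintf("read_recording: missing header file '%s'", hea),
            class = "apneatw_format_error")
    }
    lines <- readLines(hea, warn = FALSE)
    top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(top) < 4) {
      abort(sprintf("read_recording: malformed record line in '%s'", hea),
            class = "apneatw_format_error")
    }
    fs <- as.numeric(top[3])
    nsamp <- as.integer(top[4])
    if (!is.finite(fs) || fs <= 0) {
      abort(sprintf("read_recording: header '%s' declares fs = %s (must be > 0)",
                    hea, top[3]), class = "apneatw_format_error")
    }
    ch <- strsplit(trimws(lines[2]), "\\s+")[[1]]
    gain <- as.numeric(sub("/.*$", "", ch[3]))
    if (!is.finite(gain) || gain <= 0) gain <- 1
    dat <- paste0(path, ".dat")
    if (!file.exists(dat)) {
      abort(sprintf("read_recording: missing signal file '%s'", dat),
            class = "apneatw_format_error")
    }
    raw <- readBin(dat, "integer", n = nsamp, size = 2L, signed = TRUE,
                   endian = "little")
    if (length(raw) != nsamp) {
      abort(sprintf(
        "read_recording: '%s' holds %d samples but header declares %d",
        dat, length(raw), nsamp), class = "apneatw_format_error")
    }
    sig <- raw / gain
    labels <- read_label_file(paste0(path, ".apn"))
  } else {
    csv <- paste0(path, ".csv")
    if (!file.exists(csv)) {
      abort(sprintf("read_recording: missing signal file '%s'", csv),
            class = "apneatw_format_error")
    }
    sig <- as.numeric(readLines(csv, warn = FALSE))
    if (anyNA(sig)) {
      abort(sprintf("read_recording: non-numeric sample values in '%s'", csv),
            class = "apneatw_format_error")
    }
    labels <- read_label_file(paste0(path, ".labels"))
  }

  spm <- as.integer(round(60 * fs))
  n_min <- length(sig) %/% spm
  if (n_min < 1) {
    abort(sprintf(
      "read_recording: '%s' holds %.1f s of signal; at least one full minute is required",
      path, length(sig) / fs), class = "apneatw_format_error")
  }
  if (length(sig) > n_min * spm) {
    warn(sprintf(
      "read_recording: '%s' has a trailing partial minute (%.1f s); discarded",
      record_id, (length(sig) - n_min * spm) / fs))
    sig <- sig[seq_len(n_min * spm)]
  }
  if (!is.null(labels) && length(labels) != n_min) {
    abort(sprintf(
      "read_recording: '%s' annotation file has %d labels for %d full minutes of signal",
      record_id, length(labels), n_min), class = "apneatw_format_error")
  }
  ahi_class <- NA_character_
  if (!is.null(labels)) {
    ahi <- 60 / n_min * sum(labels == "A")
    ahi_class <- if (ahi > 10) "A" else if (ahi >= 5) "B" else "C"
  }
  structure(list(record_id = record_id, signal = sig, fs = fs,
                 minute_labels = labels, ahi_class = ahi_class),
            class = "ecg_recording")
}

# Accepts one label character per line or a single concatenated string.
read_label_file <- function(path) {
  if (!file.exists(path)) return(NULL)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(NULL)
  labels <- if (length(lines) == 1 && nchar(lines) > 1) {
    strsplit(lines, "")[[1]]
  } else {
    lines
  }
  if (!all(labels %in% c("A", "N"))) {
    abort(sprintf("read_recording: annotation file '%s' contains labels other than 'A'/'N'",
                  path), class = "apneatw_format_error")
  }
  labels
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording '%s'> %.0f min @ %g Hz%s\n", x$record_id,
              length(x$signal) / (60 * x$fs), x$fs,
              if (is.null(x$minute_labels)) ", unlabelled"
              else sprintf(", %d apnea min, class %s",
                           sum(x$minute_labels == "A"), x$ahi_class)))
  invisible(x)
}

#' Split a recording into contiguous one-minute segments
#'
#' Minute `k` (0-based) covers the half-open sample range
#' `[k * 60 * fs, (k + 1) * 60 * fs)`; slices are contiguous,
#' non-overlapping and concatenate back to the retained signal exactly.
#'
#' @param rec An `ecg_recording` (or a `synth_recording`).
#' @return A tibble with columns `minute` (0-based), `start`, `end` (1-based
#'   inclusive sample indices), `label` (`NA` when unlabelled) and `slice`
#'   (list column of sample vectors).
#' @export
segment_minutes <- function(rec) {
  spm <- as.integer(round(60 * rec$fs))
  n_min <- length(rec$signal) %/% spm
  labels <- rec$minute_labels %||% rep(NA_character_, n_min)
  tibble(
    minute = seq_len(n_min) - 1L,
    start = (seq_len(n_min) - 1L) * spm + 1L,
    end = seq_len(n_min) * spm,
    label = labels[seq_len(n_min)],
    slice = purrr::map2(.data$start, .data$end, ~ rec$signal[.x:.y])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
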