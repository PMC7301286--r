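#' Write a recording as CSV
#'
#' Plain numeric dialect: first column \code{time} in seconds, one column
#' per channel, header row of montage labels.
#'
#' @param recording An \code{eeg_recording}.
#' @param path Output file path.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- ncol(recording$data)
  df <- data.frame(time = (0:(n - 1)) / recording$fs)
  for (i in seq_along(recording$channel_labels))
    df[[recording$channel_labels[i]]] <- recording$data[i, ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from CSV
#'
#' Inverse of [write_recording_csv()].  The sampling rate is recovered
#' from the time column unless given.  Channel labels are validated
#' against the 10-20 montage set unless \code{validate_labels = FALSE}.
#'
#' @param path CSV file path.
#' @param subject_id,group Metadata to attach (defaults: file stem, NA).
#' @param fs Sampling rate; inferred from the time column when NULL.
#' @param validate_labels Require labels from [MONTAGE_10_20].
#' @return An \code{eeg_recording}.
#' @export
read_recording_csv <- function(path, subject_id = NULL, group = NA_character_,
                               fs = NULL, validate_labels = TRUE) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop_param("CSV lacks a 'time' column")
  labels <- setdiff(names(df), "time")
  if (validate_labels) {
    bad <- setdiff(labels, MONTAGE_10_20)
    if (length(bad))
      stop_param("channel labels not in the 10-20 set: %s (use validate_labels = FALSE to override)",
                 paste(bad, collapse = ", "))
  }
  if (is.null(fs)) {
    dt <- diff(df$time[1:2])
    if (!is.finite(dt) || dt <= 0) stop_param("cannot infer fs from time column")
    fs <- round(1 / dt)
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  data <- t(as.matrix(df[labels]))
  new_recording(subject_id, group, data, fs, labels)
}

# --- minimal EDF (16-bit European Data Format) I/O -------------------------
# Fixed 256-byte header + 256 bytes per signal, then data records of
# little-endian int16, one second per record here.  Physical scaling is
# symmetric around zero with per-signal physical maxima.

edf_pad <- function(x, width) {
  x <- as.character(x)
  substr(paste0(x, strrep(" ", width)), 1, width)
}

#' Write a recording as EDF
#'
#' Minimal EDF writer: one file per subject, channel labels and sampling
#' rate in the header, one-second data records, 16-bit samples scaled to
#' each channel's physical peak.  Quantization error is bounded by
#' \code{peak/32767} per channel.
#'
#' @param recording An \code{eeg_recording}; \code{fs} must be a whole
#'   number and the sample count a whole number of seconds.
#' @param path Output file path.
#' @export
write_recording_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  ns <- nrow(recording$data)
  n <- ncol(recording$data)
  fs <- recording$fs
  if (fs != round(fs) || n %% fs != 0)
    stop_param("EDF writer needs integer fs and whole seconds of data")
  n_rec <- n %/% fs
  pmax_ <- pmax(apply(abs(recording$data), 1, max), 1e-12)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id, 80),
    edf_pad(paste("group", recording$group), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    paste(vapply(recording$channel_labels, edf_pad, "", width = 16),
          collapse = ""),
    strrep(" ", 80 * ns),                       # transducer
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(vapply(sprintf("%.6g", -pmax_), edf_pad, "", width = 8),
          collapse = ""),
    paste(vapply(sprintf("%.6g", pmax_), edf_pad, "", width = 8),
          collapse = ""),
    paste(rep(edf_pad("-32768", 8), ns), collapse = ""),
    paste(rep(edf_pad("32767", 8), ns), collapse = ""),
    strrep(" ", 80 * ns),                       # prefiltering
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    strrep(" ", 32 * ns))
  writeChar(hdr, con, eos = NULL)
  scale <- 32767 / pmax_
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- t(recording$data[, idx, drop = FALSE] * scale)
    writeBin(as.integer(round(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads files produced by [write_recording_edf()] and plain
#' fixed-rate EDF files generally (no EDF+ annotation channels).
#'
#' @param path EDF file path.
#' @param group Group label to attach (EDF itself stores none in a
#'   structured way; the writer stores it in the recording-id field).
#' @param validate_labels Require 10-20 montage labels.
#' @return An \code{eeg_recording}.
#' @export
read_recording_edf <- function(path, group = NULL, validate_labels = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  invisible(rd(8))
  subject_id <- rd(80)
  rec_field <- rd(80)
  invisible(rd(8)); invisible(rd(8)); invisible(rd(8)); invisible(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  invisible(replicate(ns, rd(80)))
  invisible(replicate(ns, rd(8)))                       # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  invisible(replicate(ns, rd(80)))
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  invisible(replicate(ns, rd(32)))
  if (length(unique(spr)) != 1)
    stop_param("mixed per-signal rates are not supported")
  fs <- spr[1] / rec_dur
  if (validate_labels) {
    bad <- setdiff(labels, MONTAGE_10_20)
    if (length(bad))
      stop_param("channel labels not in the 10-20 set: %s",
                 paste(bad, collapse = ", "))
  }
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  data <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    data[, idx] <- t(block) * gain + (pmin_ - dmin_ * gain)
  }
  if (is.null(group))
    group <- if (startsWith(rec_field, "group "))
      sub("^group ", "", rec_field) else NA_character_
  new_recording(subject_id, group, data, fs, labels)
}

#' Write a cohort to disk
#'
#' One file per subject, named \code{<subject_id>.<ext>}, plus a
#' \code{groups.tsv} manifest (subject, group) since the CSV dialect has
#' no metadata slot for the group label.
#'
#' @param cohort List of \code{eeg_recording} objects.
#' @param dir Output directory (created if needed).
#' @param format "csv" or "edf".
#' @return Invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(rec) {
    p <- file.path(dir, paste0(rec$subject_id, ".", format))
    if (format == "csv") write_recording_csv(rec, p)
    else write_recording_edf(rec, p)
    p
  }, "")
  man <- data.frame(subject = vapply(cohort, function(r) r$subject_id, ""),
                    group = vapply(cohort, function(r) r$group, ""))
  utils::write.table(man, file.path(dir, "groups.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
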