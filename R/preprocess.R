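#' Epoch extraction scheme
#'
#' Fixed epoch windows in 0-based, half-open sample coordinates
#' \code{[offset, offset + length)}.  The defaults take a 5-s window
#' (5,000 samples at 1 kHz) from the beginning, middle and end of a 180-s
#' recording: offsets 25,000, 85,000 and 145,000.  The half-open convention
#' makes a window stated as "samples 25,000-30,000" contain exactly 5,000
#' samples.
#'
#' @param offsets Strictly increasing 0-based sample offsets.
#' @param length Samples per epoch (> 0).
#' @return An \code{epoch_spec} object.
#' @export
epoch_spec <- function(offsets = c(25000L, 85000L, 145000L),
                       length = 5000L) {
  if (length <= 0) stop_param("epoch length must be positive")
  if (is.unsorted(offsets, strictly = TRUE))
    stop_param("offsets must be strictly increasing")
  if (any(offsets < 0)) stop_param("offsets must be non-negative")
  structure(list(offsets = as.integer(offsets),
                 length = as.integer(length)),
            class = "epoch_spec")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth band-pass (designed with [signal::butter()])
#' applied forward and backward, so the net phase response is zero and the
#' effective attenuation doubles.  Edges are handled by odd-reflection
#' padding.  The default band 0.5-70 Hz mirrors typical clinical EEG
#' acquisition hardware.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Passband edges in Hz; \code{0 < f_lo < f_hi < fs/2}.
#' @return Filtered signal, same length as \code{x}.
#' @export
bandpass_filter <- function(x, fs, f_lo = 0.5, f_hi = 70) {
  if (!(f_lo > 0 && f_lo < f_hi))
    stop_param("need 0 < f_lo (%g) < f_hi (%g)", f_lo, f_hi)
  if (f_hi >= fs / 2)
    stop_param("f_hi (%g Hz) must lie below the Nyquist frequency (%g Hz)",
               f_hi, fs / 2)
  flt <- butter_coefs(fs, f_lo, f_hi)
  # pad past the slowest transient: a few periods of the high-pass corner
  pad <- min(length(x) - 1L, as.integer(ceiling(3 * fs / f_lo)))
  .filtfilt_cpp(flt$b, flt$a, x, pad)
}

.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(fs, f_lo, f_hi) {
  key <- sprintf("%g_%g_%g", fs, f_lo, f_hi)
  hit <- .butter_cache[[key]]
  if (!is.null(hit)) return(hit)
  bt <- signal::butter(2, c(f_lo, f_hi) / (fs / 2), type = "pass")
  out <- list(b = bt$b, a = bt$a)
  .butter_cache[[key]] <- out
  out
}

#' Band-pass filter every channel of a recording
#'
#' @param recording An \code{eeg_recording}.
#' @inheritParams bandpass_filter
#' @return The recording with all channels filtered.
#' @export
filter_recording <- function(recording, f_lo = 0.5, f_hi = 70) {
  stopifnot(inherits(recording, "eeg_recording"))
  for (ch in seq_len(nrow(recording$data)))
    recording$data[ch, ] <- bandpass_filter(recording$data[ch, ],
                                            recording$fs, f_lo, f_hi)
  recording
}

#' Extract fixed epochs from a recording
#'
#' One epoch per (channel, offset); sample windows are 0-based half-open
#' \code{[offset, offset + length)} and are copied verbatim (no filtering or
#' detrending happens here).  Epoch indices are 0-based in offset order.
#'
#' @param recording An \code{eeg_recording}.
#' @param spec An [epoch_spec()].
#' @return List of \code{eeg_epoch} objects (channels x offsets of them),
#'   each carrying \code{subject_id}, \code{group}, \code{channel_label},
#'   \code{epoch_index}, \code{samples} and \code{fs}.
#' @export
extract_epochs <- function(recording, spec = epoch_spec()) {
  stopifnot(inherits(recording, "eeg_recording"),
            inherits(spec, "epoch_spec"))
  n <- ncol(recording$data)
  bad <- spec$offsets[spec$offsets + spec$length > n]
  if (length(bad))
    stop_param(paste0("recording shorter than epoch window: %d samples, ",
                      "but offset %d needs %d"),
               n, bad[1], bad[1] + spec$length)
  out <- vector("list", nrow(recording$data) * length(spec$offsets))
  idx <- 1L
  for (ch in seq_len(nrow(recording$data))) {
    for (ei in seq_along(spec$offsets)) {
      off <- spec$offsets[ei]
      out[[idx]] <- structure(
        list(subject_id = recording$subject_id, group = recording$group,
             channel_label = recording$channel_labels[ch],
             epoch_index = ei - 1L,
             samples = recording$data[ch, (off + 1L):(off + spec$length)],
             fs = recording$fs),
        class = "eeg_epoch")
      idx <- idx + 1L
    }
  }
  out
}

#' Amplitude-threshold epoch rejection
#'
#' Simple artifact hook: epochs whose peak absolute amplitude exceeds
#' \code{amplitude_limit} are moved to the rejected set.  The partition is
#' exhaustive and disjoint.  This stands in for component-based artifact
#' cleaning (e.g. ICA), which this package deliberately delegates to
#' dedicated EEG tooling.
#'
#' @param epochs List of \code{eeg_epoch} objects.
#' @param amplitude_limit Positive rejection threshold.
#' @return List with elements \code{kept} and \code{rejected}.
#' @export
reject_epochs <- function(epochs, amplitude_limit) {
  if (amplitude_limit <= 0) stop_param("amplitude_limit must be positive")
  peak <- vapply(epochs, function(e) max(abs(e$samples)), numeric(1))
  keep <- peak <= amplitude_limit
  list(kept = epochs[keep], rejected = epochs[!keep])
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch> %s/%s %s #%d: %d samples @ %g Hz\n",
              x$subject_id, x$group, x$channel_label, x$epoch_index,
              length(x$samples), x$fs))
  invisible(x)
}
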