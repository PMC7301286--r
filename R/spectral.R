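#' Frequency band definition
#'
#' @param name Band name.
#' @param f_lo,f_hi Band edges in Hz, \code{0 < f_lo < f_hi}.  Bands are
#'   half-open: power is integrated over \code{[f_lo, f_hi)}.
#' @return A \code{freq_band} object.
#' @export
band <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi))
    stop_param("band %s: need 0 < f_lo < f_hi", name)
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "freq_band")
}

#' Default EEG bands: low alpha, high alpha, beta
#'
#' Low alpha 8-10 Hz, high alpha 10-12 Hz, beta 13-30 Hz.
#' @return Named list of [band()] objects.
#' @export
default_bands <- function() {
  list(low_alpha = band("low_alpha", 8, 10),
       high_alpha = band("high_alpha", 10, 12),
       beta = band("beta", 13, 30))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: Hann-windowed segments (default 1 s) with
#' 50% overlap, one-sided density normalized so that
#' \code{sum(psd) * df} equals the mean square of the (mean-removed) signal
#' up to spectral leakage.  Written out here because the estimator choice
#' (window, overlap, normalization) must be explicit and configurable.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param window_s Segment length in seconds (default 1).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with \code{freq} (Hz) and \code{psd} (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nseg <- as.integer(round(window_s * fs))
  if (length(x) < nseg)
    stop_param("signal (%d samples) shorter than one Welch segment (%d)",
               length(x), nseg)
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  x <- x - mean(x)
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  nh <- nseg %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- fft(x[s:(s + nseg - 1L)] * w)
    acc <- acc + Mod(seg[1:(nh + 1L)])^2
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nh + 1L)
  dbl[1] <- 1
  if (nseg %% 2L == 0L) dbl[nh + 1L] <- 1
  list(freq = (0:nh) * fs / nseg, psd = psd * dbl)
}

#' Band power of a signal
#'
#' Integrates the Welch spectral density over \code{[f_lo, f_hi)}
#' (half-open, rectangle rule over frequency bins).  Invariant to the
#' signal mean.
#'
#' @param x Numeric signal (at least 2 s of samples recommended).
#' @param fs Sampling rate in Hz.
#' @param bd A [band()]; \code{f_hi} must lie below Nyquist.
#' @param window_s,overlap Welch settings, see [welch_psd()].
#' @return Non-negative power value.
#' @export
band_power <- function(x, fs, bd, window_s = 1, overlap = 0.5) {
  stopifnot(inherits(bd, "freq_band"))
  if (bd$f_hi > fs / 2)
    stop_param("band %s (%g-%g Hz) exceeds Nyquist (%g Hz)",
               bd$name, bd$f_lo, bd$f_hi, fs / 2)
  sp <- welch_psd(x, fs, window_s, overlap)
  sel <- sp$freq >= bd$f_lo & sp$freq < bd$f_hi
  df <- sp$freq[2] - sp$freq[1]
  sum(sp$psd[sel]) * df
}

#' Band-power feature rows for a set of epochs
#'
#' Same long format as [features_for_epochs()] (one row per epoch and
#' band, \code{measure} set to the band name) so the statistics stage is
#' shared between complexity and spectral features.
#'
#' @param epochs List of \code{eeg_epoch} objects.
#' @param bands List of [band()] objects (default [default_bands()]).
#' @param window_s,overlap Welch settings.
#' @return A data.frame with columns \code{subject}, \code{group},
#'   \code{channel}, \code{epoch}, \code{measure}, \code{value},
#'   \code{defined}.
#' @export
band_power_table <- function(epochs, bands = default_bands(),
                             window_s = 1, overlap = 0.5) {
  if (length(epochs) == 0 || length(bands) == 0)
    return(empty_feature_table())
  rows <- lapply(epochs, function(e) {
    vals <- vapply(bands, function(bd)
      band_power(e$samples, e$fs, bd, window_s, overlap), numeric(1))
    data.frame(subject = e$subject_id, group = e$group,
               channel = e$channel_label, epoch = e$epoch_index,
               measure = vapply(bands, function(bd) bd$name, character(1)),
               value = unname(vals), defined = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
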