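#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth filtering. The band-pass is
#' applied as a cascade of a 4th-order high-pass at `low` and a 4th-order
#' low-pass at `high`; the cascade is numerically stable even when the band
#' spans almost the whole Nyquist range (the default 0.5-128 Hz chain at a
#' 256 Hz sampling rate), and forward-backward application doubles the
#' effective attenuation while cancelling phase distortion.
#'
#' When `high` reaches or exceeds Nyquist it is clipped to 0.99 x Nyquist
#' with a warning.
#'
#' @param rec an [recording()].
#' @param low,high band edges in Hz, `0 < low < high`.
#' @param order Butterworth prototype order for each edge (default 4).
#' @return filtered `eeg_recording`.
#' @seealso [notch_filter()], [remove_blink_artifacts()]
#' @export
bandpass_filter <- function(rec, low = 0.5, high = 128, order = 4) {
  stopifnot_recording(rec)
  nyq <- rec$sampling_rate / 2
  if (!(low > 0) || !(high > low)) stop("need 0 < low < high")
  if (high >= nyq) {
    high <- 0.99 * nyq
    warning(sprintf("high edge clipped to 0.99 x Nyquist = %.2f Hz", high))
    if (high <= low) stop("band collapses after Nyquist clipping")
  }
  hp <- signal::butter(order, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  out <- t(apply(rec$signal, 1, function(x) {
    x <- x - mean(x)          # exact DC removal avoids edge transients
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  rec$signal <- out
  rownames(rec$signal) <- rec$channel_labels
  rec
}

#' Notch filter (power-line removal)
#'
#' Zero-phase second-order IIR notch (biquad) at `freq` Hz with quality
#' factor `q`; the default removes 60 Hz mains interference while leaving
#' frequencies 5 Hz away essentially untouched.
#'
#' @param rec an [recording()].
#' @param freq notch centre frequency in Hz (default 60).
#' @param q quality factor, centre frequency over -3 dB bandwidth
#'   (default 30).
#' @return filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq = 60, q = 30) {
  stopifnot_recording(rec)
  nyq <- rec$sampling_rate / 2
  if (freq >= nyq) stop("notch frequency must be below Nyquist")
  w0 <- pi * freq / nyq                 # radians/sample
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  b <- b / a[1]; a <- a / a[1]
  flt <- signal::Arma(b = b, a = a)
  rec$signal <- t(apply(rec$signal, 1, function(x) signal::filtfilt(flt, x)))
  rownames(rec$signal) <- rec$channel_labels
  rec
}

#' Excise high-amplitude frontal transients (blink stand-in)
#'
#' Samples where any frontal channel (Fp1, Fp2, F3, F4) exceeds `threshold`
#' microvolts in absolute value are excised, together with a window of
#' `window` milliseconds centred on each offending sample, from all
#' channels; the surviving segments are concatenated. This is a simple
#' amplitude-threshold artifact rejector: blinks project most strongly onto
#' frontal leads, so windows around large frontal excursions are treated as
#' contaminated.
#'
#' The excised fraction is stored in `$excised_fraction`; if it exceeds 50%
#' the recording is flagged `"excessive_artifact"`.
#'
#' @param rec an [recording()].
#' @param threshold amplitude threshold in microvolts (default 100).
#' @param window excision window in milliseconds (default 400).
#' @return `eeg_recording` with contaminated windows removed.
#' @export
remove_blink_artifacts <- function(rec, threshold = 100, window = 400) {
  stopifnot_recording(rec)
  if (threshold <= 0) stop("`threshold` must be positive")
  frontal <- intersect(c("Fp1", "Fp2", "F3", "F4"), rec$channel_labels)
  n <- ncol(rec$signal)
  exceed <- apply(abs(rec$signal[frontal, , drop = FALSE]) > threshold, 2, any)
  if (!any(exceed)) return(rec)
  half <- ceiling(window / 1000 * rec$sampling_rate / 2)
  bad <- rep(FALSE, n)
  idx <- which(exceed)
  for (i in idx) {
    bad[max(1, i - half):min(n, i + half)] <- TRUE
  }
  frac <- mean(bad)
  rec$signal <- rec$signal[, !bad, drop = FALSE]
  rec$excised_fraction <- frac
  if (frac > 0.5) rec$flags <- union(rec$flags, "excessive_artifact")
  rec
}

#' Full preprocessing chain
#'
#' Band-pass (0.5-128 Hz), 60 Hz notch, then amplitude-threshold artifact
#' excision, in that order.
#'
#' @param rec an [recording()].
#' @param bandpass numeric length-2, band edges in Hz.
#' @param notch notch frequency in Hz, or `NULL` to skip.
#' @param blink_threshold microvolt threshold for artifact excision, or
#'   `NULL` to skip excision.
#' @param blink_window excision window, milliseconds.
#' @return preprocessed `eeg_recording`.
#' @export
preprocess <- function(rec, bandpass = c(0.5, 128), notch = 60,
                       blink_threshold = 100, blink_window = 400) {
  rec <- suppressWarnings(bandpass_filter(rec, bandpass[1], bandpass[2]))
  if (!is.null(notch)) rec <- notch_filter(rec, notch)
  if (!is.null(blink_threshold)) {
    rec <- remove_blink_artifacts(rec, blink_threshold, blink_window)
  }
  rec
}
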