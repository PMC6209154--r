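#' Construct a multichannel recording
#'
#' A recording couples a channels-by-samples signal matrix (microvolts) with
#' its sampling rate and the study bookkeeping needed downstream: subject,
#' session (1-6), task (1-5), accumulated practice time before the recording
#' (seconds) and the gap since the previous session (days).
#'
#' @param signal numeric matrix, channels x samples, rownames are channel
#'   labels (defaults to [eeg_channels()]).
#' @param sampling_rate sampling frequency in Hz.
#' @param channel_labels channel names; must be the 20-label 10-20 montage.
#' @param subject_id subject identifier.
#' @param session session index (1-6 in the study design, any positive
#'   integer accepted).
#' @param task task identifier (1-5).
#' @param repetitions number of repetitions pooled into this recording.
#' @param practice_time accumulated practice before this recording, seconds.
#' @param practice_gap days since the previous session.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(signal, sampling_rate,
                      channel_labels = eeg_channels(),
                      subject_id = NA, session = NA_integer_,
                      task = NA_integer_, repetitions = 1L,
                      practice_time = NA_real_, practice_gap = NA_real_) {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("`signal` must be numeric")
  if (length(channel_labels) != nrow(signal)) {
    stop("number of rows of `signal` (", nrow(signal),
         ") does not match `channel_labels` (", length(channel_labels), ")")
  }
  missing <- setdiff(eeg_channels(), channel_labels)
  if (length(missing) > 0) {
    stop("recording is missing montage channels: ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number")
  }
  rownames(signal) <- channel_labels
  # keep canonical montage order so adjacency rows always align
  signal <- signal[eeg_channels(), , drop = FALSE]
  structure(
    list(
      signal = signal,
      sampling_rate = sampling_rate,
      channel_labels = eeg_channels(),
      subject_id = subject_id,
      session = as.integer(session),
      task = as.integer(task),
      repetitions = as.integer(repetitions),
      practice_time = practice_time,
      practice_gap = practice_gap,
      excised_fraction = 0,
      flags = character(0)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$signal), ncol(x$signal), x$sampling_rate,
    ncol(x$signal) / x$sampling_rate
  ))
  cat(sprintf("  subject %s, session %s, task %s\n",
              as.character(x$subject_id), as.character(x$session),
              as.character(x$task)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

stopifnot_recording <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stop("expected an `eeg_recording`")
  if (any(!is.finite(rec$signal))) stop("recording contains non-finite samples")
  invisible(rec)
}
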