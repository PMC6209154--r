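#' Standard 20-channel montage and structural system map
#'
#' The analyses in this package assume a fixed 20-channel 10-20 montage.
#' Channels are grouped a priori into structural systems: the motor system
#' (frontal and central leads), the visual system (occipital leads), the
#' cognitive system (prefrontal and parietal leads) and a remainder of
#' temporal leads labelled `other`.
#'
#' @return `eeg_channels()` returns the 20 channel labels in canonical
#'   order. `system_map()` returns a named character vector mapping each
#'   channel label to its structural system.
#' @examples
#' eeg_channels()
#' table(system_map())
#' @export
eeg_channels <- function() {
  c("Fp1", "Fp2", "F3", "Fz", "F4", "F7", "F8", "C3", "Cz", "C4",
    "T3", "T4", "T5", "T6", "P3", "Pz", "P4", "POz", "O1", "O2")
}

#' @rdname eeg_channels
#' @export
system_map <- function() {
  map <- c(
    Fp1 = "cognitive", Fp2 = "cognitive",
    F3 = "motor", Fz = "motor", F4 = "motor", F7 = "motor", F8 = "motor",
    C3 = "motor", Cz = "motor", C4 = "motor",
    T3 = "other", T4 = "other", T5 = "other", T6 = "other",
    P3 = "cognitive", Pz = "cognitive", P4 = "cognitive", POz = "cognitive",
    O1 = "visual", O2 = "visual"
  )
  map[eeg_channels()]
}

#' Channels belonging to a structural system
#'
#' @param system one of `"motor"`, `"visual"`, `"cognitive"`, `"other"`.
#' @return character vector of channel labels.
#' @export
system_channels <- function(system) {
  map <- system_map()
  system <- match.arg(system, unique(map))
  names(map)[map == system]
}

#' Frequency-band definitions
#'
#' Band edges (Hz) used throughout the connectivity analyses:
#' theta 4-8, alpha 8-12, beta 12-35, gamma 35-60. The
#' movement-desynchronization feature ([aiming_period_activity()]) uses a
#' narrower beta of 13-30 Hz in its own context; that band is available as
#' `eeg_bands(context = "spectral")$beta`.
#'
#' @param context `"connectivity"` (default) or `"spectral"`.
#' @return named list of `c(low, high)` numeric pairs.
#' @examples
#' eeg_bands()$alpha
#' @export
eeg_bands <- function(context = c("connectivity", "spectral")) {
  context <- match.arg(context)
  b <- list(
    theta = c(4, 8),
    alpha = c(8, 12),
    beta  = c(12, 35),
    gamma = c(35, 60)
  )
  if (context == "spectral") b$beta <- c(13, 30)
  b
}

band_names <- function() names(eeg_bands())

check_band <- function(band) {
  bands <- eeg_bands()
  if (is.character(band) && length(band) == 1 && band %in% names(bands)) {
    return(band)
  }
  stop("unknown band; must be one of: ",
       paste(names(bands), collapse = ", "))
}
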