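#' Instantaneous band phase by Morlet wavelet convolution
#'
#' Convolves each channel with a complex Morlet wavelet centred at the
#' band's midpoint frequency (width 6 cycles) and takes the argument of the
#' analytic result, wrapped to \[-pi, pi\]. Samples within one wavelet
#' support of either end of the recording are inside the cone of influence;
#' their index count is stored in the `edge` field and downstream
#' synchronization sums exclude them.
#'
#' @param rec a preprocessed [recording()].
#' @param band band name (`"theta"`, `"alpha"`, `"beta"`, `"gamma"`) per
#'   [eeg_bands()].
#' @param n_cycles Morlet width parameter in cycles (default 6).
#' @return an object of class `phase_series`: list with `phase` (channels x
#'   samples matrix, radians in \[-pi, pi\]), `band`, `sampling_rate` and
#'   `edge` (number of cone-of-influence samples on each side).
#' @export
extract_phase <- function(rec, band, n_cycles = 6) {
  stopifnot_recording(rec)
  band <- check_band(band)
  edges <- eeg_bands()[[band]]
  fs <- rec$sampling_rate
  if (edges[2] > fs / 2) {
    stop(sprintf("band %s (up to %g Hz) exceeds Nyquist (%g Hz)",
                 band, edges[2], fs / 2))
  }
  fc <- mean(edges)
  sigma_t <- n_cycles / (2 * pi * fc)
  half <- ceiling(3.5 * sigma_t * fs)
  tt <- (-half:half) / fs
  kern <- exp(1i * 2 * pi * fc * tt) * exp(-tt^2 / (2 * sigma_t^2))
  kern <- kern / sum(Mod(kern))
  n <- ncol(rec$signal)
  phase <- matrix(0, nrow(rec$signal), n,
                  dimnames = list(rec$channel_labels, NULL))
  for (ch in seq_len(nrow(rec$signal))) {
    conv <- conv_same(rec$signal[ch, ], kern)
    phase[ch, ] <- Arg(conv)
  }
  structure(
    list(phase = phase, band = band, sampling_rate = fs, edge = half),
    class = "phase_series"
  )
}

# FFT-based "same" linear convolution of a real series with a complex
# kernel of odd length.
conv_same <- function(x, kern) {
  n <- length(x)
  m <- length(kern)
  nfft <- stats::nextn(n + m - 1, 2)
  full <- stats::fft(stats::fft(c(x, rep(0, nfft - n))) *
                       stats::fft(c(kern, rep(0, nfft - m))),
                     inverse = TRUE) / nfft
  half <- (m - 1) / 2
  full[(half + 1):(half + n)]
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> band %s, %d channels x %d samples, edge %d\n",
              x$band, nrow(x$phase), ncol(x$phase), x$edge))
  invisible(x)
}

#' Absolute phase difference between two phase series
#'
#' The phase difference for a channel pair at each time point is the
#' absolute difference of the wrapped instantaneous phases,
#' `|phi_x - phi_y|`, which lies in \[0, 2 pi). With `normalize = TRUE` it
#' is mapped to \[0, 1\] by dividing by the full range 2 pi.
#'
#' @param phi_x,phi_y numeric vectors of wrapped phases in \[-pi, pi\]
#'   (equal lengths).
#' @param normalize divide by 2 pi (default `FALSE`, radians).
#' @return numeric vector of phase differences.
#' @export
phase_difference <- function(phi_x, phi_y, normalize = FALSE) {
  if (length(phi_x) != length(phi_y)) stop("phase series lengths differ")
  d <- abs(phi_x - phi_y)
  if (normalize) d / (2 * pi) else d
}

#' Pairwise phase-synchronization index
#'
#' For a phase-difference series `dphi_t` over `P_s` samples the index is
#' built from the resultant of the unit vectors at angles `dphi_t`:
#' `S = (sum_t cos dphi_t)^2 + (sum_t sin dphi_t)^2`.
#' Under the `"normalized"` convention (default) the index is `S / P_s^2`,
#' which lies in \[0, 1\], equals 1 under perfect phase locking (constant
#' `dphi`) and has expectation `1 / P_s` for independent uniform phase
#' differences. Under `"literal"` the resultant is divided by `P_s` once,
#' so the index ranges over \[0, P_s\]; it is retained for comparison with
#' sources that print the singly-normalized form.
#'
#' When two phase series are supplied, the resultant is computed over the
#' signed difference `phi_x - phi_y` (cosine is even, so only the sine
#' term is affected). Folding the difference to its absolute value would
#' rectify the sine term and leave a bias of about `1/pi^2` under complete
#' independence; the signed form is the proper phase-locking statistic,
#' vanishing for unrelated channels as `P_s` grows.
#'
#' With `stationary_only = TRUE` the sum is restricted to phase-locked time
#' points, i.e. samples where the central-difference derivative of the
#' phase difference is below `eps` radians/sample in absolute value.
#'
#' @param phi_x,phi_y wrapped phase vectors (radians), or `dphi` may be
#'   supplied directly.
#' @param dphi optional precomputed phase-difference series; overrides
#'   `phi_x`/`phi_y`.
#' @param convention `"normalized"` (range \[0,1\], default) or
#'   `"literal"`.
#' @param stationary_only restrict the sum to stationary phase-difference
#'   samples.
#' @param eps stationarity tolerance, radians per sample (default 0.05).
#' @return scalar synchronization index.
#' @export
sync_index <- function(phi_x = NULL, phi_y = NULL, dphi = NULL,
                       convention = c("normalized", "literal"),
                       stationary_only = FALSE, eps = 0.05) {
  convention <- match.arg(convention)
  if (is.null(dphi)) {
    if (length(phi_x) != length(phi_y)) stop("phase series lengths differ")
    dphi <- phi_x - phi_y               # signed; cos/sin are 2*pi-periodic
  }
  if (stationary_only && length(dphi) >= 3) {
    n <- length(dphi)
    inc <- (diff(dphi) + pi) %% (2 * pi) - pi
    deriv <- (c(inc[1], inc) + c(inc, inc[n - 1])) / 2
    keep <- abs(deriv) < eps
    if (any(keep)) dphi <- dphi[keep]
  }
  ps <- length(dphi)
  if (ps == 0) stop("empty phase-difference series")
  s <- sum(cos(dphi))^2 + sum(sin(dphi))^2
  if (convention == "normalized") s / ps^2 else s / ps
}

#' Per-band synchronization adjacency matrix
#'
#' Extracts band phases for all channels and computes the synchronization
#' index for each of the 190 unordered channel pairs, mirroring into a
#' symmetric 20 x 20 matrix with a zero diagonal. Cone-of-influence edge
#' samples from the wavelet convolution are excluded from the sums.
#'
#' @param rec a preprocessed [recording()].
#' @param band band name per [eeg_bands()].
#' @param convention passed to [sync_index()].
#' @param stationary_only,eps passed to [sync_index()].
#' @param min_samples minimum usable interior samples (default 512).
#' @return object of class `band_adjacency`: list with `gamma` (labelled
#'   20 x 20 matrix), `band`, `convention`, `n_samples`.
#' @export
build_adjacency <- function(rec, band,
                            convention = c("normalized", "literal"),
                            stationary_only = FALSE, eps = 0.05,
                            min_samples = 512) {
  convention <- match.arg(convention)
  ps <- extract_phase(rec, band)
  keep <- seq_len(ncol(ps$phase))
  if (ps$edge > 0 && ncol(ps$phase) > 2 * ps$edge) {
    keep <- (ps$edge + 1):(ncol(ps$phase) - ps$edge)
  }
  if (length(keep) < min_samples) {
    stop(sprintf(
      "only %d interior samples; need at least %d for phase estimation",
      length(keep), min_samples))
  }
  phase <- ps$phase[, keep, drop = FALSE]
  nch <- nrow(phase)
  g <- matrix(0, nch, nch,
              dimnames = list(rec$channel_labels, rec$channel_labels))
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      val <- sync_index(phase[i, ], phase[j, ], convention = convention,
                        stationary_only = stationary_only, eps = eps)
      g[i, j] <- val
      g[j, i] <- val
    }
  }
  structure(
    list(gamma = g, band = band, convention = convention,
         n_samples = length(keep)),
    class = "band_adjacency"
  )
}

#' @export
print.band_adjacency <- function(x, ...) {
  off <- x$gamma[upper.tri(x$gamma)]
  cat(sprintf(
    "<band_adjacency> band %s (%s), %d nodes, P_s = %d, mean off-diag %.3f\n",
    x$band, x$convention, nrow(x$gamma), x$n_samples, mean(off)))
  invisible(x)
}

as_adjacency_matrix <- function(adj) {
  if (inherits(adj, "band_adjacency")) return(adj$gamma)
  m <- as.matrix(adj)
  if (nrow(m) != ncol(m)) stop("adjacency must be square")
  if (max(abs(m - t(m))) > 1e-8) stop("adjacency must be symmetric")
  diag(m) <- 0
  m
}
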