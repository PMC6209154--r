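# Independent oracles and small fixture builders used across the suite.

# Analytic-signal (Hilbert) instantaneous phase, FFT implementation.
# Independent of the package's Morlet path.
hilbert_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

# Circular agreement between two angle series: resultant length of their
# pointwise difference (1 = identical up to a constant offset, ~0 for
# unrelated drifting phases). Robust where moment-based circular
# correlations degenerate (uniformly drifting phases have near-zero
# resultants, making their circular means arbitrary).
circular_agreement <- function(a, b) {
  Mod(mean(exp(1i * (a - b))))
}

# All set partitions of n elements as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_id) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (id in seq_len(next_id)) {
      recurse(c(labels, id), max(next_id, id + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Best modularity over every partition (brute-force oracle).
exhaustive_best_q <- function(w, gamma = 1) {
  parts <- all_partitions(nrow(w))
  qs <- vapply(parts, function(p) modularity_q(w, p, gamma), numeric(1))
  list(q = max(qs), labels = parts[[which.max(qs)]])
}

# Symmetric block adjacency with given block sizes.
block_adjacency <- function(sizes, within = 0.8, between = 0.05,
                            labels = NULL) {
  n <- sum(sizes)
  block <- rep(seq_along(sizes), sizes)
  w <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(block == b)
    w[idx, idx] <- within
  }
  diag(w) <- 0
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  dimnames(w) <- list(labels, labels)
  attr(w, "block") <- block
  w
}

# Recording whose channels are set from a named list of signal vectors;
# unlisted channels get low-amplitude white noise.
make_recording <- function(channel_signals, fs = 256, n = NULL,
                           noise_sd = 0.01, seed = 99, ...) {
  if (is.null(n)) n <- length(channel_signals[[1]])
  set.seed(seed)
  sig <- matrix(stats::rnorm(20 * n, sd = noise_sd), 20, n,
                dimnames = list(eeg_channels(), NULL))
  for (ch in names(channel_signals)) {
    sig[ch, ] <- channel_signals[[ch]]
  }
  recording(sig, fs, ...)
}

# Band-limited noise via Butterworth band-pass of white noise.
narrowband_noise <- function(n, fs, band, seed = 1) {
  set.seed(seed)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
}

# Hand-rolled label partitions for allegiance tests.
label_partition <- function(labels, channels = eeg_channels(),
                            session = NULL, band = NULL, ...) {
  names(labels) <- channels
  p <- eegstates:::partition(labels, q = NA_real_, gamma = NA_real_)
  meta <- list(...)
  if (!is.null(session)) meta$session <- session
  if (!is.null(band)) meta$band <- band
  p$meta <- meta
  p
}
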