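#' Welch band power
#'
#' Power of `x` in a frequency band, estimated by Welch's method:
#' Hamming-windowed segments of `seg_sec` seconds with 50% overlap,
#' periodogram per segment, band power = integral of the periodogram over
#' the band's frequency bins (sum times bin width, so the estimate does
#' not depend on the segment length's frequency resolution). With
#' `per_segment = TRUE` the per-segment band powers are returned instead
#' of their mean (used by the asymmetry index, which needs the
#' within-recording range of alpha power).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate, Hz.
#' @param band numeric length-2 band edges in Hz.
#' @param seg_sec segment length in seconds (default 2).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param per_segment return the vector of per-segment band powers.
#' @return scalar mean band power, or numeric vector if `per_segment`.
#' @export
welch_band_power <- function(x, fs, band, seg_sec = 2, overlap = 0.5,
                             per_segment = FALSE) {
  nseg <- max(8, round(seg_sec * fs))
  nseg <- min(nseg, length(x))
  step <- max(1, round(nseg * (1 - overlap)))
  starts <- seq(1, length(x) - nseg + 1, by = step)
  win <- 0.54 - 0.46 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  freqs <- (0:(nseg - 1)) * fs / nseg
  sel <- freqs >= band[1] & freqs <= band[2] & freqs <= fs / 2
  if (!any(sel)) stop("no frequency bins inside the band")
  df <- fs / nseg
  pows <- vapply(starts, function(s) {
    seg <- x[s:(s + nseg - 1)] * win
    p <- Mod(stats::fft(seg))^2 / (sum(win^2) * fs)
    sum(p[sel]) * df
  }, numeric(1))
  if (per_segment) pows else mean(pows)
}

#' Completion time of a recording
#'
#' Total task duration: number of samples divided by the sampling rate.
#'
#' @param rec an [recording()].
#' @return completion time in seconds.
#' @export
completion_time <- function(rec) {
  if (rec$sampling_rate <= 0) stop("sampling rate must be positive")
  ncol(rec$signal) / rec$sampling_rate
}

#' Within-system connectivity strength
#'
#' Mean synchronization over the unordered within-system channel pairs
#' (self-pairs excluded: the adjacency diagonal is structurally zero and
#' would deflate the average).
#'
#' @param adj a [build_adjacency()] result or symmetric matrix.
#' @param system system name, needs >= 2 channels.
#' @param map channel-to-system map (default [system_map()]).
#' @return scalar mean connectivity.
#' @export
strength <- function(adj, system, map = system_map()) {
  w <- as_adjacency_matrix(adj)
  chans <- intersect(rownames(w), names(map)[map == system])
  if (length(chans) < 2) stop("system '", system, "' has fewer than two channels")
  sub <- w[chans, chans]
  mean(sub[upper.tri(sub)])
}

#' Between-system communication
#'
#' Mean synchronization over channel pairs spanning two different systems:
#' `C = sum_{i in s1, j in s2} Gamma_ij / (|s1| |s2|)`.
#'
#' @inheritParams strength
#' @param s1,s2 distinct system names.
#' @return scalar mean cross-system connectivity.
#' @export
communication <- function(adj, s1, s2, map = system_map()) {
  if (identical(s1, s2)) stop("use strength() for a system with itself")
  w <- as_adjacency_matrix(adj)
  c1 <- intersect(rownames(w), names(map)[map == s1])
  c2 <- intersect(rownames(w), names(map)[map == s2])
  if (length(c1) == 0 || length(c2) == 0) stop("empty system")
  sum(w[c1, c2]) / (length(c1) * length(c2))
}

#' Whole-scalp mean connectivity
#'
#' Mean of the 190 unique off-diagonal synchronization values; the scalar
#' connectivity summary used in feature tables.
#'
#' @param adj a [build_adjacency()] result or symmetric matrix.
#' @return scalar.
#' @export
global_strength <- function(adj) {
  w <- as_adjacency_matrix(adj)
  mean(w[upper.tri(w)])
}

#' Mean cross-system communication
#'
#' Average of [communication()] over all unordered pairs of the systems in
#' `map`; the scalar communication summary used in feature tables.
#'
#' @inheritParams strength
#' @return scalar.
#' @export
global_communication <- function(adj, map = system_map()) {
  systems <- unique(map)
  pairs <- utils::combn(systems, 2, simplify = FALSE)
  mean(vapply(pairs, function(p) communication(adj, p[1], p[2], map),
              numeric(1)))
}

#' Frontal alpha asymmetry index
#'
#' Difference between the within-recording range of alpha-band power on
#' the left (F3, F7) and right (F4, F8) frontal leads, normalized:
#' `AI = (L - R) / (L + R)` with
#' `L = [Pmax - Pmin](F3) + [Pmax - Pmin](F7)` and `R` likewise for F4 and
#' F8. Per-segment alpha powers come from [welch_band_power()] over
#' sliding windows; `Pmax`/`Pmin` are taken across segments. `AI` lies in
#' \[-1, 1\]; a right-lateralized alpha-power modulation gives negative
#' values. If both ranges are zero the index is defined as 0 and the
#' result carries attribute `flag = "zero_range"`.
#'
#' @param rec an [recording()].
#' @param seg_sec,overlap Welch windowing, see [welch_band_power()].
#' @return scalar asymmetry index in \[-1, 1\].
#' @export
asymmetry_index <- function(rec, seg_sec = 2, overlap = 0.5) {
  stopifnot_recording(rec)
  alpha <- eeg_bands()$alpha
  rng <- function(ch) {
    p <- welch_band_power(rec$signal[ch, ], rec$sampling_rate, alpha,
                          seg_sec, overlap, per_segment = TRUE)
    max(p) - min(p)
  }
  L <- rng("F3") + rng("F7")
  R <- rng("F4") + rng("F8")
  if (L + R == 0) {
    return(structure(0, flag = "zero_range"))
  }
  (L - R) / (L + R)
}

#' Aiming-period activity (movement-related desynchronization)
#'
#' Relative power reduction in the alpha (8-12 Hz) and beta (13-30 Hz)
#' bands over the central channels (C3, Cz, C4) between a baseline
#' (aiming) window and a movement window:
#' `APA = mean over bands and channels of (P_base - P_move) / P_base`.
#' Positive values indicate desynchronization during movement. By default
#' the first 10% of the recording is the baseline and the remainder the
#' movement window.
#'
#' @param rec an [recording()].
#' @param baseline_window,movement_window numeric length-2 sample index
#'   ranges; defaults split the recording 10% / 90%.
#' @param channels central channel subset (default C3, Cz, C4).
#' @return scalar APA.
#' @export
aiming_period_activity <- function(rec, baseline_window = NULL,
                                   movement_window = NULL,
                                   channels = c("C3", "Cz", "C4")) {
  stopifnot_recording(rec)
  n <- ncol(rec$signal)
  if (is.null(baseline_window)) baseline_window <- c(1, max(2, floor(0.1 * n)))
  if (is.null(movement_window)) {
    movement_window <- c(baseline_window[2] + 1, n)
  }
  overlap <- movement_window[1] <= baseline_window[2] &&
    baseline_window[1] <= movement_window[2]
  if (overlap) stop("baseline and movement windows must be disjoint")
  bands <- list(alpha = eeg_bands()$alpha,
                beta = eeg_bands(context = "spectral")$beta)
  fs <- rec$sampling_rate
  vals <- c()
  for (b in bands) {
    for (ch in channels) {
      xb <- rec$signal[ch, baseline_window[1]:baseline_window[2]]
      xm <- rec$signal[ch, movement_window[1]:movement_window[2]]
      pb <- welch_band_power(xb, fs, b,
                             seg_sec = min(2, length(xb) / fs))
      pm <- welch_band_power(xm, fs, b,
                             seg_sec = min(2, length(xm) / fs))
      if (pb == 0) stop("zero baseline power in band")
      vals <- c(vals, (pb - pm) / pb)
    }
  }
  mean(vals)
}

#' NASA-TLX task difficulty
#'
#' Sum of the mental-demand, physical-demand, temporal-demand and effort
#' indices, each on the questionnaire's 1-20 scale (performance and
#' frustration are excluded: trainees lack the expertise to judge their
#' own outcome). Range 4-80.
#'
#' @param md,pd,td,effort the four indices, each in \[1, 20\]. `md` may
#'   instead be a data frame / list with columns `MD`, `PD`, `TD`, `E`.
#' @return difficulty score(s).
#' @export
difficulty <- function(md, pd = NULL, td = NULL, effort = NULL) {
  if (is.list(md)) {
    pd <- md$PD; td <- md$TD; effort <- md$E; md <- md$MD
  }
  vals <- cbind(md, pd, td, effort)
  if (any(vals < 1 | vals > 20)) {
    stop("NASA-TLX indices must lie in [1, 20]")
  }
  as.numeric(md + pd + td + effort)
}

#' Performance level from tool-based scores
#'
#' `Performance = 100 - mean(8 FSRS metric scores)`. FSRS scores are
#' penalty-like (higher = worse), so performance decreases by 1/8 per unit
#' of any score. If any score is missing the result is `NA` (the recording
#' is treated as FSRS-missing).
#'
#' @param scores numeric vector (or one-row data frame) of the 8 FSRS
#'   metric scores, nonnegative.
#' @return performance level on a 0-100-like scale, or `NA` if incomplete.
#' @export
performance_level <- function(scores) {
  scores <- as.numeric(unlist(scores))
  if (length(scores) != 8) stop("expected 8 FSRS scores")
  if (anyNA(scores)) return(NA_real_)
  if (any(scores < 0)) stop("FSRS scores must be nonnegative")
  100 - mean(scores)
}

#' Task complexity lookup
#'
#' Expert-assigned complexity of the five simulator tasks (1 = simplest,
#' 5 = most complex): instrument control 2, ball placement 4, spatial
#' control II 5, fourth-arm tissue retraction 3, hands-on surgical
#' training 1.
#'
#' @param task_id integer task id(s) in 1..5.
#' @return integer complexity level(s).
#' @export
task_complexity <- function(task_id) {
  lookup <- c(`1` = 2L, `2` = 4L, `3` = 5L, `4` = 3L, `5` = 1L)
  if (any(!task_id %in% 1:5)) stop("task_id must be in 1..5")
  unname(lookup[as.character(task_id)])
}

fsrs_metric_names <- function() {
  c("clutch_usage", "left_tool_grasp", "left_tool_out_of_view",
    "n_errors", "right_tool_grasp", "right_tool_out_of_view",
    "tissue_damage", "tool_collision")
}

tlx_index_names <- function() c("MD", "PD", "TD", "PS", "E", "Frustration")

#' Per-recording feature row
#'
#' Computes the full network + spectral feature set of one preprocessed
#' recording: completion time, per-band whole-scalp strength and mean
#' cross-system communication, asymmetry index and aiming-period
#' activity.
#'
#' @param rec a preprocessed [recording()].
#' @param bands band names to cover (default all four).
#' @param convention synchronization convention, see [sync_index()].
#' @return one-row data frame.
#' @export
extract_features <- function(rec, bands = band_names(),
                             convention = "normalized") {
  row <- data.frame(
    subject_id = rec$subject_id, session = rec$session, task = rec$task,
    CT = completion_time(rec),
    AI = as.numeric(asymmetry_index(rec)),
    APA = aiming_period_activity(rec),
    practice_time = rec$practice_time, practice_gap = rec$practice_gap,
    stringsAsFactors = FALSE
  )
  for (b in bands) {
    adj <- build_adjacency(rec, b, convention = convention)
    row[[paste0("strength_", b)]] <- global_strength(adj)
    row[[paste0("communication_", b)]] <- global_communication(adj)
  }
  row
}
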