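#' Planted study design for synthetic data generation
#'
#' Describes a synthetic study emulating the skill-acquisition design:
#' subjects practicing simulator tasks over repeated sessions, each
#' recording a 20-channel oscillatory signal with planted phase-coupled
#' community structure. Channels in the same planted module share, per
#' band, a common stochastic phase; the within-module coupling `kappa_in`
#' and between-module coupling `kappa_out` control how strongly each
#' channel's phase follows the module-shared and globally-shared phase
#' processes.
#'
#' @param n_subjects number of subjects (default 27).
#' @param n_sessions number of sessions (default 6).
#' @param tasks data frame with columns `id` and `complexity` (default:
#'   the five simulator tasks with their [task_complexity()] levels).
#' @param sampling_rate Hz (default 256; must be at least twice the
#'   highest band edge, 120 Hz).
#' @param duration seconds per recording (default 60).
#' @param band_coupling named list, band -> `c(kappa_in, kappa_out)` with
#'   `0 <= kappa_out <= kappa_in <= 1`. Bands not listed are generated as
#'   uncoupled oscillations.
#' @param planted_modules named integer vector, channel -> module label,
#'   covering all 20 channels. Default: motor channels = module 1,
#'   cognitive = 2, visual and temporal = 3.
#' @param session_trend named list, band -> additive per-session drift of
#'   `c(kappa_in, kappa_out)` (a single number is taken as a drift of
#'   `kappa_out` only). Couplings are clipped to keep
#'   `0 <= kappa_out <= kappa_in <= 1`.
#' @param noise_sd additive white-noise standard deviation in signal units
#'   (default 0.5; each band contributes a unit-amplitude cosine).
#' @param session_days day of each session relative to the first (default
#'   `c(0, 7, 30, 90, 180, 365)`: initial, one week, one month, three
#'   months, six months, one year).
#' @param seed master seed; all generated randomness derives from it.
#' @return object of class `planted_design`.
#' @export
planted_design <- function(n_subjects = 27, n_sessions = 6,
                           tasks = data.frame(id = 1:5,
                                              complexity = task_complexity(1:5)),
                           sampling_rate = 256, duration = 60,
                           band_coupling = list(
                             alpha = c(kappa_in = 0.8, kappa_out = 0.3)),
                           planted_modules = default_planted_modules(),
                           session_trend = list(),
                           noise_sd = 0.5,
                           session_days = c(0, 7, 30, 90, 180, 365),
                           seed = 1L) {
  if (sampling_rate < 2 * max(unlist(eeg_bands()))) {
    stop("sampling_rate must be at least twice the highest band edge (120 Hz)")
  }
  if (duration * sampling_rate < 512) {
    stop("recording too short: need at least 512 samples for phase estimation")
  }
  if (!setequal(names(planted_modules), eeg_channels())) {
    stop("planted_modules must cover all 20 montage channels")
  }
  planted_modules <- planted_modules[eeg_channels()]
  for (b in names(band_coupling)) {
    check_band(b)
    k <- band_coupling[[b]]
    if (length(k) != 2 || any(k < 0) || any(k > 1) || k[2] > k[1]) {
      stop("band_coupling[[", b, "]] must be c(kappa_in, kappa_out) with ",
           "0 <= kappa_out <= kappa_in <= 1")
    }
  }
  if (length(session_days) < n_sessions) {
    stop("session_days must cover all sessions")
  }
  structure(
    list(n_subjects = n_subjects, n_sessions = n_sessions, tasks = tasks,
         sampling_rate = sampling_rate, duration = duration,
         band_coupling = band_coupling,
         planted_modules = planted_modules,
         session_trend = session_trend, noise_sd = noise_sd,
         session_days = session_days[seq_len(n_sessions)],
         seed = as.integer(seed)),
    class = "planted_design"
  )
}

#' @rdname planted_design
#' @export
default_planted_modules <- function() {
  map <- system_map()
  mod <- ifelse(map == "motor", 1L, ifelse(map == "cognitive", 2L, 3L))
  names(mod) <- names(map)
  mod
}

#' @export
print.planted_design <- function(x, ...) {
  cat(sprintf(
    "<planted_design> %d subjects x %d sessions x %d tasks, %g s @ %g Hz\n",
    x$n_subjects, x$n_sessions, nrow(x$tasks), x$duration, x$sampling_rate))
  for (b in names(x$band_coupling)) {
    k <- session_coupling(x, b, 1)
    cat(sprintf("  %s: kappa_in %.2f, kappa_out %.2f%s\n", b, k[1], k[2],
                if (!is.null(x$session_trend[[b]])) " (+ session trend)" else ""))
  }
  invisible(x)
}

# Coupling of band `b` at session `s`, with the per-session trend applied
# and clipped so 0 <= kappa_out <= kappa_in <= 1.
session_coupling <- function(design, band, session) {
  k <- design$band_coupling[[band]]
  tr <- design$session_trend[[band]]
  if (!is.null(tr)) {
    if (length(tr) == 1) tr <- c(0, tr)
    k <- k + tr * (session - 1)
  }
  k <- pmin(pmax(k, 0), 1)
  if (k[2] > k[1]) k[2] <- k[1]
  unname(k)
}

# Ornstein-Uhlenbeck phase perturbation as a stationary AR(1) series:
# mean-reversion timescale `tau` seconds, stationary sd `sigma` radians.
ou_series <- function(n, fs, tau = 1, sigma = pi) {
  rho <- exp(-1 / (fs * tau))
  innov <- stats::rnorm(n, sd = sigma * sqrt(1 - rho^2))
  init <- stats::rnorm(1, sd = sigma)
  as.numeric(stats::filter(innov, rho, method = "recursive", init = init))
}

#' Generate phase-coupled recordings for one session
#'
#' One recording per subject x task. Per coupled band, every channel's
#' instantaneous phase is a convex blend of a globally shared, a
#' module-shared and a private Ornstein-Uhlenbeck-perturbed phase process
#' around the band's centre frequency, with blend weights
#' `kappa_out` (global), `kappa_in - kappa_out` (module) and
#' `1 - kappa_in` (private). The signal is the sum over bands of
#' unit-amplitude cosines of these phases plus white noise, so expected
#' within-module synchronization exceeds between-module synchronization by
#' a margin that grows with `kappa_in - kappa_out`.
#'
#' @param design a [planted_design()].
#' @param session session index.
#' @param subjects optional subject subset (default all).
#' @return list of [recording()] objects.
#' @export
generate_coupled_signals <- function(design, session,
                                     subjects = seq_len(design$n_subjects)) {
  if (!inherits(design, "planted_design")) stop("expected a `planted_design`")
  if (session < 1 || session > design$n_sessions) stop("session out of range")
  fs <- design$sampling_rate
  n <- round(design$duration * fs)
  if (n < 512) stop("recording too short: need at least 512 samples")
  tvec <- (seq_len(n) - 1) / fs
  mods <- design$planted_modules
  recs <- list()
  for (subj in subjects) {
    for (ti in seq_len(nrow(design$tasks))) {
      task <- design$tasks$id[ti]
      rec_seed <- derive_seed(design$seed,
                              ((subj * 31L + session) * 31L + ti))
      sig <- with_seed(rec_seed, {
        out <- matrix(0, length(mods), n,
                      dimnames = list(names(mods), NULL))
        for (b in names(design$band_coupling)) {
          k <- session_coupling(design, b, session)
          w_global <- k[2]
          w_module <- k[1] - k[2]
          w_priv <- 1 - k[1]
          fc <- mean(eeg_bands()[[b]])
          base <- 2 * pi * fc * tvec
          u_global <- ou_series(n, fs)
          u_module <- lapply(sort(unique(mods)),
                             function(m) ou_series(n, fs))
          names(u_module) <- as.character(sort(unique(mods)))
          for (ch in seq_along(mods)) {
            phase <- base + w_global * u_global +
              w_module * u_module[[as.character(mods[ch])]] +
              w_priv * ou_series(n, fs)
            out[ch, ] <- out[ch, ] + cos(phase)
          }
        }
        if (design$noise_sd > 0) {
          out <- out + matrix(stats::rnorm(length(out),
                                           sd = design$noise_sd),
                              nrow(out), ncol(out))
        }
        out
      })
      recs[[length(recs) + 1L]] <- recording(
        sig, fs, subject_id = subj, session = session, task = task,
        practice_time = NA_real_, practice_gap = NA_real_)
    }
  }
  recs
}

parse_effect_sizes <- function(effect_sizes) {
  if (is.null(effect_sizes) || length(effect_sizes) == 0) {
    return(data.frame(a = character(0), b = character(0), r = numeric(0)))
  }
  nm <- names(effect_sizes)
  if (is.null(nm) || any(nm == "")) {
    stop("effect_sizes must be a named vector/list, names like 'CT~clutch_usage'")
  }
  parts <- strsplit(nm, "~", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) stop("malformed effect-size name(s): ",
                     paste(nm[bad], collapse = ", "))
  r <- unlist(effect_sizes)
  if (any(abs(r) >= 1)) stop("target correlations must lie in (-1, 1)")
  data.frame(a = vapply(parts, `[`, character(1), 1),
             b = vapply(parts, `[`, character(1), 2),
             r = as.numeric(r), stringsAsFactors = FALSE)
}

# Latent-variable names of the copula: D targets are expanded over the
# four difficulty components at half the requested correlation (the sum
# of four equal-variance components then carries the full correlation).
expand_effects <- function(eff) {
  out <- eff[0, ]
  for (i in seq_len(nrow(eff))) {
    row <- eff[i, ]
    if (row$a == "D" || row$b == "D") {
      other <- if (row$a == "D") row$b else row$a
      for (comp in c("MD", "PD", "TD", "E")) {
        out <- rbind(out, data.frame(a = comp, b = other, r = row$r / 2))
      }
    } else {
      out <- rbind(out, row)
    }
  }
  out
}

synthetic_columns <- function() {
  c(fsrs_metric_names(), tlx_index_names(), "CT", "APA", "AI",
    paste0("strength_", band_names()),
    paste0("communication_", band_names()))
}

#' Generate behavioral and network feature tables with planted effects
#'
#' Draws per-recording feature rows (FSRS tool-based metrics, NASA-TLX
#' indices, completion time, spectral and network features) from a
#' Gaussian copula whose latent correlation matrix carries the requested
#' pairwise effect sizes, then maps each latent variable through an affine
#' transform onto a realistic scale (FSRS scores nonnegative, NASA-TLX in
#' 1-20). Targets on the derived difficulty `D` are spread over its four
#' NASA-TLX components. Emulating the study's missing-score mechanism,
#' task 5 never has FSRS scores and other tasks lose them independently at
#' `fsrs_missing_rate`.
#'
#' @param design a [planted_design()].
#' @param effect_sizes named vector, names of the form `"colA~colB"` over
#'   the generated columns (plus `"D"`), values = target Pearson
#'   correlations in (-1, 1). The implied latent correlation matrix must
#'   be positive semidefinite.
#' @param fsrs_missing_rate probability that a non-task-5 recording lacks
#'   FSRS scores (default 0.6, giving roughly 260 complete rows under the
#'   default 27 x 6 x 5 design).
#' @return a `synthetic_bundle` list: `features` (full per-recording
#'   table including derived `D`, `performance`, `complexity`,
#'   `practice_time`, `practice_gap` and an `fsrs_missing` flag),
#'   `fsrs_table`, `tlx_table`, and `truth` (design echo plus the
#'   requested effects).
#' @export
generate_feature_tables <- function(design, effect_sizes = NULL,
                                    fsrs_missing_rate = 0.6) {
  if (!inherits(design, "planted_design")) stop("expected a `planted_design`")
  eff <- expand_effects(parse_effect_sizes(effect_sizes))
  cols <- synthetic_columns()
  unknown <- setdiff(unique(c(eff$a, eff$b)), cols)
  if (length(unknown)) stop("unknown effect-size column(s): ",
                            paste(unknown, collapse = ", "))
  p <- length(cols)
  R <- diag(p)
  dimnames(R) <- list(cols, cols)
  for (i in seq_len(nrow(eff))) {
    R[eff$a[i], eff$b[i]] <- R[eff$a[i], eff$b[i]] + eff$r[i]
    R[eff$b[i], eff$a[i]] <- R[eff$a[i], eff$b[i]]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf(
      "requested correlation matrix is not positive semidefinite (min eigenvalue %.3g)",
      min(ev)))
  }
  grid <- expand.grid(task = design$tasks$id,
                      session = seq_len(design$n_sessions),
                      subject_id = seq_len(design$n_subjects))
  grid <- grid[, c("subject_id", "session", "task")]
  nrec <- nrow(grid)
  z <- with_seed(derive_seed(design$seed, 104729L), {
    MASS::mvrnorm(nrec, mu = rep(0, p), Sigma = R)
  })
  colnames(z) <- cols
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  feat <- as.data.frame(grid)
  for (m in fsrs_metric_names()) feat[[m]] <- pmax(0, 8 + 3 * z[, m])
  for (m in tlx_index_names()) feat[[m]] <- clip(10.5 + 3 * z[, m], 1, 20)
  feat$CT <- pmax(10, 90 + 25 * z[, "CT"])
  feat$APA <- 0.2 + 0.15 * z[, "APA"]
  feat$AI <- clip(0.2 * z[, "AI"], -1, 1)
  for (b in band_names()) {
    feat[[paste0("strength_", b)]] <-
      clip(0.3 + 0.1 * z[, paste0("strength_", b)], 0.01, 1)
    feat[[paste0("communication_", b)]] <-
      clip(0.25 + 0.08 * z[, paste0("communication_", b)], 0.01, 1)
  }
  feat$D <- difficulty(feat$MD, feat$PD, feat$TD, feat$E)
  feat$complexity <- task_complexity(feat$task)
  # bookkeeping: session calendar and accumulated practice
  days <- design$session_days
  feat$practice_gap <- c(0, diff(days))[feat$session]
  feat <- feat[order(feat$subject_id, feat$session, feat$task), ]
  feat$practice_time <- stats::ave(feat$CT, feat$subject_id,
                                   FUN = function(ct) cumsum(ct) - ct)
  # missing-FSRS mechanism: task 5 always missing, others at a fixed rate
  miss <- with_seed(derive_seed(design$seed, 224737L), {
    stats::runif(nrec) < fsrs_missing_rate
  })
  feat$fsrs_missing <- feat$task == 5 | miss
  feat[feat$fsrs_missing, fsrs_metric_names()] <- NA_real_
  feat$performance <- ifelse(
    feat$fsrs_missing, NA_real_,
    100 - rowMeans(feat[fsrs_metric_names()]))
  rownames(feat) <- NULL
  keys <- c("subject_id", "session", "task")
  structure(
    list(features = feat,
         fsrs_table = feat[c(keys, fsrs_metric_names(), "fsrs_missing")],
         tlx_table = feat[c(keys, tlx_index_names())],
         truth = list(design = design, effect_sizes = effect_sizes)),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat(sprintf(
    "<synthetic_bundle> %d recordings (%d with FSRS)%s\n",
    nrow(x$features), sum(!x$features$fsrs_missing),
    if (!is.null(x$recordings)) sprintf(", %d signal recordings",
                                        length(x$recordings)) else ""))
  invisible(x)
}

#' Generate a complete synthetic study
#'
#' Feature tables via [generate_feature_tables()] plus, optionally, the
#' phase-coupled signal recordings for every session via
#' [generate_coupled_signals()], with the accumulated-practice and
#' session-gap covariates from the feature table attached to each
#' recording.
#'
#' @inheritParams generate_feature_tables
#' @param signals also generate signal recordings (default `TRUE`).
#' @param subjects optional subject subset for signal generation.
#' @return `synthetic_bundle` with a `recordings` element when
#'   `signals = TRUE`.
#' @export
generate_study <- function(design, effect_sizes = NULL,
                           fsrs_missing_rate = 0.6, signals = TRUE,
                           subjects = seq_len(design$n_subjects)) {
  bundle <- generate_feature_tables(design, effect_sizes, fsrs_missing_rate)
  if (signals) {
    recs <- list()
    for (s in seq_len(design$n_sessions)) {
      recs <- c(recs, generate_coupled_signals(design, s, subjects))
    }
    feat <- bundle$features
    for (i in seq_along(recs)) {
      r <- recs[[i]]
      hit <- which(feat$subject_id == r$subject_id &
                     feat$session == r$session & feat$task == r$task)
      if (length(hit) == 1) {
        recs[[i]]$practice_time <- feat$practice_time[hit]
        recs[[i]]$practice_gap <- feat$practice_gap[hit]
      }
    }
    bundle$recordings <- recs
  }
  bundle
}
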