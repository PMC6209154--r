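test_that("completion time is samples over sampling rate, exactly", {
  expect_equal(completion_time(make_recording(list(), n = 256, fs = 256)), 1)
  expect_equal(completion_time(make_recording(list(), n = 15360, fs = 256)), 60)
  expect_equal(completion_time(make_recording(list(), n = 1000, fs = 128)),
               7.8125)
})

test_that("strength and communication equal hand-computed pair means", {
  chans <- eeg_channels()
  set.seed(12)
  w <- matrix(runif(400), 20, 20)
  w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(chans, chans)

  c0 <- 0.42
  unif <- matrix(c0, 20, 20); diag(unif) <- 0
  dimnames(unif) <- list(chans, chans)
  expect_equal(strength(unif, "motor"), c0)
  expect_equal(communication(unif, "motor", "visual"), c0)

  expect_equal(strength(w, "visual"), w["O1", "O2"])
  motor <- system_channels("motor")
  visual <- system_channels("visual")
  expect_equal(communication(w, "motor", "visual"),
               sum(w[motor, visual]) / 16)
  expect_equal(communication(w, "motor", "visual"),
               communication(w, "visual", "motor"))

  zero_cross <- w
  zero_cross[motor, visual] <- 0
  zero_cross[visual, motor] <- 0
  expect_equal(communication(zero_cross, "motor", "visual"), 0)
})

test_that("within-system strength is the self-pair-excluded communication", {
  # letting both systems coincide in the printed mean reduces to the
  # within-system pair average once self-pairs are excluded consistently
  set.seed(13)
  w <- matrix(runif(400), 20, 20)
  w <- (w + t(w)) / 2; diag(w) <- 0
  dimnames(w) <- list(eeg_channels(), eeg_channels())
  motor <- system_channels("motor")
  m <- length(motor)
  self_excluded <- sum(w[motor, motor]) / (m * (m - 1))
  expect_equal(strength(w, "motor"), self_excluded)
})

test_that("asymmetry index is zero for mirror-symmetric frontal signals", {
  fs <- 256
  n <- fs * 8
  x <- narrowband_noise(n, fs, c(8, 12), seed = 31)
  y <- narrowband_noise(n, fs, c(8, 12), seed = 32)
  rec <- make_recording(list(F3 = x, F4 = x, F7 = y, F8 = y), noise_sd = 0.01)
  expect_equal(asymmetry_index(rec), 0, tolerance = 1e-10)
})

test_that("right-lateralized alpha modulation drives AI towards -1", {
  fs <- 256
  n <- fs * 8
  tt <- (0:(n - 1)) / fs
  # right channels: alpha bursts (large power range); left: steady alpha
  envelope <- 1 + 0.95 * sign(sin(2 * pi * 0.25 * tt))
  right <- envelope * cos(2 * pi * 10 * tt)
  left <- cos(2 * pi * 10 * tt)
  rec <- make_recording(list(F3 = left, F7 = left, F4 = right, F8 = right),
                        noise_sd = 0.001)
  expect_lt(asymmetry_index(rec), -0.8)
})

test_that("zero-range recordings get AI = 0 with a flag", {
  rec <- make_recording(list(), n = 2048, noise_sd = 0)
  ai <- asymmetry_index(rec)
  expect_equal(as.numeric(ai), 0)
  expect_equal(attr(ai, "flag"), "zero_range")
})

test_that("aiming-period activity tracks alpha/beta power drops only", {
  fs <- 256
  n <- fs * 10
  tt <- (0:(n - 1)) / fs
  base_end <- floor(0.1 * n)

  # stationary signal: no power change between windows
  steady <- cos(2 * pi * 10 * tt) + cos(2 * pi * 20 * tt)
  rec <- make_recording(list(C3 = steady, Cz = steady, C4 = steady),
                        noise_sd = 0.001)
  expect_equal(aiming_period_activity(rec), 0, tolerance = 0.05)

  # alpha amplitude halves in power during movement; beta unchanged
  amp <- ifelse(seq_len(n) <= base_end, 1, 1 / sqrt(2))
  moving <- amp * cos(2 * pi * 10 * tt) + cos(2 * pi * 20 * tt)
  rec <- make_recording(list(C3 = moving, Cz = moving, C4 = moving),
                        noise_sd = 0.001)
  expect_equal(aiming_period_activity(rec), 0.25, tolerance = 0.05)

  # gamma-band change is invisible to APA
  amp_g <- ifelse(seq_len(n) <= base_end, 1, 0.2)
  gchange <- cos(2 * pi * 10 * tt) + cos(2 * pi * 20 * tt) +
    amp_g * cos(2 * pi * 45 * tt)
  rec <- make_recording(list(C3 = gchange, Cz = gchange, C4 = gchange),
                        noise_sd = 0.001)
  expect_equal(aiming_period_activity(rec), 0, tolerance = 0.05)
})

test_that("difficulty is the exact four-index sum with range validation", {
  expect_equal(difficulty(5, 5, 5, 5), 20)
  expect_equal(difficulty(1, 1, 1, 1), 4)
  expect_equal(difficulty(12, 7, 15, 18), 52)
  expect_equal(difficulty(data.frame(MD = 2, PD = 3, TD = 4, E = 5)), 14)
  expect_error(difficulty(0, 5, 5, 5), "1, 20")
  expect_error(difficulty(5, 21, 5, 5), "1, 20")
})

test_that("performance level is 100 minus the mean of the 8 scores", {
  expect_equal(performance_level(rep(0, 8)), 100)
  expect_equal(performance_level(rep(8, 8)), 92)
  expect_equal(performance_level(1:8), 95.5)
  expect_true(is.na(performance_level(c(1:7, NA))))
  expect_error(performance_level(1:7), "8 FSRS")
  # affine with slope -1/8 in each score
  base <- performance_level(rep(4, 8))
  bumped <- performance_level(c(rep(4, 7), 5))
  expect_equal(bumped - base, -1 / 8)
})

test_that("per-recording feature rows carry all network and spectral columns", {
  d <- planted_design(
    n_subjects = 1, n_sessions = 1, tasks = data.frame(id = 3, complexity = 5),
    duration = 8, band_coupling = list(alpha = c(0.8, 0.2)),
    noise_sd = 0.5, seed = 61)
  rec <- generate_coupled_signals(d, 1)[[1]]
  row <- extract_features(rec, bands = c("theta", "alpha"))
  expect_equal(nrow(row), 1)
  expect_equal(row$CT, 8)
  expect_equal(row$task, 3L)
  expect_true(all(c("AI", "APA", "strength_theta", "strength_alpha",
                    "communication_theta", "communication_alpha") %in%
                    names(row)))
  expect_true(row$strength_alpha >= 0 && row$strength_alpha <= 1)
  expect_true(abs(row$AI) <= 1)
})

test_that("task complexity is the fixed curriculum lookup", {
  expect_equal(task_complexity(1), 2L)
  expect_equal(task_complexity(3), 5L)
  expect_equal(task_complexity(5), 1L)
  expect_equal(task_complexity(c(2, 4)), c(4L, 3L))
  expect_error(task_complexity(6), "1..5")
})
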