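tiny_design <- function(..., seed = 101) {
  planted_design(
    n_subjects = 1, n_sessions = 1,
    tasks = data.frame(id = 1, complexity = 2),
    duration = 30, seed = seed, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  d <- tiny_design(band_coupling = list(alpha = c(0.8, 0.2)))
  r1 <- generate_coupled_signals(d, 1)[[1]]
  r2 <- generate_coupled_signals(d, 1)[[1]]
  expect_identical(r1$signal, r2$signal)

  b1 <- generate_feature_tables(planted_design(seed = 7))
  b2 <- generate_feature_tables(planted_design(seed = 7))
  expect_identical(b1$features, b2$features)
  b3 <- generate_feature_tables(planted_design(seed = 8))
  expect_false(identical(b1$features, b3$features))
})

test_that("perfect coupling yields constant within-module phase differences", {
  d <- tiny_design(band_coupling = list(alpha = c(kappa_in = 1, kappa_out = 0)),
                   noise_sd = 0)
  rec <- generate_coupled_signals(d, 1)[[1]]
  ps <- extract_phase(rec, "alpha")
  interior <- (ps$edge + 1):(ncol(ps$phase) - ps$edge)
  mods <- d$planted_modules
  same_mod <- which(mods == mods[1])
  d12 <- phase_difference(ps$phase[same_mod[1], interior],
                          ps$phase[same_mod[2], interior])
  expect_lt(max(d12) - min(d12), 1e-6)
})

test_that("equal couplings equalize within- and between-module synchronization", {
  d <- tiny_design(
    band_coupling = list(alpha = c(kappa_in = 0.5, kappa_out = 0.5)),
    noise_sd = 0.3, seed = 103)
  rec <- generate_coupled_signals(d, 1)[[1]]
  adj <- build_adjacency(rec, "alpha")
  mods <- d$planted_modules
  same <- outer(mods, mods, "==") & upper.tri(adj$gamma)
  diff <- (!outer(mods, mods, "==")) & upper.tri(adj$gamma)
  expect_equal(mean(adj$gamma[same]), mean(adj$gamma[diff]),
               tolerance = 0.15)
})

test_that("planted-module recovery improves with the coupling gap", {
  ari_at <- function(kin) {
    d <- tiny_design(
      band_coupling = list(alpha = c(kappa_in = kin, kappa_out = 0.1)),
      noise_sd = 0.5, seed = 104)
    rec <- generate_coupled_signals(d, 1)[[1]]
    adj <- build_adjacency(rec, "alpha")
    p <- select_resolution(adj, gamma_grid = seq(0.6, 1.6, 0.2),
                           restarts = 5, seed = 9)
    mclust::adjustedRandIndex(p$labels, d$planted_modules)
  }
  aris <- vapply(c(0.2, 0.5, 0.9), ari_at, numeric(1))
  expect_lte(aris[1], aris[2] + 0.05)
  expect_lte(aris[2], aris[3] + 0.05)
  expect_gt(aris[3], 0.9)
})

test_that("invalid designs are rejected", {
  expect_error(tiny_design(band_coupling = list(alpha = c(0.2, 0.8))),
               "kappa")
  expect_error(planted_design(duration = 1, sampling_rate = 128),
               "512 samples")
  expect_error(planted_design(sampling_rate = 100), "twice the highest")
  pm <- default_planted_modules()[1:19]
  expect_error(tiny_design(planted_modules = pm), "cover all 20")
})

test_that("session trends move the coupling monotonically and clip at bounds", {
  d <- planted_design(
    band_coupling = list(alpha = c(kappa_in = 0.75, kappa_out = 0.6)),
    session_trend = list(alpha = -0.12), seed = 105)
  ks <- t(vapply(1:6, function(s) eegstates:::session_coupling(d, "alpha", s),
                 numeric(2)))
  expect_true(all(diff(ks[, 2]) <= 0))
  expect_true(all(ks[, 2] >= 0 & ks[, 2] <= ks[, 1]))
  expect_equal(ks[1, 2], 0.6)
  expect_equal(ks[6, 2], 0)
})

test_that("null feature tables are uncorrelated; planted effects are recovered", {
  d <- planted_design(seed = 106)
  null_bundle <- generate_feature_tables(d)
  cc <- null_bundle$features[!null_bundle$features$fsrs_missing, ]
  expect_gte(nrow(cc), 200)
  expect_lt(abs(cor(cc$CT, cc$clutch_usage)), 0.15)
  expect_lt(abs(cor(cc$AI, cc$n_errors)), 0.15)

  rs <- vapply(1:10, function(s) {
    b <- generate_feature_tables(planted_design(seed = 1000 + s),
                                 effect_sizes = c("CT~clutch_usage" = 0.5))
    cc <- b$features[!b$features$fsrs_missing, ]
    cor(cc$CT, cc$clutch_usage)
  }, numeric(1))
  expect_true(all(rs > 0.4 & rs < 0.6))
})

test_that("difficulty targets propagate through the component expansion", {
  b <- generate_feature_tables(planted_design(seed = 107),
                               effect_sizes = c("D~n_errors" = 0.4))
  cc <- b$features[!b$features$fsrs_missing, ]
  expect_equal(cor(cc$D, cc$n_errors), 0.4, tolerance = 0.1)
  expect_equal(cc$D, cc$MD + cc$PD + cc$TD + cc$E)
})

test_that("infeasible correlation requests fail with a PSD diagnostic", {
  d <- planted_design(seed = 108)
  expect_error(
    generate_feature_tables(d, effect_sizes = c(
      "CT~clutch_usage" = 0.9, "CT~AI" = 0.9, "clutch_usage~AI" = -0.9)),
    "positive semidefinite")
  expect_error(generate_feature_tables(d, effect_sizes = c("CT~nope" = 0.3)),
               "unknown effect-size column")
  expect_error(generate_feature_tables(d, effect_sizes = c("CT~AI" = 1.2)),
               "\\(-1, 1\\)")
})

test_that("the missing-FSRS mechanism mirrors the study design", {
  b <- generate_feature_tables(planted_design(seed = 109))
  f <- b$features
  expect_true(all(f$fsrs_missing[f$task == 5]))
  expect_true(all(is.na(f$clutch_usage[f$fsrs_missing])))
  expect_true(all(is.na(f$performance[f$fsrs_missing])))
  expect_false(anyNA(f$performance[!f$fsrs_missing]))
  # roughly 260 complete rows under the default design
  expect_gt(sum(!f$fsrs_missing), 200)
  expect_lt(sum(!f$fsrs_missing), 330)
  # FSRS nonnegative, NASA-TLX on its 1-20 scale
  expect_true(all(f$clutch_usage[!f$fsrs_missing] >= 0))
  expect_true(all(f$MD >= 1 & f$MD <= 20))
  # practice bookkeeping: nondecreasing within subject, session gaps fixed
  one <- f[f$subject_id == 1, ]
  expect_true(all(diff(one$practice_time) >= 0))
  expect_equal(unique(f$practice_gap[f$session == 2]), 7)
})
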