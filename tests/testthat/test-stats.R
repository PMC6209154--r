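test_that("pearson_r_p matches the reference implementation", {
  set.seed(14)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    ours <- pearson_r_p(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$n, n)
  }
})

test_that("perfect linearity, symmetry, and affine invariance hold", {
  x <- 1:20
  res <- pearson_r_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_lt(res$p, 1e-12)

  set.seed(15)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson_r_p(a, b)$r, pearson_r_p(b, a)$r)
  expect_equal(pearson_r_p(5 * a + 2, b)$r, pearson_r_p(a, b)$r)
  expect_equal(pearson_r_p(-5 * a, b)$r, -pearson_r_p(a, b)$r)
})

test_that("degenerate inputs are flagged or rejected", {
  expect_error(pearson_r_p(1:2, 1:2), "at least 3")
  res <- pearson_r_p(rep(1, 10), rnorm(10))
  expect_true(is.na(res$r))
  expect_equal(res$flag, "zero_variance")
  # pairwise-complete deletion
  x <- c(1:9, NA)
  y <- c(NA, 2 * (2:10))
  expect_equal(pearson_r_p(x, y)$n, 8)
})

test_that("null correlations stay small at large n", {
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    abs(pearson_r_p(rnorm(1e4), rnorm(1e4))$r) < 0.03
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("printed-correlation p-values and the critical |r| are consistent", {
  expect_equal(r_to_p(-0.84, 6), 0.036, tolerance = 0.015)
  expect_equal(r_to_p(-0.90, 6), 0.014, tolerance = 0.015)
  # critical |r| at n = 6 makes the |r| > 0.2 gate nearly vacuous
  expect_equal(critical_r(6), 0.8114, tolerance = 1e-3)
  expect_equal(r_to_p(critical_r(6), 6), 0.05, tolerance = 1e-10)
  expect_lt(critical_r(260), 0.2)
})

test_that("the joint significance rule gates on both |r| and p", {
  expect_true(is_significant(0.5, 0.01))
  expect_false(is_significant(0.15, 0.001))   # |r| too small
  expect_false(is_significant(0.9, 0.2))      # p too large
  expect_false(is_significant(NA, 0.01))
})

test_that("session-level reports cover six measures per band per covariate", {
  set.seed(16)
  summary <- expand.grid(session = 1:6,
                         band = c("theta", "alpha", "beta", "gamma"),
                         stringsAsFactors = FALSE)
  for (m in c("recruitment_motor", "recruitment_cognitive",
              "recruitment_visual", "integration_motor_visual",
              "integration_motor_cognitive", "integration_visual_cognitive")) {
    summary[[m]] <- runif(nrow(summary))
  }
  summary$avg_practice_time <- 100 * summary$session + rnorm(24)
  summary$avg_practice_gap <- c(0, 7, 23, 60, 90, 185)[summary$session]
  summary$avg_performance <- 70 + 2 * summary$session + rnorm(24)
  reports <- build_session_report(summary)
  expect_named(reports, c("performance", "practice_time", "practice_gap"))
  expect_equal(nrow(reports$practice_time), 24)
  expect_true(all(reports$practice_time$n == 6))

  # a planted perfect monotone relation is recovered with r = -1
  summary$integration_motor_cognitive <- 1 - 0.1 * summary$session
  rep2 <- session_correlations(summary, "avg_practice_gap")
  cell <- rep2[rep2$band == "alpha" &
                 rep2$measure == "integration_motor_cognitive", ]
  expect_lt(cell$r, -0.9)
})

test_that("constant series produce flagged, non-significant cells", {
  summary <- data.frame(session = 1:6, band = "alpha",
                        recruitment_motor = 0.8,
                        recruitment_cognitive = runif(6),
                        recruitment_visual = runif(6),
                        integration_motor_visual = runif(6),
                        integration_motor_cognitive = runif(6),
                        integration_visual_cognitive = runif(6),
                        avg_practice_time = 1:6 * 100,
                        avg_practice_gap = c(0, 7, 23, 60, 90, 185),
                        avg_performance = 70 + 1:6)
  rep <- session_correlations(summary, "avg_practice_time")
  cell <- rep[rep$measure == "recruitment_motor", ]
  expect_true(is.na(cell$r))
  expect_equal(cell$flag, "zero_variance")
  expect_false(cell$significant)
})

test_that("feature reports demand complete FSRS rows and apply the bold rule", {
  set.seed(17)
  n <- 120
  feats <- data.frame(CT = rnorm(n, 90, 20), APA = rnorm(n, 0.2, 0.1),
                      AI = rnorm(n, 0, 0.2))
  for (b in c("theta", "alpha", "beta", "gamma")) {
    feats[[paste0("strength_", b)]] <- runif(n)
    feats[[paste0("communication_", b)]] <- runif(n)
  }
  for (m in eegstates:::fsrs_metric_names()) feats[[m]] <- rnorm(n, 8, 3)
  # plant one strong relation
  feats$clutch_usage <- feats$clutch_usage + 0.08 * feats$CT
  rep <- build_feature_report(feats)
  # 11 features present (no pass-through cognitive columns) x 8 metrics
  expect_equal(nrow(rep), 11 * 8)
  cell <- rep[rep$feature == "CT" & rep$metric == "clutch_usage", ]
  expect_true(cell$significant)

  feats$D <- rnorm(n, 40, 10)
  feats$complexity <- sample(1:5, n, TRUE)
  rep4 <- build_difficulty_report(feats)
  expect_equal(nrow(rep4), 2 * 8)

  few <- feats[1:5, ]
  expect_error(build_feature_report(few), "FSRS-complete rows")
  expect_error(build_feature_report(feats[, -match("clutch_usage",
                                                   names(feats))]),
               "missing FSRS")
})

test_that("markdown rendering bolds exactly the significant cells", {
  rep <- data.frame(feature = c("CT", "CT"), metric = c("m1", "m2"),
                    r = c(0.5, 0.1), p = c(0.001, 0.6), n = 100,
                    significant = c(TRUE, FALSE), flag = "")
  class(rep) <- c("correlation_report", class(rep))
  md <- format_report_markdown(rep, row_col = "feature", col_col = "metric")
  expect_true(any(grepl("\\*\\*0\\.50", md)))
  expect_false(any(grepl("\\*\\*0\\.10", md)))
})
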