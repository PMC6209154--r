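#' Pearson correlation with two-tailed t-test p-value
#'
#' Sample Pearson correlation of the pairwise-complete observations, with
#' the two-tailed p-value from the t transform
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric series.
#' @return list with `r`, `p`, `n`. If either series has zero variance the
#'   correlation is undefined: `r` and `p` are `NA` and `flag` is
#'   `"zero_variance"`.
#' @export
pearson_r_p <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairwise-complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = n, flag = "zero_variance"))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n, flag = NULL)
}

#' Joint significance rule for correlation cells
#'
#' A correlation is reported significant when `|r| > 0.2` and `p < 0.05`
#' jointly. At small n the p-value gate dominates (at n = 6 the critical
#' |r| at p = 0.05 is about 0.811); at large n the |r| > 0.2 gate
#' dominates.
#'
#' @param r,p correlation and p-value (vectorized).
#' @param r_min correlation-magnitude gate (default 0.2).
#' @param alpha p-value gate (default 0.05).
#' @return logical vector.
#' @export
is_significant <- function(r, p, r_min = 0.2, alpha = 0.05) {
  !is.na(r) & !is.na(p) & abs(r) > r_min & p < alpha
}

#' Critical correlation magnitude of the two-tailed t-test
#'
#' The |r| above which the two-tailed t-transform p-value drops below
#' `alpha` at sample size `n`.
#'
#' @param n sample size.
#' @param alpha significance level (default 0.05).
#' @return scalar critical |r|.
#' @export
critical_r <- function(n, alpha = 0.05) {
  tcrit <- stats::qt(1 - alpha / 2, df = n - 2)
  tcrit / sqrt(n - 2 + tcrit^2)
}

#' Two-tailed p-value of a printed correlation
#'
#' Recovers the p-value implied by a reported Pearson correlation at a
#' given sample size via the t transform; useful for checking the
#' internal consistency of published (r, p, n) triples.
#'
#' @param r correlation coefficient.
#' @param n sample size.
#' @return two-tailed p-value.
#' @examples
#' r_to_p(-0.84, 6)  # ~ 0.036
#' @export
r_to_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

report_row <- function(x, y) {
  n_ok <- sum(is.finite(x) & is.finite(y))
  if (n_ok < 3) {
    return(data.frame(r = NA_real_, p = NA_real_, n = n_ok,
                      significant = FALSE, flag = "insufficient_n",
                      stringsAsFactors = FALSE))
  }
  res <- pearson_r_p(x, y)
  data.frame(r = res$r, p = res$p, n = res$n,
             significant = is_significant(res$r, res$p),
             flag = if (is.null(res$flag)) "" else res$flag,
             stringsAsFactors = FALSE)
}

#' Session-level correlation reports (integration/recruitment dynamics)
#'
#' From a session-by-band summary of integration and recruitment (the
#' `summary` element of [pool_by_session()]), correlates each of the six
#' dynamic-architecture measures (motor/cognitive/visual recruitment;
#' motor-visual, motor-cognitive, visual-cognitive integration) with a
#' session-level covariate, per band, across the sessions (n = number of
#' sessions, 6 in the study design).
#'
#' `build_session_report(summary)` returns the reports against average
#' performance and practice time (the learning-dynamics table) and against
#' practice gap (the gap table).
#'
#' @param summary data frame as produced by [pool_by_session()].
#' @param covariate column name of the covariate to correlate against.
#' @return data frame of class `correlation_report` with one row per
#'   (band, measure).
#' @export
session_correlations <- function(summary, covariate) {
  measures <- c("recruitment_motor", "recruitment_cognitive",
                "recruitment_visual", "integration_motor_visual",
                "integration_motor_cognitive", "integration_visual_cognitive")
  if (!covariate %in% names(summary)) {
    stop("covariate column not found: ", covariate)
  }
  rows <- list()
  for (band in unique(summary$band)) {
    sub <- summary[summary$band == band, ]
    for (m in measures) {
      cell <- report_row(sub[[m]], sub[[covariate]])
      rows[[paste(band, m)]] <- cbind(
        data.frame(band = band, measure = m, covariate = covariate,
                   stringsAsFactors = FALSE),
        cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", class(out))
  out
}

#' @rdname session_correlations
#' @export
build_session_report <- function(summary) {
  list(
    performance = session_correlations(summary, "avg_performance"),
    practice_time = session_correlations(summary, "avg_practice_time"),
    practice_gap = session_correlations(summary, "avg_practice_gap")
  )
}

#' Recording-level correlation reports (features vs tool-based metrics)
#'
#' `build_feature_report()` correlates each available EEG/behavioral
#' feature column (CT, optional pass-through cognitive columns, APA, AI,
#' per-band strength and communication) with the eight FSRS tool-based
#' metrics over recordings with complete FSRS scores.
#' `build_difficulty_report()` correlates NASA-TLX difficulty and task
#' complexity with the same metrics.
#'
#' @param features per-recording feature table carrying the FSRS metric
#'   columns ([fsrs_metric_names()]) and feature columns.
#' @param feature_cols optional explicit feature column set.
#' @param min_rows minimum number of FSRS-complete rows (default 10).
#' @return data frame of class `correlation_report`, one row per
#'   (feature, metric) pair.
#' @export
build_feature_report <- function(features, feature_cols = NULL,
                                 min_rows = 10) {
  metrics <- fsrs_metric_names()
  missing <- setdiff(metrics, names(features))
  if (length(missing)) stop("missing FSRS columns: ",
                            paste(missing, collapse = ", "))
  complete <- stats::complete.cases(features[metrics])
  feats <- features[complete, , drop = FALSE]
  if (nrow(feats) < min_rows) {
    stop("only ", nrow(feats), " FSRS-complete rows; need >= ", min_rows)
  }
  if (is.null(feature_cols)) {
    candidates <- c("CT", "Distraction", "LE", "HE", "MW", "APA", "AI",
                    paste0("strength_", band_names()),
                    paste0("communication_", band_names()))
    feature_cols <- intersect(candidates, names(feats))
  }
  rows <- list()
  for (f in feature_cols) {
    for (m in metrics) {
      cell <- report_row(feats[[f]], feats[[m]])
      rows[[paste(f, m)]] <- cbind(
        data.frame(feature = f, metric = m, stringsAsFactors = FALSE), cell)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("correlation_report", class(out))
  out
}

#' @rdname build_feature_report
#' @export
build_difficulty_report <- function(features, min_rows = 10) {
  need <- c("D", "complexity")
  missing <- setdiff(need, names(features))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  build_feature_report(features, feature_cols = need, min_rows = min_rows)
}

#' @export
print.correlation_report <- function(x, ...) {
  df <- as.data.frame(x)
  df$r <- round(df$r, 2)
  df$p <- signif(df$p, 2)
  df$significant <- ifelse(df$significant, "*", "")
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Render a correlation report as Markdown
#'
#' Significant cells (joint rule of [is_significant()]) are bolded, the
#' convention used in the printed tables this report mirrors.
#'
#' @param report a `correlation_report`.
#' @param row_col,col_col column names spanning the output rows/columns.
#' @return character vector of Markdown lines.
#' @export
format_report_markdown <- function(report,
                                   row_col = intersect(c("feature", "measure"),
                                                       names(report))[1],
                                   col_col = intersect(c("metric", "covariate"),
                                                       names(report))[1]) {
  rows <- unique(report[[row_col]])
  cols <- unique(report[[col_col]])
  fmt <- function(r, p, sig) {
    cell <- sprintf("%.2f (%.3g)", r, p)
    if (isTRUE(sig)) paste0("**", cell, "**") else cell
  }
  header <- paste0("| ", row_col, " | ", paste(cols, collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", length(cols) + 1), collapse = "|"), "|")
  lines <- c(header, sep)
  for (rw in rows) {
    cells <- vapply(cols, function(cl) {
      hit <- report[[row_col]] == rw & report[[col_col]] == cl
      if (!any(hit)) return("")
      i <- which(hit)[1]
      fmt(report$r[i], report$p[i], report$significant[i])
    }, character(1))
    lines <- c(lines, paste0("| ", rw, " | ",
                             paste(cells, collapse = " | "), " |"))
  }
  lines
}
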