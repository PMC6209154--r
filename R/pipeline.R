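#' Run the full functional-state pipeline
#'
#' For every recording and requested band: (optionally) preprocess, build
#' the phase-synchronization adjacency, select a partition by
#' resolution-swept modularity maximization; then pool partitions into
#' per-(session, band) module-allegiance matrices, summarize integration
#' and recruitment against session covariates, and build the session-level
#' correlation reports. If a feature table with FSRS scores is supplied
#' (e.g. from [generate_feature_tables()]), recording-level feature and
#' difficulty reports are built as well.
#'
#' @param recordings list of [recording()] objects, or a
#'   `synthetic_bundle` from [generate_study()] (its recordings and
#'   feature table are both used).
#' @param features optional per-recording feature table carrying
#'   `subject_id`, `session`, `task`, FSRS columns and covariates.
#' @param bands bands to analyse (default all four).
#' @param convention synchronization convention ([sync_index()]).
#' @param gamma_grid,restarts,max_communities resolution-selection
#'   controls ([select_resolution()]).
#' @param seed master seed for the community-detection restarts.
#' @param preprocess_signals apply [preprocess()] to each recording first
#'   (default `TRUE`).
#' @param out_dir optional directory; when given, adjacencies, partitions,
#'   allegiance matrices and reports are written there as CSV/JSON.
#' @param verbose log progress to the console.
#' @return list with `partitions`, `pools` (allegiance matrices and the
#'   session summary), `session_reports`, and when FSRS features are
#'   available `feature_report` and `difficulty_report`.
#' @export
run_pipeline <- function(recordings, features = NULL,
                         bands = band_names(),
                         convention = "normalized",
                         gamma_grid = seq(0.5, 2, by = 0.05),
                         restarts = 20, max_communities = 6, seed = 1L,
                         preprocess_signals = TRUE, out_dir = NULL,
                         verbose = FALSE) {
  if (inherits(recordings, "synthetic_bundle")) {
    if (is.null(features)) features <- recordings$features
    recordings <- recordings$recordings
  }
  if (is.null(recordings) || length(recordings) == 0) {
    stop("no recordings supplied")
  }
  bands <- vapply(bands, check_band, character(1))
  say <- function(...) if (verbose) message(sprintf(...))
  perf_of <- function(rec) {
    if (is.null(features)) return(NA_real_)
    hit <- which(features$subject_id == rec$subject_id &
                   features$session == rec$session &
                   features$task == rec$task)
    if (length(hit) == 1 && "performance" %in% names(features)) {
      features$performance[hit]
    } else NA_real_
  }
  partitions <- list()
  for (ri in seq_along(recordings)) {
    rec <- recordings[[ri]]
    if (preprocess_signals) rec <- preprocess(rec)
    if (rec$excised_fraction > 0) {
      say("recording %d: excised %.1f%% as artifact", ri,
          100 * rec$excised_fraction)
    }
    for (b in bands) {
      adj <- build_adjacency(rec, b, convention = convention)
      part <- select_resolution(adj, gamma_grid = gamma_grid,
                                restarts = restarts,
                                max_communities = max_communities,
                                seed = derive_seed(seed, ri * 37L +
                                                     match(b, band_names())))
      part$meta <- list(
        subject_id = rec$subject_id, session = rec$session,
        task = rec$task, band = b,
        practice_time = rec$practice_time,
        practice_gap = rec$practice_gap,
        performance = perf_of(rec))
      partitions[[length(partitions) + 1L]] <- part
      say("recording %d band %s: %d communities, Q = %.3f at gamma = %.2f",
          ri, b, part$n_communities, part$q, part$gamma)
    }
  }
  pools <- pool_by_session(partitions)
  session_reports <- build_session_report(pools$summary)
  out <- list(partitions = partitions, pools = pools,
              session_reports = session_reports)
  if (!is.null(features) &&
      all(fsrs_metric_names() %in% names(features)) &&
      sum(stats::complete.cases(features[fsrs_metric_names()])) >= 10) {
    out$feature_report <- build_feature_report(features)
    if (all(c("D", "complexity") %in% names(features))) {
      out$difficulty_report <- build_difficulty_report(features)
    }
  }
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (key in names(result$pools$mams)) {
    write_mam_csv(result$pools$mams[[key]],
                  file.path(out_dir, paste0("mam_", key, ".csv")))
  }
  utils::write.csv(result$pools$summary,
                   file.path(out_dir, "session_summary.csv"),
                   row.names = FALSE)
  for (nm in names(result$session_reports)) {
    utils::write.csv(result$session_reports[[nm]],
                     file.path(out_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(result$feature_report)) {
    utils::write.csv(result$feature_report,
                     file.path(out_dir, "report_features.csv"),
                     row.names = FALSE)
  }
  if (!is.null(result$difficulty_report)) {
    utils::write.csv(result$difficulty_report,
                     file.path(out_dir, "report_difficulty.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}
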