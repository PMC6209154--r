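#' Read and write recordings as CSV
#'
#' The on-disk format is one CSV per recording with one column per montage
#' channel (header = channel labels) and one row per sample, in microvolts.
#' Study metadata (sampling rate, subject, session, task, practice
#' covariates) travels in a JSON sidecar `<path>.meta.json`, written and
#' read automatically. Extra columns in the CSV are ignored with a
#' warning; missing montage channels are an error naming the absent
#' labels.
#'
#' @param rec an [recording()].
#' @param path CSV file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot_recording(rec)
  df <- as.data.frame(t(rec$signal))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               subject_id = rec$subject_id, session = rec$session,
               task = rec$task, repetitions = rec$repetitions,
               practice_time = rec$practice_time,
               practice_gap = rec$practice_gap)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate sampling rate override; defaults to the sidecar
#'   value and errors if neither is available.
#' @export
read_recording_csv <- function(path, sampling_rate = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(eeg_channels(), names(df))
  if (length(missing)) {
    stop("recording is missing montage channels: ",
         paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(df), eeg_channels())
  if (length(extra)) {
    warning("ignoring extra columns: ", paste(extra, collapse = ", "))
  }
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list()
  if (is.null(sampling_rate)) sampling_rate <- meta$sampling_rate
  if (is.null(sampling_rate)) {
    stop("no sampling rate: supply `sampling_rate` or a .meta.json sidecar")
  }
  null_na <- function(x, na) if (is.null(x)) na else x
  recording(t(as.matrix(df[eeg_channels()])), sampling_rate,
            subject_id = null_na(meta$subject_id, NA),
            session = null_na(meta$session, NA_integer_),
            task = null_na(meta$task, NA_integer_),
            repetitions = null_na(meta$repetitions, 1L),
            practice_time = null_na(meta$practice_time, NA_real_),
            practice_gap = null_na(meta$practice_gap, NA_real_))
}

#' Read and write adjacency and allegiance matrices as labelled CSV
#'
#' Row and column headers are the channel labels; values round-trip
#' through full-precision decimal representation.
#'
#' @param adj a [build_adjacency()] result.
#' @param path CSV file path.
#' @export
write_adjacency_csv <- function(adj, path) {
  m <- as_adjacency_matrix(adj)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  if (inherits(adj, "band_adjacency")) {
    jsonlite::write_json(
      list(band = adj$band, convention = adj$convention,
           n_samples = adj$n_samples),
      paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_adjacency_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    structure(list(gamma = m, band = meta$band,
                   convention = meta$convention,
                   n_samples = meta$n_samples),
              class = "band_adjacency")
  } else m
}

#' @rdname write_adjacency_csv
#' @param mam an [build_mam()] result.
#' @export
write_mam_csv <- function(mam, path) {
  m <- as_mam_matrix(mam)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_adjacency_csv
#' @export
read_mam_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  structure(list(mam = m, n_partitions = NA_integer_, pool = NULL),
            class = "allegiance_matrix")
}

#' Serialize a partition to JSON
#'
#' The JSON object carries the channel-to-community map plus the achieved
#' modularity, the selected resolution and the seed.
#'
#' @param part an `eeg_partition`.
#' @param path JSON file path.
#' @export
write_partition_json <- function(part, path) {
  obj <- list(labels = as.list(part$labels), q = part$q,
              gamma = part$gamma, seed = part$seed,
              n_communities = part$n_communities,
              flags = part$flags, meta = part$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_partition_json
#' @export
read_partition_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- unlist(obj$labels)
  out <- partition(labels, q = obj$q, gamma = obj$gamma,
                   seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
                   flags = unlist(obj$flags) %||% character(0),
                   meta = as.list(obj$meta))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
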