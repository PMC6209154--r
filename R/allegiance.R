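#' Module allegiance matrix from a pool of partitions
#'
#' Entry (i, j) is the empirical probability, over the supplied partitions,
#' that channels i and j were assigned to the same functional community.
#' The diagonal is identically 1.
#'
#' @param partitions list of [louvain_maximize()]/[select_resolution()]
#'   partitions (or plain label vectors) over the same channel set.
#' @return object of class `allegiance_matrix`: list with `mam` (labelled
#'   symmetric matrix in \[0, 1\]), `n_partitions` and optional `pool`
#'   descriptor.
#' @export
build_mam <- function(partitions) {
  if (length(partitions) < 1) stop("need at least one partition")
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "eeg_partition")) p$labels else p
  })
  nm <- names(labs[[1]])
  n <- length(labs[[1]])
  for (l in labs) {
    if (length(l) != n || !identical(names(l), nm)) {
      stop("all partitions must cover the same channels in the same order")
    }
  }
  acc <- matrix(0, n, n, dimnames = list(nm, nm))
  for (l in labs) {
    acc <- acc + outer(l, l, "==")
  }
  mam <- acc / length(labs)
  structure(
    list(mam = mam, n_partitions = length(labs), pool = NULL),
    class = "allegiance_matrix"
  )
}

#' @export
print.allegiance_matrix <- function(x, ...) {
  cat(sprintf("<allegiance_matrix> %d channels, pooled over %d partitions\n",
              nrow(x$mam), x$n_partitions))
  if (!is.null(x$pool)) {
    cat("  pool:", paste(names(x$pool), unlist(x$pool), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

as_mam_matrix <- function(mam) {
  if (inherits(mam, "allegiance_matrix")) return(mam$mam)
  m <- as.matrix(mam)
  if (nrow(m) != ncol(m)) stop("allegiance matrix must be square")
  m
}

#' Recruitment of a structural system
#'
#' Mean co-assignment probability over the unordered within-system channel
#' pairs (self-pairs excluded; the diagonal is identically 1 and carries no
#' information).
#'
#' @param mam an [build_mam()] result or plain co-assignment matrix.
#' @param system system name per [system_map()], needs >= 2 channels.
#' @param map optional channel-to-system map overriding [system_map()].
#' @return scalar in \[0, 1\].
#' @export
recruitment <- function(mam, system, map = system_map()) {
  m <- as_mam_matrix(mam)
  chans <- names(map)[map == system]
  if (length(chans) < 2) {
    stop("system '", system, "' has fewer than two channels")
  }
  chans <- intersect(rownames(m), chans)
  sub <- m[chans, chans]
  mean(sub[upper.tri(sub)])
}

#' Integration between two structural systems
#'
#' Mean co-assignment probability over channel pairs with one channel in
#' each system; symmetric in its system arguments.
#'
#' @inheritParams recruitment
#' @param s1,s2 distinct system names.
#' @return scalar in \[0, 1\].
#' @export
integration <- function(mam, s1, s2, map = system_map()) {
  if (identical(s1, s2)) stop("`s1` and `s2` must differ; see recruitment()")
  m <- as_mam_matrix(mam)
  for (s in c(s1, s2)) {
    if (!s %in% map) stop("unknown system: ", s)
  }
  c1 <- intersect(rownames(m), names(map)[map == s1])
  c2 <- intersect(rownames(m), names(map)[map == s2])
  if (length(c1) == 0 || length(c2) == 0) stop("empty system")
  mean(m[c1, c2])
}

#' Pool partitions into per-(session, band) allegiance matrices
#'
#' Groups a flat list of partitions by session and band (taken from each
#' partition's `$meta`), builds one allegiance matrix per group, and
#' summarizes integration and recruitment of the structural systems next
#' to pool-averaged covariates (practice time, practice gap, performance).
#'
#' @param partitions list of `eeg_partition`s whose `$meta` contains
#'   `session`, `band`, and optionally `practice_time`, `practice_gap`,
#'   `performance`.
#' @param map channel-to-system map (default [system_map()]).
#' @return list with `mams` (named list, keys `"<band>.s<session>"`) and
#'   `summary`, a data frame with one row per (session, band) carrying the
#'   three recruitment and three integration coefficients plus averaged
#'   covariates.
#' @export
pool_by_session <- function(partitions, map = system_map()) {
  meta_of <- function(p, field) {
    v <- p$meta[[field]]
    if (is.null(v)) NA else v
  }
  sessions <- vapply(partitions, meta_of, numeric(1), field = "session")
  bands <- vapply(partitions, function(p) {
    v <- p$meta$band
    if (is.null(v)) NA_character_ else v
  }, character(1))
  if (anyNA(sessions) || anyNA(bands)) {
    stop("every partition needs `session` and `band` in its $meta")
  }
  keys <- split(seq_along(partitions), list(band = bands, session = sessions),
                drop = TRUE)
  mams <- list()
  rows <- list()
  for (key in names(keys)) {
    idx <- keys[[key]]
    pool <- partitions[idx]
    mam <- build_mam(pool)
    band <- bands[idx[1]]
    session <- sessions[idx[1]]
    mam$pool <- list(session = session, band = band,
                     n_partitions = length(idx))
    mams[[paste0(band, ".s", session)]] <- mam
    avg <- function(field) {
      v <- vapply(pool, meta_of, numeric(1), field = field)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
    rows[[key]] <- data.frame(
      session = session, band = band, n_partitions = length(idx),
      recruitment_motor = recruitment(mam, "motor", map),
      recruitment_cognitive = recruitment(mam, "cognitive", map),
      recruitment_visual = recruitment(mam, "visual", map),
      integration_motor_visual = integration(mam, "motor", "visual", map),
      integration_motor_cognitive = integration(mam, "motor", "cognitive", map),
      integration_visual_cognitive = integration(mam, "visual", "cognitive", map),
      avg_practice_time = avg("practice_time"),
      avg_practice_gap = avg("practice_gap"),
      avg_performance = avg("performance"),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, rows)
  summary <- summary[order(summary$band, summary$session), ]
  rownames(summary) <- NULL
  list(mams = mams, summary = summary)
}
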