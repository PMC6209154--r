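#' Newman-Girvan null model of a weighted network
#'
#' Expected edge weights under the configuration-model null:
#' `M_ij = k_i k_j / (2m)` with node strengths `k_i = sum_j W_ij` and total
#' weight `m = sum_i k_i / 2`.
#'
#' @param adj symmetric nonnegative adjacency ([build_adjacency()] result
#'   or plain matrix); diagonal is ignored.
#' @return list with `M` (expected-weight matrix), `k` (strengths), `m`.
#' @export
ng_null <- function(adj) {
  w <- as_adjacency_matrix(adj)
  k <- rowSums(w)
  m <- sum(k) / 2
  M <- if (m > 0) outer(k, k) / (2 * m) else matrix(0, nrow(w), ncol(w))
  dimnames(M) <- dimnames(w)
  list(M = M, k = k, m = m)
}

#' Modularity of a partition
#'
#' `Q = sum_{i != j} (W_ij - gamma * M_ij) * [g_i == g_j]`, summing over
#' ordered node pairs with the diagonal excluded; `M` is the Newman-Girvan
#' null ([ng_null()]) and `gamma` the resolution parameter. Self-pairs
#' carry no community information (the diagonal of a synchronization
#' adjacency is an artifact of self-locking), so they are excluded.
#'
#' @param adj symmetric nonnegative adjacency.
#' @param labels integer or factor community labels covering all nodes.
#' @param gamma resolution parameter, positive (default 1).
#' @return scalar modularity Q.
#' @examples
#' # two disconnected unit dyads, partitioned into the dyads: Q = 3
#' w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
#' modularity_q(w, c(1, 1, 2, 2))
#' @export
modularity_q <- function(adj, labels, gamma = 1) {
  w <- as_adjacency_matrix(adj)
  if (any(w < 0)) stop("negative edge weights are not supported")
  if (gamma < 0) stop("`gamma` must be nonnegative")
  labels <- as.integer(as.factor(labels))
  if (length(labels) != nrow(w)) stop("labels must cover all nodes")
  nullm <- ng_null(w)
  B <- w - gamma * nullm$M
  diag(B) <- 0
  same <- outer(labels, labels, "==")
  sum(B[same])
}

# Modularity matrix B = W - gamma*M with zero diagonal.
modularity_matrix <- function(w, gamma) {
  nullm <- ng_null(w)
  B <- w - gamma * nullm$M
  diag(B) <- 0
  B
}

# One sweep of greedy single-node moves on (possibly aggregated) matrix B
# (diagonal = internal weight, constant under moves). Nodes are visited in
# `node_order`; each node moves to the community with the largest strictly
# positive modularity gain (ties: lowest community id; a fresh singleton
# community is the last-preference candidate). Returns the final labels.
local_moves <- function(B, comm, node_order, tol = 1e-12) {
  n <- nrow(B)
  repeat {
    moved <- FALSE
    for (i in node_order) {
      w <- B[i, ]
      w[i] <- 0
      s <- vapply(split(w, comm), sum, numeric(1))
      cids <- as.integer(names(s))
      a <- comm[i]
      s_a <- s[match(a, cids)]
      # gain of moving i into community c: 2 * (s_c - s_a); into a new
      # singleton: 2 * (0 - s_a)
      gains <- 2 * (s - s_a)
      gains[match(a, cids)] <- 0
      new_id <- max(comm) + 1L
      cand <- c(cids, new_id)
      cand_gain <- c(gains, -2 * s_a)
      best <- max(cand_gain)
      if (best > tol) {
        pick <- cand[cand_gain >= best - 1e-15][1]
        if (pick != a) {
          comm[i] <- pick
          moved <- TRUE
        }
      }
    }
    if (!moved) break
  }
  comm
}

# Aggregate B by communities; diagonal accumulates internal weight.
aggregate_matrix <- function(B, comm) {
  f <- as.factor(comm)
  agg <- rowsum(t(rowsum(B, f)), f)
  as.matrix(agg)
}

louvain_once <- function(B, node_order) {
  n <- nrow(B)
  q_of <- function(lab) sum(B[outer(lab, lab, "==")])
  # phase 1: greedy node moves from singletons
  labels <- local_moves(B, seq_len(n), node_order)
  labels <- match(labels, sort(unique(labels)))
  # iterate (community-level aggregation moves, node-level refinement)
  # until a full cycle stops improving Q
  repeat {
    q_before <- q_of(labels)
    repeat {
      Bagg <- aggregate_matrix(B, labels)
      k <- nrow(Bagg)
      if (k == 1) break
      agg <- local_moves(Bagg, seq_len(k), seq_len(k))
      agg <- match(agg, sort(unique(agg)))
      labels <- agg[labels]
      if (length(unique(agg)) == k) break
    }
    labels <- local_moves(B, labels, node_order)
    labels <- match(labels, sort(unique(labels)))
    if (q_of(labels) <= q_before + 1e-12) break
  }
  match(labels, unique(labels))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483629)
}

#' Greedy Louvain modularity maximization
#'
#' Generalized-Louvain style maximization of [modularity_q()] at a fixed
#' resolution: repeated greedy single-node moves followed by community
#' aggregation, then a final node-level refinement pass, so the returned
#' partition is a local maximum (no single-node move increases Q). The
#' node visiting order is drawn under `seed`, making the run deterministic.
#'
#' @param adj symmetric nonnegative adjacency.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed controlling the node order.
#' @return object of class `eeg_partition`: list with `labels` (named
#'   integer vector, community ids contiguous from 1), `q`, `gamma`,
#'   `n_communities`, `seed`.
#' @export
louvain_maximize <- function(adj, gamma = 1, seed = 1L) {
  w <- as_adjacency_matrix(adj)
  if (any(w < 0)) stop("negative edge weights are not supported")
  B <- modularity_matrix(w, gamma)
  n <- nrow(w)
  ord <- with_seed(seed, sample.int(n))
  labels <- louvain_once(B, ord)
  names(labels) <- rownames(w)
  partition(labels, q = modularity_q(w, labels, gamma), gamma = gamma,
            seed = seed)
}

partition <- function(labels, q, gamma, seed = NA_integer_,
                      flags = character(0), meta = list()) {
  nm <- names(labels)
  labels <- match(labels, unique(labels))
  names(labels) <- nm
  structure(
    list(labels = labels, q = q, gamma = gamma,
         n_communities = length(unique(labels)),
         seed = seed, flags = flags, meta = meta),
    class = "eeg_partition"
  )
}

#' @export
print.eeg_partition <- function(x, ...) {
  cat(sprintf(
    "<eeg_partition> %d communities, Q = %.4f at gamma = %.3g\n",
    x$n_communities, x$q, x$gamma))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Resolution selection by constrained modularity maximization
#'
#' Sweeps a grid of resolution values; at each value runs
#' [louvain_maximize()] with `restarts` random node orders and keeps the
#' best modularity. Among grid points whose best partition has at most
#' `max_communities` communities, the partition with maximal Q is
#' returned; ties break toward the smaller resolution. If no grid point
#' satisfies the community cap the partition with the fewest communities
#' is returned, flagged `"constraint_unmet"`.
#'
#' The default cap of 6 matches the montage's six anatomical groupings
#' (frontal, prefrontal, central, temporal, parietal, occipital); finer
#' partitions of a 20-node network tend to produce uninformative
#' singleton communities.
#'
#' @param adj symmetric nonnegative adjacency.
#' @param gamma_grid ascending grid of resolutions (default 0.5-2.0 by
#'   0.05).
#' @param max_communities maximum acceptable community count (default 6).
#' @param restarts random-order restarts per grid point (default 20).
#' @param seed master seed; restart seeds are derived from it.
#' @return `eeg_partition` with the selected resolution recorded in
#'   `$gamma`; the full sweep is attached as attribute `"sweep"`.
#' @export
select_resolution <- function(adj, gamma_grid = seq(0.5, 2, by = 0.05),
                              max_communities = 6, restarts = 20,
                              seed = 1L) {
  if (length(gamma_grid) == 0) stop("`gamma_grid` must be nonempty")
  if (is.unsorted(gamma_grid, strictly = TRUE)) {
    stop("`gamma_grid` must be strictly ascending")
  }
  w <- as_adjacency_matrix(adj)
  if (any(w < 0)) stop("negative edge weights are not supported")
  n <- nrow(w)
  results <- vector("list", length(gamma_grid))
  for (gi in seq_along(gamma_grid)) {
    g <- gamma_grid[gi]
    B <- modularity_matrix(w, g)
    best_q <- -Inf
    best_labels <- NULL
    best_seed <- NA_integer_
    for (r in seq_len(restarts)) {
      rs <- derive_seed(seed, (gi - 1L) * restarts + r)
      ord <- with_seed(rs, sample.int(n))
      labels <- louvain_once(B, ord)
      q <- modularity_q(w, labels, g)
      if (q > best_q + 1e-12) {
        best_q <- q
        best_labels <- labels
        best_seed <- rs
      }
    }
    results[[gi]] <- list(gamma = g, q = best_q, labels = best_labels,
                          n_comm = length(unique(best_labels)),
                          seed = best_seed)
  }
  ncomm <- vapply(results, `[[`, integer(1), "n_comm")
  qs <- vapply(results, `[[`, numeric(1), "q")
  ok <- ncomm <= max_communities
  flags <- character(0)
  if (any(ok)) {
    pick <- which(ok)[which.max(qs[ok])]   # first max -> smaller gamma
  } else {
    pick <- which(ncomm == min(ncomm))[1]
    flags <- "constraint_unmet"
  }
  sel <- results[[pick]]
  labels <- sel$labels
  names(labels) <- rownames(w)
  out <- partition(labels, q = sel$q, gamma = sel$gamma, seed = sel$seed,
                   flags = flags)
  attr(out, "sweep") <- data.frame(gamma = gamma_grid, q = qs,
                                   n_communities = ncomm)
  out
}
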