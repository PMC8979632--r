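#' Local outlier factor of a query point against a reference set
#'
#' Density-ratio anomaly score used to filter freshly acquired surface points
#' against the recent acquisition buffer. Scores near 1 indicate the point is
#' as dense as its neighbourhood; scores well above 1 indicate an outlier
#' (e.g. a tracking glitch).
#'
#' Definitions follow the classical formulation. For the query point `p` with
#' reference set `neighbors` (which never contains `p` itself):
#' * `k-distance(o)` is the distance from `o` to its k-th nearest neighbour
#'   within the reference set (excluding `o`);
#' * the k-neighbourhood `N_k(o)` contains every reference point within
#'   `k-distance(o)` (ties included, so it may exceed k points);
#' * reachability distance `reach_k(a, b) = max(k-distance(b), d(a, b))`;
#' * local reachability density `lrd(a) = 1 / mean(reach_k(a, o), o in N_k(a))`;
#' * `LOF(p) = mean(lrd(o), o in N_k(p)) / lrd(p)`.
#'
#' The query's neighbourhood and every neighbour's neighbourhood are taken
#' within the reference set only ("novelty" convention), matching the
#' streaming use where the buffer is the reference.
#'
#' @param p length-3 numeric, the query point (mm).
#' @param neighbors n x 3 matrix of reference points (mm), n > k.
#' @param k neighbour count (default 5).
#' @return A single positive LOF score.
#' @export
local_outlier_factor <- function(p, neighbors, k = 5L) {
  nb <- as.matrix(neighbors)
  if (is.null(dim(nb)) || ncol(nb) != 3) stop("neighbors must be an n x 3 matrix")
  n <- nrow(nb)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k) {
    stop(sprintf("local_outlier_factor needs more than k = %d reference points (got %d); wait for the buffer to fill", k, n))
  }

  # pairwise distances within the reference set
  d_ref <- as.matrix(stats::dist(nb))
  # query-to-reference distances
  d_q <- sqrt(colSums((t(nb) - p)^2))

  kdist <- numeric(n)       # k-distance of each reference point within the set
  hood <- vector("list", n) # its k-neighbourhood (indices), ties included
  for (i in seq_len(n)) {
    di <- d_ref[i, -i]
    idx <- seq_len(n)[-i]
    kd <- sort(di, partial = k)[k]
    kdist[i] <- kd
    hood[[i]] <- idx[di <= kd + .Machine$double.eps * max(kd, 1)]
  }

  lrd_ref <- vapply(seq_len(n), function(i) {
    o <- hood[[i]]
    r <- pmax(kdist[o], d_ref[i, o])
    m <- mean(r)
    if (m == 0) Inf else 1 / m
  }, numeric(1))

  kd_q <- sort(d_q, partial = k)[k]
  hood_q <- which(d_q <= kd_q + .Machine$double.eps * max(kd_q, 1))
  r_q <- pmax(kdist[hood_q], d_q[hood_q])
  m_q <- mean(r_q)
  lrd_q <- if (m_q == 0) Inf else 1 / m_q

  num <- mean(lrd_ref[hood_q])
  if (is.infinite(lrd_q) && is.infinite(num)) return(1)
  if (is.infinite(lrd_q)) return(0)
  num / lrd_q
}
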