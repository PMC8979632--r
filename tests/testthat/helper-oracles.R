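# Independent oracles used across the suite. These are deliberately written
# from first principles (naive loops, closed forms), not by calling the
# package internals they check.

# --- brute-force LOF straight from the definition ---------------------------
lof_bruteforce <- function(p, nb, k) {
  n <- nrow(nb)
  dmat <- as.matrix(stats::dist(nb))
  dq <- apply(nb, 1, function(r) sqrt(sum((p - r)^2)))
  kdist <- sapply(seq_len(n), function(i) sort(dmat[i, -i])[k])
  hood <- lapply(seq_len(n), function(i) {
    idx <- setdiff(seq_len(n), i)
    idx[dmat[i, idx] <= kdist[i] + 1e-12]
  })
  lrd <- sapply(seq_len(n), function(i) {
    1 / mean(pmax(kdist[hood[[i]]], dmat[i, hood[[i]]]))
  })
  kq <- sort(dq)[k]
  hood_q <- which(dq <= kq + 1e-12)
  lrd_q <- 1 / mean(pmax(kdist[hood_q], dq[hood_q]))
  mean(lrd[hood_q]) / lrd_q
}

# --- closed-form distance from a sphere to a cone's lateral surface ---------
# apex a, unit axis u, half-angle alpha; sphere centre c, radius r
cone_sphere_clearance <- function(a, u, alpha, c, r) {
  v <- c - a
  t_ax <- sum(v * u)
  r_perp <- sqrt(max(sum(v^2) - t_ax^2, 0))
  # distance from (t_ax, r_perp) to the line r = t * tan(alpha) in the
  # axial half-plane (point assumed inside the cone)
  t_ax * sin(alpha) - r_perp * cos(alpha) - r
}

# --- naive exact point-to-triangle distance (barycentric clamp by search) ---
point_triangle_dist_naive <- function(p, a, b, c, n_grid = 60) {
  s <- seq(0, 1, length.out = n_grid)
  best <- Inf
  for (u in s) for (v in s) {
    if (u + v <= 1) {
      q <- a + u * (b - a) + v * (c - a)
      best <- min(best, sqrt(sum((p - q)^2)))
    }
  }
  best
}

# exhaustive min distance between a point set and a mesh: every vertex pair
# plus projections onto every face plane (clamped via dense sampling)
min_point_mesh_dist_naive <- function(points, mesh, n_grid = 25) {
  v <- mesh$vertices; f <- mesh$faces
  best <- Inf
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    for (j in seq_len(nrow(f))) {
      best <- min(best, point_triangle_dist_naive(p, v[f[j, 1], ], v[f[j, 2], ],
                                                  v[f[j, 3], ], n_grid))
    }
  }
  best
}

# --- exhaustive graph-cut energy oracle --------------------------------------
# Recomputes the segmentation energy from its definition (32-bin Laplace
# histograms on the raw image, contrast-weighted Potts with
# sigma^2 = mean(dI^2)) and enumerates all labellings of the free pixels.
# Returns the minimal energy and one minimising mask.
graphcut_exhaustive <- function(image, labels, lambda, connectivity = 4,
                                n_bins = 32) {
  H <- nrow(image); W <- ncol(image)
  breaks <- seq(0, 255, length.out = n_bins + 1); breaks[n_bins + 1] <- Inf
  hist_p <- function(x) {
    cnt <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
    (cnt + 1) / (sum(cnt) + n_bins)
  }
  p_fg <- hist_p(image[labels == 2])
  p_bg <- hist_p(image[labels == 0 | labels == 3])
  bin <- findInterval(image, breaks, all.inside = TRUE)
  d_fg <- matrix(-log(p_fg)[bin], H, W)
  d_bg <- matrix(-log(p_bg)[bin], H, W)

  id <- matrix(seq_len(H * W), H, W)
  pairs <- rbind(cbind(as.vector(id[-H, ]), as.vector(id[-1, ]), 1),
                 cbind(as.vector(id[, -W]), as.vector(id[, -1]), 1))
  if (connectivity == 8) {
    pairs <- rbind(pairs,
                   cbind(as.vector(id[-H, -W]), as.vector(id[-1, -1]), sqrt(2)),
                   cbind(as.vector(id[-1, -W]), as.vector(id[-H, -1]), sqrt(2)))
  }
  dI <- image[pairs[, 1]] - image[pairs[, 2]]
  sig2 <- mean(dI^2); if (sig2 == 0) sig2 <- 1
  wgt <- lambda * exp(-dI^2 / (2 * sig2)) / pairs[, 3]

  fixed <- matrix(NA, H, W)
  fixed[labels == 2] <- TRUE
  fixed[labels == 0 | labels == 3] <- FALSE
  free <- which(is.na(fixed))
  stopifnot(length(free) <= 16)

  base <- fixed
  best_e <- Inf; best_mask <- NULL
  for (code in 0:(2^length(free) - 1)) {
    l <- base
    l[free] <- bitwAnd(bitwShiftR(code, seq_along(free) - 1L), 1L) == 1L
    e <- sum(d_fg[l]) + sum(d_bg[!l]) +
      sum(wgt[l[pairs[, 1]] != l[pairs[, 2]]])
    if (e < best_e) { best_e <- e; best_mask <- l }
  }
  list(energy = best_e, mask = best_mask,
       energy_of = function(mask) {
         sum(d_fg[mask]) + sum(d_bg[!mask]) +
           sum(wgt[mask[pairs[, 1]] != mask[pairs[, 2]]])
       })
}

# --- shared small-phantom fixtures ------------------------------------------
.fixture_env <- new.env()

small_phantom_config <- function(seed = 11L, ...) {
  phantom_config(seed = seed,
                 image_size_px = c(128L, 96L),
                 pixel_spacing_mm = c(0.5, 0.5), ...)
}

# contact model trained once per session on a small phantom
cached_contact_model <- function() {
  if (is.null(.fixture_env$model)) {
    cfg <- small_phantom_config(seed = 77L)
    gt <- generate_phantom(cfg)
    tr <- phantom_training_set(gt, n = 160L, cfg, seed = 770L)
    .fixture_env$model <- train_contact_model(tr$features, tr$labels, seed = 7L)
  }
  .fixture_env$model
}

# a flat phantom (zero surface amplitude) for analytic ground truth
flat_phantom <- function(seed = 21L, ...) {
  cfg <- small_phantom_config(seed = seed, surface_amplitude_mm = 0, ...)
  list(cfg = cfg, gt = generate_phantom(cfg))
}

random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- rbind(
    c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[4] * q[1]), 2 * (q[2] * q[4] + q[3] * q[1])),
    c(2 * (q[2] * q[3] + q[4] * q[1]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[2] * q[1])),
    c(2 * (q[2] * q[4] - q[3] * q[1]), 2 * (q[3] * q[4] + q[2] * q[1]), 1 - 2 * (q[2]^2 + q[3]^2))
  )
  rigid_from_rt(R, stats::rnorm(3, 0, 50))
}
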