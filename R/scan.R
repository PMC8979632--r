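#' Streaming surface acquisition with LOF outlier rejection
#'
#' Implements the scanning loop: every frame is contact-classified; contact
#' frames contribute one candidate surface point (by default the world
#' position of the top-row midpoint pixel, i.e. the transducer-face centre on
#' the liver capsule). Candidates pass through a sliding buffer of the most
#' recent `window` points; once the buffer holds more than `k` points, a
#' candidate enters the point cloud only if its local outlier factor against
#' the buffer stays at or below `tau`. A no-contact frame clears the buffer,
#' so probe lift-offs never bridge stale geometry into a new sweep segment.
#'
#' The inlier rule deserves a note: LOF is approximately 1 for points exactly
#' as dense as their neighbourhood and fluctuates above and below 1 for
#' genuine inliers, so the default accepts `LOF <= tau` with `tau = 1.5`.
#' Two presets reproduce stricter printed variants for auditability:
#' `"prose"` accepts only `LOF < 1`, `"pseudocode"` inverts the rule and
#' accepts `LOF > 1`.
#'
#' @param frames list of `tracked_frame`.
#' @param calib a `probe_calibration`.
#' @param model a trained `contact_model`.
#' @param window sliding buffer size W (default 10).
#' @param k LOF neighbour count; effective k is `min(k, buffer size - 1)`
#'   (default 9).
#' @param tau LOF acceptance threshold (default 1.5).
#' @param preset one of "default", "prose", "pseudocode" (see above).
#' @param surface_pixel function(image) -> length-2 pixel; default top-row
#'   midpoint `c(ncol(image)/2, 0)`.
#' @param min_cloud_size minimum cloud size for meshing (default 50).
#' @param reconstruct logical: reconstruct the mesh (default TRUE).
#' @param recon_config list passed to [reconstruct_surface()].
#' @return list with `cloud` (`point_cloud3d`), `mesh` (`triangle_mesh` or
#'   NULL), `n_contact`, `n_rejected`.
#' @export
scan_stream <- function(frames, calib, model,
                        window = 10L, k = 9L, tau = 1.5,
                        preset = c("default", "prose", "pseudocode"),
                        surface_pixel = NULL,
                        min_cloud_size = 50L,
                        reconstruct = TRUE,
                        recon_config = list()) {
  preset <- match.arg(preset)
  if (length(frames) < 1) stop("scan_stream needs at least one frame")
  if (is.null(surface_pixel)) {
    surface_pixel <- function(image) c(ncol(image) / 2, 0)
  }
  accept <- switch(preset,
    default = function(lof) lof <= tau,
    prose = function(lof) lof < 1,
    pseudocode = function(lof) lof > 1
  )

  buffer <- matrix(numeric(0), ncol = 3)
  pts <- list()
  src <- integer(0)
  n_contact <- 0L
  n_rejected <- 0L

  for (fr in frames) {
    if (predict_contact(model, fr$image) != "contact") {
      buffer <- matrix(numeric(0), ncol = 3)   # clear buffer on lift-off
      next
    }
    n_contact <- n_contact + 1L
    p <- pixel_to_world(fr, calib, surface_pixel(fr$image))
    nb <- nrow(buffer)
    if (nb > k) {
      lof <- local_outlier_factor(p, buffer, min(k, nb - 1L))
      if (accept(lof)) {
        pts[[length(pts) + 1L]] <- p
        src <- c(src, fr$index)
      } else {
        n_rejected <- n_rejected + 1L
      }
    }
    buffer <- rbind(buffer, p)
    if (nrow(buffer) > window) buffer <- buffer[-1, , drop = FALSE]
  }

  if (n_contact == 0L) stop("no surface acquired: no contact frames in the stream")
  cloud <- point_cloud3d(do.call(rbind, c(pts, list(matrix(numeric(0), ncol = 3)))),
                         src)
  mesh <- NULL
  if (reconstruct) {
    if (nrow(cloud$points) < min_cloud_size) {
      stop(errorCondition(
        sprintf("cloud too small for meshing (%d < %d); partial cloud attached",
                nrow(cloud$points), min_cloud_size),
        cloud = cloud, class = c("sononav_small_cloud", "error", "condition")
      ))
    }
    mesh <- do.call(reconstruct_surface, c(list(cloud), recon_config))
  }
  list(cloud = cloud, mesh = mesh, n_contact = n_contact, n_rejected = n_rejected)
}

#' Surface mesh reconstruction from an acquired point cloud
#'
#' Tangent-plane signed-distance reconstruction in the spirit of Hoppe's
#' method, specialised to the open, graph-like patches a liver surface scan
#' produces: the cloud's PCA base plane provides a parameterisation, local
#' weighted tangent planes are fitted around each node of a regular grid in
#' that plane, and the zero-crossing of the signed distance along the base
#' normal gives the node height. Grid cells whose nodes have no nearby
#' support are dropped, so disjoint sweep segments are not bridged.
#'
#' @param cloud a `point_cloud3d` (or n x 3 matrix).
#' @param grid_mm grid spacing in the base plane (default 2 mm).
#' @param k_fit number of nearest cloud points per node fit (default 12).
#' @param max_gap_mm nodes farther than this from their nearest cloud point
#'   are dropped (default 6 mm).
#' @param extrapolation_limit_mm nodes whose fitting neighbourhood is
#'   one-sided — the centroid of the supporting points lies farther than this
#'   from the node — are dropped rather than extrapolated (default
#'   `1.75 * grid_mm`); this trims the footprint's corners instead of bending
#'   tangent planes past the data.
#' @param min_points minimum cloud size (default 50).
#' @return A `triangle_mesh`, oriented with normals toward the cloud's
#'   outward (+z-most) side.
#' @export
reconstruct_surface <- function(cloud, grid_mm = 2, k_fit = 12L,
                                max_gap_mm = 6,
                                extrapolation_limit_mm = 1.75 * grid_mm,
                                min_points = 50L) {
  P <- if (inherits(cloud, "point_cloud3d")) cloud$points else as.matrix(cloud)
  n <- nrow(P)
  if (n < min_points) stop(sprintf("need at least %d points (got %d)", min_points, n))
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  sv <- svd(Pc, nu = 0)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1)) {
    stop("degenerate cloud: points are collinear or coincident")
  }
  V <- sv$v
  w <- V[, 3]
  if (w[3] < 0) w <- -w                      # orient toward +z when possible
  uax <- V[, 1]; vax <- cross3(w, uax)

  U <- Pc %*% cbind(uax, vax)                # base-plane coordinates
  Hh <- drop(Pc %*% w)                       # heights along the base normal

  gu <- seq(min(U[, 1]), max(U[, 1]), by = grid_mm)
  gv <- seq(min(U[, 2]), max(U[, 2]), by = grid_mm)
  if (length(gu) < 2 || length(gv) < 2) stop("cloud extent smaller than the grid spacing")
  nu <- length(gu); nv <- length(gv)
  height <- matrix(NA_real_, nu, nv)
  k_fit <- min(k_fit, n)

  for (j in seq_len(nv)) {
    dv2 <- (U[, 2] - gv[j])^2
    for (i in seq_len(nu)) {
      d2 <- (U[, 1] - gu[i])^2 + dv2
      ord <- order(d2)[seq_len(k_fit)]
      if (sqrt(d2[ord[1]]) > max_gap_mm) next
      du <- U[ord, 1] - gu[i]; dvv <- U[ord, 2] - gv[j]
      # one-sided support means the node lies outside the sampled patch
      if (sqrt(mean(du)^2 + mean(dvv)^2) > extrapolation_limit_mm) next
      hh <- Hh[ord]
      h_band <- max(stats::median(sqrt(d2[ord])), grid_mm / 2)
      wt <- exp(-d2[ord] / (2 * h_band^2))
      # weighted linear tangent plane h(u, v); its value at the node is the
      # zero-crossing of the local signed distance along the base normal
      X <- cbind(1, du, dvv)
      A <- crossprod(X * wt, X)
      b <- crossprod(X * wt, hh)
      coef <- tryCatch(solve(A, b), error = function(e) NULL)
      height[i, j] <- if (is.null(coef)) sum(wt * hh) / sum(wt) else coef[1]
    }
  }

  active <- !is.na(height)
  vid <- matrix(0L, nu, nv)
  vid[active] <- seq_len(sum(active))
  gi <- rep(seq_len(nu), times = nv)[active]
  gj <- rep(seq_len(nv), each = nu)[active]
  base <- cbind(gu[gi], gv[gj])
  verts <- sweep(base[, 1, drop = FALSE] %*% t(uax) +
                 base[, 2, drop = FALSE] %*% t(vax) +
                 height[active] %*% t(w), 2, ctr, "+")

  faces <- list()
  for (j in seq_len(nv - 1)) {
    for (i in seq_len(nu - 1)) {
      a <- vid[i, j]; b <- vid[i + 1, j]; cc <- vid[i, j + 1]; d <- vid[i + 1, j + 1]
      if (a && b && d && cc) {
        faces[[length(faces) + 1L]] <- rbind(c(a, b, d), c(a, d, cc))
      }
    }
  }
  if (length(faces) == 0) stop("no connected grid cells; cloud too sparse for this grid")
  triangle_mesh(verts, do.call(rbind, faces), drop_degenerate = TRUE)
}
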