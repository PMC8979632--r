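#' Synthetic liver phantom with full ground truth
#'
#' Generates every input the planning pipeline consumes: a smooth liver-like
#' heightfield surface, embedded spherical tumor mimics (hyperechoic on
#' speckle), tracked B-mode sweeps with contact/no-contact states and pose
#' noise, and post-resection specimen meshes. Defaults emulate the ex-vivo
#' conditions the method was evaluated under: tumor diameters drawn from
#' N(12.1, 2.5) mm truncated above 4 mm, tumor centres 10-20 mm below the
#' local surface, lesions brighter than the speckle background.
#'
#' Rendering is appearance-level (multiplicative Rayleigh speckle, lesion
#' contrast, mild depth attenuation), not a wave-propagation simulation: the
#' pipeline consumes intensity statistics and contours only.
#'
#' @name synthetic-phantom
NULL

#' Phantom configuration
#'
#' @param seed RNG seed; every generator is deterministic given it.
#' @param domain_mm x/y extent of the phantom, centred on the origin.
#' @param surface_amplitude_mm heightfield amplitude (mm).
#' @param surface_smoothness_mm correlation length of the heightfield (mm).
#' @param n_tumors number of tumor mimics.
#' @param tumor_diameter_mean_mm,tumor_diameter_sd_mm diameter distribution
#'   (normal, truncated below at `tumor_diameter_min_mm`).
#' @param tumor_diameter_min_mm truncation bound (mm).
#' @param tumor_depth_range_mm tumor-centre depth below the local surface
#'   (uniform; default 10-20 mm).
#' @param tumor_clearance_mm minimum surface-to-surface clearance between
#'   tumors (rejection sampling).
#' @param pixel_spacing_mm mm per pixel (lateral, depth).
#' @param image_size_px image width x height in pixels (default 300 x 250,
#'   i.e. a 60 x 50 mm field at 0.2 mm/px).
#' @param speckle_mean mean background intensity of contact frames (default
#'   70, low enough that hyperechoic lesions up to ~2.5x contrast stay within
#'   the 8-bit range without saturation biasing their mean).
#' @param lesion_contrast lesion-to-background mean intensity ratio.
#' @param attenuation_per_mm depth attenuation coefficient (1/mm).
#' @param sensor_noise_sd additive sensor noise in no-contact frames.
#' @param sweep list of sweep parameters: `region` (xmin, xmax, ymin, ymax;
#'   NULL = auto around the tumors), `n_frames`, `n_rows` (serpentine raster
#'   rows), `pose_noise_mm`, `pose_noise_deg`, `no_contact_fraction`,
#'   `no_contact_block`, `outlier_frames`, `outlier_jump_mm`, `lift_mm`.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(seed = 1L,
                           domain_mm = c(120, 120),
                           surface_amplitude_mm = 4,
                           surface_smoothness_mm = 45,
                           n_tumors = 2L,
                           tumor_diameter_mean_mm = 12.1,
                           tumor_diameter_sd_mm = 2.5,
                           tumor_diameter_min_mm = 4,
                           tumor_depth_range_mm = c(10, 20),
                           tumor_clearance_mm = 10,
                           pixel_spacing_mm = c(0.2, 0.2),
                           image_size_px = c(300L, 250L),
                           speckle_mean = 70,
                           lesion_contrast = 2.0,
                           attenuation_per_mm = 0.004,
                           sensor_noise_sd = 4,
                           sweep = list()) {
  sw <- utils::modifyList(list(
    region = NULL, n_frames = 500L, n_rows = 8L,
    pose_noise_mm = 0.2, pose_noise_deg = 0.2,
    no_contact_fraction = 0, no_contact_block = 8L,
    outlier_frames = integer(0), outlier_jump_mm = 50,
    lift_mm = 20
  ), sweep)
  cfg <- list(seed = as.integer(seed), domain_mm = domain_mm,
              surface_amplitude_mm = surface_amplitude_mm,
              surface_smoothness_mm = surface_smoothness_mm,
              n_tumors = as.integer(n_tumors),
              tumor_diameter_mean_mm = tumor_diameter_mean_mm,
              tumor_diameter_sd_mm = tumor_diameter_sd_mm,
              tumor_diameter_min_mm = tumor_diameter_min_mm,
              tumor_depth_range_mm = tumor_depth_range_mm,
              tumor_clearance_mm = tumor_clearance_mm,
              pixel_spacing_mm = pixel_spacing_mm,
              image_size_px = as.integer(image_size_px),
              speckle_mean = speckle_mean,
              lesion_contrast = lesion_contrast,
              attenuation_per_mm = attenuation_per_mm,
              sensor_noise_sd = sensor_noise_sd,
              sweep = sw)
  stopifnot(cfg$tumor_diameter_min_mm > 0, all(cfg$tumor_depth_range_mm > 0),
            sw$n_frames >= 1)
  structure(cfg, class = "phantom_config")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Sample tumor diameters from the configured distribution
#'
#' Normal with the configured mean/sd, rejection-truncated below the minimum
#' diameter.
#'
#' @param n number of draws.
#' @param config a `phantom_config`.
#' @return Numeric vector of diameters (mm).
#' @export
sample_tumor_diameters <- function(n, config = phantom_config()) {
  out <- numeric(0)
  while (length(out) < n) {
    d <- stats::rnorm(n, config$tumor_diameter_mean_mm, config$tumor_diameter_sd_mm)
    out <- c(out, d[d > config$tumor_diameter_min_mm])
  }
  out[seq_len(n)]
}

#' Evaluate the phantom surface height
#'
#' @param gt a `phantom_ground_truth`.
#' @param x,y coordinates (mm), recycled.
#' @return Heights z (mm).
#' @export
surface_height <- function(gt, x, y) {
  cf <- gt$surface_coefs
  z <- rep(0, length(x))
  for (i in seq_len(nrow(cf))) {
    z <- z + cf$amp[i] * cos(2 * pi * (cf$fx[i] * x + cf$fy[i] * y) + cf$phase[i])
  }
  z
}

#' Generate a phantom with ground truth
#'
#' Deterministic given `config$seed`. The surface is a smooth random cosine
#' heightfield; tumors are spheres sampled from the configured diameter and
#' depth distributions with rejection to keep pairwise clearance.
#'
#' @param config a `phantom_config`.
#' @return A `phantom_ground_truth`: config, surface coefficients, surface
#'   mesh, and a data.frame `tumors` with columns cx, cy, cz, diameter_mm,
#'   depth_mm.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, {
    n_comp <- 8L
    f0 <- 1 / config$surface_smoothness_mm
    ang <- stats::runif(n_comp, 0, 2 * pi)
    fmag <- f0 * stats::runif(n_comp, 0.4, 1.0)
    cf <- data.frame(
      fx = fmag * cos(ang), fy = fmag * sin(ang),
      amp = config$surface_amplitude_mm * abs(stats::rnorm(n_comp)) / n_comp * 2,
      phase = stats::runif(n_comp, 0, 2 * pi)
    )
    gt <- structure(list(config = config, surface_coefs = cf), class = "phantom_ground_truth")

    hx <- config$domain_mm[1] / 2; hy <- config$domain_mm[2] / 2
    gx <- seq(-hx, hx, by = 2)
    gy <- seq(-hy, hy, by = 2)
    Z <- outer(gx, gy, function(a, b) surface_height(gt, a, b))
    gt$surface_mesh <- mesh_heightfield(gx, gy, Z)

    tumors <- data.frame()
    tries <- 0L
    while (nrow(tumors) < config$n_tumors) {
      tries <- tries + 1L
      if (tries > 200L * config$n_tumors) {
        stop(sprintf("could not place %d tumors with %g mm clearance; try fewer tumors",
                     config$n_tumors, config$tumor_clearance_mm))
      }
      d <- sample_tumor_diameters(1, config)
      cx <- stats::runif(1, -hx * 0.5, hx * 0.5)
      cy <- stats::runif(1, -hy * 0.5, hy * 0.5)
      depth <- stats::runif(1, config$tumor_depth_range_mm[1], config$tumor_depth_range_mm[2])
      cz <- surface_height(gt, cx, cy) - depth
      if (nrow(tumors) > 0) {
        gap <- sqrt((tumors$cx - cx)^2 + (tumors$cy - cy)^2 + (tumors$cz - cz)^2) -
          (tumors$diameter_mm + d) / 2
        if (any(gap < config$tumor_clearance_mm)) next
      }
      tumors <- rbind(tumors, data.frame(cx = cx, cy = cy, cz = cz,
                                         diameter_mm = d, depth_mm = depth))
    }
    gt$tumors <- tumors
    gt
  })
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("<phantom_ground_truth> %d tumors, surface %s\n",
              nrow(x$tumors), format(x$surface_mesh)[1]))
  invisible(x)
}

# rotation of the probe at a raster position: image x -> world +y (lateral),
# image y -> world -z (depth), image z -> world -x
probe_rotation <- function() {
  cbind(c(0, 1, 0), c(0, 0, -1), c(-1, 0, 0))
}

#' Probe pose touching a given surface point
#'
#' Builds the world-from-US-image transform that places the image's top-row
#' midpoint pixel at the 3D point `s`, with the image lateral axis along
#' world +y and depth pointing down (-z) — the orientation the simulated
#' sweeps use.
#'
#' @param s length-3 surface point (mm).
#' @param calib a `probe_calibration`.
#' @param image_size_px image width x height in pixels.
#' @return A `rigid_transform` (world_T_us).
#' @export
probe_pose_at <- function(s, calib, image_size_px) {
  R <- probe_rotation()
  top_mid <- c(image_size_px[1] / 2 * calib$pixel_spacing_mm[1], 0, 0)
  rigid_from_rt(R, s - as.numeric(R %*% top_mid))
}

small_rotation <- function(sd_deg) {
  if (sd_deg <= 0) return(diag(3))
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, sd_deg * pi / 180)
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Render a B-mode-like frame of the phantom
#'
#' Multiplicative Rayleigh speckle around the configured mean, lesion pixels
#' (sphere-plane intersection) brightened by the contrast ratio, mild
#' depth-dependent attenuation. No-contact frames render a dark upper band
#' with sensor noise over a dim deep region.
#'
#' @param gt a `phantom_ground_truth`.
#' @param world_t_us `rigid_transform` placing the US image frame in the
#'   world (image x lateral, y depth, plane z = 0).
#' @param config a `phantom_config` (defaults to the phantom's own).
#' @param contact render a contact frame (TRUE) or a lifted/no-contact frame.
#' @return list `image` (H x W intensity matrix in `[0, 255]`) and `mask`
#'   (H x W logical lesion ground truth; all-FALSE when no tumor is cut).
#' @export
render_bmode <- function(gt, world_t_us, config = gt$config, contact = TRUE) {
  W <- config$image_size_px[1]; H <- config$image_size_px[2]
  sp <- config$pixel_spacing_mm
  # pixel centres in image mm coordinates
  px <- rep(seq_len(W) - 1L, each = H)
  py <- rep(seq_len(H) - 1L, times = W)
  n <- W * H
  mask <- rep(FALSE, n)

  if (contact) {
    coords <- cbind(px * sp[1], py * sp[2], 0)
    world <- transform_points(world_t_us, coords)
    level <- rep(config$speckle_mean, n)
    for (i in seq_len(nrow(gt$tumors))) {
      tu <- gt$tumors[i, ]
      d2 <- (world[, 1] - tu$cx)^2 + (world[, 2] - tu$cy)^2 + (world[, 3] - tu$cz)^2
      inside <- d2 <= (tu$diameter_mm / 2)^2
      level[inside] <- level[inside] * config$lesion_contrast
      mask <- mask | inside
    }
    level <- level * exp(-config$attenuation_per_mm * py * sp[2])
    speckle <- sqrt(-2 * log(stats::runif(n)))     # Rayleigh, sigma = 1
    img <- level * speckle / sqrt(pi / 2)
  } else {
    img <- rep(0, n)
    band <- py < floor(H / 3)
    img[band] <- abs(stats::rnorm(sum(band), 0, config$sensor_noise_sd))
    img[!band] <- config$speckle_mean * 0.25 *
      sqrt(-2 * log(stats::runif(sum(!band)))) / sqrt(pi / 2)
  }
  img <- pmin(pmax(img, 0), 255)
  list(image = matrix(img, nrow = H, ncol = W),
       mask = matrix(mask, nrow = H, ncol = W))
}

#' Simulate a tracked serpentine sweep over the phantom surface
#'
#' The probe glides along a serpentine raster; on contact frames the top-row
#' midpoint of the image touches the surface. Scheduled no-contact frames
#' lift the probe. Recorded (tracked) poses carry the configured pose noise;
#' the true poses and true contact labels are returned alongside.
#'
#' @param gt a `phantom_ground_truth`.
#' @param config a `phantom_config` (defaults to the phantom's own).
#' @param calib optional `probe_calibration` (default: identity `ms_t_us`
#'   with the config's pixel spacing).
#' @return list with `frames` (list of `tracked_frame`, poses = noisy
#'   tracking), `contact` (logical ground truth), `true_poses` (list of
#'   world_T_us `rigid_transform`), `masks` (lesion ground-truth matrices or
#'   NULL), `calib`.
#' @export
simulate_sweep <- function(gt, config = gt$config, calib = NULL) {
  stopifnot(inherits(gt, "phantom_ground_truth"))
  sw <- config$sweep
  if (is.null(calib)) {
    calib <- probe_calibration(rigid_identity(), config$pixel_spacing_mm)
  }
  region <- sw$region
  if (is.null(region)) {
    tu <- gt$tumors
    region <- c(min(tu$cx) - 20, max(tu$cx) + 20, min(tu$cy) - 12, max(tu$cy) + 12)
  }
  hx <- config$domain_mm[1] / 2; hy <- config$domain_mm[2] / 2
  if (region[1] < -hx || region[2] > hx || region[3] < -hy || region[4] > hy) {
    stop("sweep path leaves the phantom bounds")
  }
  n <- sw$n_frames
  rows <- sw$n_rows
  ys <- seq(region[3], region[4], length.out = rows)
  per <- diff(round(seq(0, n, length.out = rows + 1)))
  xs_dir <- 1
  path <- NULL
  for (r in seq_len(rows)) {
    xr <- seq(region[1], region[2], length.out = per[r])
    if (xs_dir < 0) xr <- rev(xr)
    path <- rbind(path, cbind(xr, ys[r]))
    xs_dir <- -xs_dir
  }
  contact <- rep(TRUE, n)
  if (sw$no_contact_fraction > 0) {
    n_nc <- round(n * sw$no_contact_fraction)
    blk <- max(1L, as.integer(sw$no_contact_block))
    n_blocks <- ceiling(n_nc / blk)
    starts <- round(seq(1, n - blk + 1, length.out = n_blocks + 2))[2:(n_blocks + 1)]
    idx <- unique(unlist(lapply(starts, function(s) s + seq_len(blk) - 1L)))
    idx <- idx[idx <= n][seq_len(min(n_nc, length(idx)))]
    contact[idx] <- FALSE
  }

  with_seed(config$seed + 1L, {
    frames <- vector("list", n)
    true_poses <- vector("list", n)
    masks <- vector("list", n)
    for (i in seq_len(n)) {
      xy <- path[i, ]
      s <- c(xy[1], xy[2], surface_height(gt, xy[1], xy[2]))
      if (!contact[i]) s[3] <- s[3] + sw$lift_mm
      pose_true <- probe_pose_at(s, calib, config$image_size_px)
      rb <- render_bmode(gt, pose_true, config, contact = contact[i])
      # tracking noise on the recorded pose
      dR <- small_rotation(sw$pose_noise_deg)
      dt <- stats::rnorm(3, 0, sw$pose_noise_mm)
      m <- pose_true$matrix
      m[1:3, 1:3] <- dR %*% m[1:3, 1:3]
      m[1:3, 4] <- m[1:3, 4] + dt
      if (i %in% sw$outlier_frames) {
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        m[1:3, 4] <- m[1:3, 4] + dir * sw$outlier_jump_mm
      }
      pose_rec <- rigid_transform(m)
      c_t_ms <- compose(pose_rec, rigid_invert(calib$ms_t_us))
      frames[[i]] <- tracked_frame(rb$image, c_t_ms, index = i - 1L)
      true_poses[[i]] <- pose_true
      masks[[i]] <- if (any(rb$mask)) rb$mask else NULL
    }
    list(frames = frames, contact = contact, true_poses = true_poses,
         masks = masks, calib = calib, path = path)
  })
}

#' Training frames for the contact classifier
#'
#' Renders balanced contact / no-contact frames at random raster positions
#' and returns their feature rows and labels.
#'
#' @param gt a `phantom_ground_truth`.
#' @param n total number of frames (half per class).
#' @param config a `phantom_config`.
#' @param seed RNG seed.
#' @return list `features` (n x 5 matrix), `labels` (character).
#' @export
phantom_training_set <- function(gt, n = 400L, config = gt$config, seed = 99L) {
  with_seed(seed, {
    n_c <- n %/% 2L; n_n <- n - n_c
    lab <- c(rep("contact", n_c), rep("no_contact", n_n))
    hx <- config$domain_mm[1] / 2 * 0.8; hy <- config$domain_mm[2] / 2 * 0.8
    calib <- probe_calibration(rigid_identity(), config$pixel_spacing_mm)
    feats <- matrix(NA_real_, n, 5, dimnames = list(NULL, FEATURE_NAMES))
    for (i in seq_len(n)) {
      x <- stats::runif(1, -hx, hx); y <- stats::runif(1, -hy, hy)
      s <- c(x, y, surface_height(gt, x, y))
      is_contact <- lab[i] == "contact"
      if (!is_contact) s[3] <- s[3] + config$sweep$lift_mm
      pose <- probe_pose_at(s, calib, config$image_size_px)
      rb <- render_bmode(gt, pose, config, contact = is_contact)
      feats[i, ] <- extract_contact_features(rb$image)
    }
    list(features = feats, labels = lab)
  })
}

#' Simulate executing a resection plan on the phantom
#'
#' Carves the specimen enclosed by the (optionally noise-perturbed) cone and
#' the phantom surface and returns it with the true tumor mesh, ready for
#' [measure_margin()]. Execution noise displaces the lateral cut surface
#' along its outward normal by a smooth random field (Gaussian-filtered white
#' noise on the cut parameterisation) of the given standard deviation,
#' mimicking coherent surgical deviation rather than vertex jitter. Noise
#' large enough to cut into the tumor is not an error: margin analysis will
#' simply report R1.
#'
#' @param gt a `phantom_ground_truth`.
#' @param plan a `resection_plan` (see [fit_resection_shape()]).
#' @param execution_noise_mm sd of the cut-surface displacement field (mm).
#' @param tumor_index which phantom tumor the plan targets (default 1).
#' @param n_theta,n_axial cut-surface mesh resolution.
#' @param noise_smooth_cells Gaussian smoothing radius of the noise field, in
#'   grid cells (default 3).
#' @param seed RNG seed for the noise field (default the phantom's).
#' @return list of `triangle_mesh`es: `tumor`, `specimen` (closed), and
#'   `cut_surface` (the resection surface alone — apex and lateral wall,
#'   without the capsule-side cap).
#' @export
simulate_resection <- function(gt, plan, execution_noise_mm = 0,
                               tumor_index = 1L, n_theta = 64L, n_axial = 28L,
                               noise_smooth_cells = 3, seed = gt$config$seed + 7L) {
  stopifnot(inherits(gt, "phantom_ground_truth"), inherits(plan, "resection_plan"))
  tu <- gt$tumors[tumor_index, ]
  tumor_mesh <- mesh_uv_sphere(c(tu$cx, tu$cy, tu$cz), tu$diameter_mm / 2,
                               n_theta = 64L, n_phi = 32L)

  a <- plan$apex; u <- plan$axis; alpha <- plan$half_angle
  e1 <- pick_perp(u); e2 <- cross3(u, e1)
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  # per-azimuth surface hit of the cone generator
  t_surf <- vapply(theta, function(th) {
    d <- u * cos(alpha) + (e1 * cos(th) + e2 * sin(th)) * sin(alpha)
    ray_surface_hit(gt, a, d)
  }, numeric(1))

  # smooth noise field on the (axial ring, azimuth) parameterisation
  noise <- matrix(0, n_axial, n_theta)
  if (execution_noise_mm > 0) {
    noise <- with_seed(seed, {
      w <- matrix(stats::rnorm(n_axial * n_theta), n_axial, n_theta)
      sm <- smooth_field(w, noise_smooth_cells)
      sm * (execution_noise_mm / stats::sd(as.numeric(sm)))
    })
  }

  verts <- matrix(a, 1, 3)                      # vertex 1 = apex
  ring_id <- matrix(0L, n_axial, n_theta)
  nv <- 1L
  for (k in seq_len(n_axial)) {
    s_frac <- k / n_axial
    ring <- matrix(NA_real_, n_theta, 3)
    for (j in seq_len(n_theta)) {
      th <- theta[j]
      ev <- e1 * cos(th) + e2 * sin(th)
      d <- u * cos(alpha) + ev * sin(alpha)
      p <- a + d * (s_frac * t_surf[j])
      nrm <- ev * cos(alpha) - u * sin(alpha)   # outward lateral normal
      p <- p + nrm * noise[k, j] * min(1, s_frac / 0.2)  # blend to 0 at the apex
      if (k == n_axial) p[3] <- surface_height(gt, p[1], p[2])  # rim on surface
      ring[j, ] <- p
    }
    verts <- rbind(verts, ring)
    ring_id[k, ] <- nv + seq_len(n_theta)
    nv <- nv + n_theta
  }

  # top cap: radial spokes from the axis-surface point to the rim, on the surface
  t_c <- ray_surface_hit(gt, a, u)
  c0 <- a + u * t_c
  c0[3] <- surface_height(gt, c0[1], c0[2])
  cap_rings <- 8L
  cap_id <- matrix(0L, cap_rings - 1L, n_theta)
  rim <- verts[ring_id[n_axial, ], , drop = FALSE]
  for (m in seq_len(cap_rings - 1L)) {
    rho <- m / cap_rings
    xy <- cbind(c0[1] + rho * (rim[, 1] - c0[1]), c0[2] + rho * (rim[, 2] - c0[2]))
    ring <- cbind(xy, surface_height(gt, xy[, 1], xy[, 2]))
    verts <- rbind(verts, ring)
    cap_id[m, ] <- nv + seq_len(n_theta)
    nv <- nv + n_theta
  }
  verts <- rbind(verts, c0)
  center_id <- nv + 1L

  nxt <- c(seq_len(n_theta)[-1], 1L)
  faces <- list(cbind(1L, ring_id[1, ], ring_id[1, nxt]))          # apex fan
  for (k in seq_len(n_axial - 1L)) {
    aR <- ring_id[k, ]; bR <- ring_id[k + 1L, ]
    faces[[length(faces) + 1L]] <- cbind(aR, bR, bR[nxt])
    faces[[length(faces) + 1L]] <- cbind(aR, bR[nxt], aR[nxt])
  }
  cap_seq <- rbind(ring_id[n_axial, ], cap_id)                      # rim inward
  for (m in seq_len(nrow(cap_seq) - 1L)) {
    aR <- cap_seq[m, ]; bR <- cap_seq[m + 1L, ]
    faces[[length(faces) + 1L]] <- cbind(aR, bR, bR[nxt])
    faces[[length(faces) + 1L]] <- cbind(aR, bR[nxt], aR[nxt])
  }
  inner <- cap_seq[nrow(cap_seq), ]
  faces[[length(faces) + 1L]] <- cbind(center_id, inner[nxt], inner)

  specimen <- triangle_mesh(verts, do.call(rbind, faces), drop_degenerate = TRUE)
  # the resection (cut) surface alone: apex fan + lateral wall, no liver cap
  n_wall <- 1L + 2L * (n_axial - 1L)
  cut_faces <- do.call(rbind, faces[seq_len(n_wall)])
  cut_surface <- triangle_mesh(verts, cut_faces, drop_degenerate = TRUE)
  list(tumor = tumor_mesh, specimen = specimen, cut_surface = cut_surface)
}

# first t > 0 where a + t*d crosses the heightfield (z - surface = 0)
ray_surface_hit <- function(gt, a, d) {
  f <- function(t) {
    p <- a + t * d
    p[3] - surface_height(gt, p[1], p[2])
  }
  t_hi <- 1
  while (f(t_hi) < 0 && t_hi < 1e4) t_hi <- t_hi * 2
  if (f(t_hi) < 0) stop("cone generator does not reach the phantom surface")
  lo <- 0; hi <- t_hi
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Gaussian smoothing, circular in both dimensions (azimuth wraps; the axial
# wrap is harmless for a smooth field)
smooth_field <- function(w, sigma) {
  if (sigma <= 0) return(w)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), 0, sigma)
  k <- k / sum(k)
  circ <- function(m, kv) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(kv)) {
      sh <- o - half - 1L
      out <- out + kv[o] * m[((seq_len(n) - 1L + sh) %% n) + 1L, , drop = FALSE]
    }
    out
  }
  t(circ(t(circ(w, k)), k))
}

pick_perp <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- cross3(u, v)
  w / sqrt(sum(w^2))
}
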