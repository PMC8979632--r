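#' Rigid transforms, probe calibration and tracked frames
#'
#' The navigation chain works in homogeneous 4x4 matrices throughout:
#' `p_world = C_T_MS %*% MS_T_US %*% T_scale %*% p_pixel`, where `C_T_MS` is
#' the per-frame camera-to-marker-shield pose, `MS_T_US` the fixed probe
#' calibration, and `T_scale` the pixel-spacing scaling into mm. All 3D
#' coordinates are millimetres; the camera frame is right-handed.
#'
#' Image convention: pixel (0,0) is the top-left corner, +x runs rightward
#' (lateral), +y runs downward (axial/depth), and the image plane is z = 0
#' in the US frame.
#'
#' @name geometry-tracking
NULL

RIGID_TOL <- 1e-9

#' Construct a validated rigid transform
#'
#' @param matrix A 4x4 homogeneous transform. The 3x3 rotation block must be
#'   orthonormal with determinant +1 (tolerance 1e-9) and the last row must
#'   be (0, 0, 0, 1). Translation is in mm.
#' @return An object of class `rigid_transform` wrapping the matrix.
#' @export
rigid_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (!is.numeric(m) || any(dim(m) != c(4L, 4L)) || any(!is.finite(m))) {
    stop("rigid transform must be a finite numeric 4x4 matrix")
  }
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > RIGID_TOL) {
    stop("invalid rigid transform: last row must be (0, 0, 0, 1)")
  }
  R <- m[1:3, 1:3]
  ortho_err <- max(abs(crossprod(R) - diag(3)))
  if (ortho_err > RIGID_TOL) {
    stop(sprintf(
      "invalid rigid transform: rotation block not orthonormal (max |R'R - I| = %.3g)",
      ortho_err
    ))
  }
  if (abs(det(R) - 1) > RIGID_TOL) {
    stop(sprintf(
      "invalid rigid transform: rotation block determinant %.12f != +1 (reflection?)",
      det(R)
    ))
  }
  structure(list(matrix = m), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform> (mm)\n")
  print(x$matrix, ...)
  invisible(x)
}

#' Identity rigid transform
#' @return The identity `rigid_transform`.
#' @export
rigid_identity <- function() rigid_transform(diag(4))

#' Build a rigid transform from rotation and translation
#'
#' @param rotation 3x3 rotation matrix (default identity).
#' @param translation length-3 translation in mm (default zero).
#' @export
rigid_from_rt <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation
  m[1:3, 4] <- translation
  rigid_transform(m)
}

#' Rotation about a coordinate axis
#'
#' @param axis one of "x", "y", "z".
#' @param angle rotation angle in radians (right-handed).
#' @export
rotation_about <- function(axis = c("x", "y", "z"), angle) {
  axis <- match.arg(axis)
  c_ <- cos(angle); s_ <- sin(angle)
  R <- switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1))
  )
  rigid_from_rt(R)
}

#' Compose two rigid transforms
#'
#' `compose(a, b)` applies `b` first, then `a`: the result's matrix is
#' `a$matrix %*% b$matrix`, mirroring the chained matrix product of the
#' navigation pipeline.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  m <- a$matrix %*% b$matrix
  # re-orthonormalisation is deliberately NOT performed; accumulated error is
  # checked against the rigidity tolerance instead
  rigid_transform(m)
}

#' Invert a rigid transform
#' @param a A `rigid_transform`.
#' @export
rigid_invert <- function(a) {
  stopifnot(inherits(a, "rigid_transform"))
  R <- a$matrix[1:3, 1:3]
  t <- a$matrix[1:3, 4]
  m <- diag(4)
  m[1:3, 1:3] <- t(R)
  m[1:3, 4] <- -t(R) %*% t
  rigid_transform(m)
}

#' Apply a rigid transform to 3D points
#'
#' @param a A `rigid_transform`.
#' @param pts numeric vector of length 3 or an n x 3 matrix (mm).
#' @return Points of the same shape, transformed.
#' @export
transform_points <- function(a, pts) {
  stopifnot(inherits(a, "rigid_transform"))
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, nrow = 1) else as.matrix(pts)
  stopifnot(ncol(p) == 3)
  out <- p %*% t(a$matrix[1:3, 1:3])
  out <- sweep(out, 2, a$matrix[1:3, 4], "+")
  if (single) drop(out) else out
}

#' Probe calibration
#'
#' Holds the fixed marker-shield-to-US-image rigid transform and the pixel
#' spacing. The calibration itself is an input (estimated preoperatively with
#' a z-wire phantom on the physical system); it is never estimated here.
#'
#' @param ms_t_us `rigid_transform` from the US image frame into the marker
#'   shield frame.
#' @param pixel_spacing_mm length-2 numeric, mm per pixel along image x
#'   (lateral) and y (depth); both strictly positive.
#' @export
probe_calibration <- function(ms_t_us = rigid_identity(),
                              pixel_spacing_mm = c(0.2, 0.2)) {
  stopifnot(inherits(ms_t_us, "rigid_transform"))
  sp <- as.numeric(pixel_spacing_mm)
  if (length(sp) != 2 || any(!is.finite(sp)) || any(sp <= 0)) {
    stop("pixel_spacing_mm must be two strictly positive numbers (mm/px)")
  }
  structure(list(ms_t_us = ms_t_us, pixel_spacing_mm = sp),
            class = "probe_calibration")
}

#' A tracked B-mode frame
#'
#' @param image numeric matrix of intensities in `[0, 255]`; rows are image
#'   y (depth), columns image x (lateral).
#' @param c_t_ms `rigid_transform`: camera-to-marker-shield pose of the frame.
#' @param index non-negative integer sequence number within the stream.
#' @export
tracked_frame <- function(image, c_t_ms = rigid_identity(), index = 0L) {
  img <- as.matrix(image)
  if (!is.numeric(img) || length(img) == 0) stop("frame image must be a non-empty numeric matrix")
  stopifnot(inherits(c_t_ms, "rigid_transform"))
  if (index < 0) stop("frame index must be non-negative")
  structure(list(image = img, c_t_ms = c_t_ms, index = as.integer(index)),
            class = "tracked_frame")
}

#' Map an image pixel to a 3D camera-frame point
#'
#' Scales the pixel by the calibration's pixel spacing into mm in the US
#' plane (z = 0 there), then applies `ms_t_us` and the frame pose `c_t_ms`.
#'
#' @param frame A `tracked_frame`.
#' @param calib A `probe_calibration`.
#' @param px length-2 pixel coordinate `(x, y)`, 0-based, or an n x 2 matrix.
#' @param check_bounds error if the pixel falls outside the image (default TRUE).
#' @return 3D point (mm) in the camera frame, or an n x 3 matrix.
#' @export
pixel_to_world <- function(frame, calib, px, check_bounds = TRUE) {
  stopifnot(inherits(frame, "tracked_frame"), inherits(calib, "probe_calibration"))
  single <- is.null(dim(px))
  p <- if (single) matrix(px, nrow = 1) else as.matrix(px)
  stopifnot(ncol(p) == 2)
  if (check_bounds) {
    w <- ncol(frame$image); h <- nrow(frame$image)
    bad <- p[, 1] < 0 | p[, 1] > w - 1 | p[, 2] < 0 | p[, 2] > h - 1
    if (any(bad)) {
      stop(sprintf("pixel (%g, %g) outside image bounds %d x %d",
                   p[which(bad)[1], 1], p[which(bad)[1], 2], w, h))
    }
  }
  sp <- calib$pixel_spacing_mm
  us_mm <- cbind(p[, 1] * sp[1], p[, 2] * sp[2], 0)
  chain <- compose(frame$c_t_ms, calib$ms_t_us)
  out <- transform_points(chain, us_mm)
  if (single) drop(out) else out
}

#' Map a 3D camera-frame point back to frame pixels
#'
#' Inverse of [pixel_to_world()] for points on (or near) the image plane; the
#' returned pixel coordinates are continuous and the residual out-of-plane
#' offset is returned as the `z_mm` attribute.
#'
#' @inheritParams pixel_to_world
#' @param pts 3D point or n x 3 matrix in the camera frame (mm).
#' @return n x 2 matrix (or length-2 vector) of pixel coordinates with
#'   attribute `z_mm`, the signed out-of-plane distances in mm.
#' @export
world_to_pixel <- function(frame, calib, pts) {
  stopifnot(inherits(frame, "tracked_frame"), inherits(calib, "probe_calibration"))
  single <- is.null(dim(pts))
  p <- if (single) matrix(pts, nrow = 1) else as.matrix(pts)
  chain_inv <- rigid_invert(compose(frame$c_t_ms, calib$ms_t_us))
  us <- transform_points(chain_inv, p)
  us <- if (is.null(dim(us))) matrix(us, nrow = 1) else us
  sp <- calib$pixel_spacing_mm
  px <- cbind(us[, 1] / sp[1], us[, 2] / sp[2])
  z <- us[, 3]
  out <- if (single) drop(px) else px
  attr(out, "z_mm") <- if (single) unname(z) else z
  out
}

#' The 3D plane of a tracked frame
#'
#' @inheritParams pixel_to_world
#' @return A list with `origin` (world position of pixel (0,0)), unit in-plane
#'   axes `ax` (image +x) and `ay` (image +y), and unit `normal = ax x ay`,
#'   all in mm / unitless directions in the camera frame.
#' @export
frame_plane <- function(frame, calib) {
  stopifnot(inherits(frame, "tracked_frame"), inherits(calib, "probe_calibration"))
  sp <- calib$pixel_spacing_mm
  if (any(sp <= 0)) stop("degenerate pixel spacing")
  chain <- compose(frame$c_t_ms, calib$ms_t_us)
  R <- chain$matrix[1:3, 1:3]
  origin <- transform_points(chain, c(0, 0, 0))
  ax <- R[, 1]
  ay <- R[, 2]
  list(origin = origin, ax = ax, ay = ay, normal = cross3(ax, ay))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Read / write pose logs
#'
#' Pose logs are CSV with columns `index, r00..r23` — the row-major 3x4 upper
#' block of each frame's camera-to-marker-shield transform — or JSON with
#' nested 4x4 arrays under `poses`.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return A list of `rigid_transform`, named by frame index.
#' @export
read_pose_log <- function(path) {
  if (!file.exists(path)) stop(sprintf("pose log not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    mats <- doc$poses
    if (is.null(mats)) stop("JSON pose log must contain a 'poses' array")
    if (is.array(mats) && length(dim(mats)) == 3) {
      out <- lapply(seq_len(dim(mats)[1]), function(i) rigid_transform(mats[i, , ]))
    } else {
      out <- lapply(mats, function(m) rigid_transform(do.call(rbind, lapply(m, unlist))))
    }
    names(out) <- as.character(doc$index %||% (seq_along(out) - 1L))
    return(out)
  }
  df <- utils::read.csv(path)
  need <- c("index", paste0("r", rep(0:2, each = 4), rep(0:3, 3)))
  if (!all(need %in% names(df))) {
    stop("pose CSV must have columns index, r00..r23 (row-major 3x4)")
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    m <- rbind(matrix(as.numeric(df[i, need[-1]]), nrow = 3, byrow = TRUE),
               c(0, 0, 0, 1))
    rigid_transform(m)
  })
  names(out) <- as.character(df$index)
  out
}

#' @rdname read_pose_log
#' @param poses list of `rigid_transform`.
#' @param indices integer frame indices (default 0-based sequence).
#' @export
write_pose_log <- function(poses, path, indices = seq_along(poses) - 1L) {
  rows <- t(vapply(poses, function(p) as.numeric(t(p$matrix[1:3, ])), numeric(12)))
  df <- data.frame(index = indices, rows)
  names(df) <- c("index", paste0("r", rep(0:2, each = 4), rep(0:3, 3)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe calibration YAML
#'
#' The YAML holds `ms_t_us` as a 4x4 nested list and `pixel_spacing_mm` as
#' `[sx, sy]`. Conventions: pixel (0,0) top-left, +x lateral, +y depth,
#' image plane z = 0; millimetres throughout.
#'
#' @param path YAML file path.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop(sprintf("calibration file not found: %s", path))
  doc <- yaml::read_yaml(path)
  m <- do.call(rbind, lapply(doc$ms_t_us, function(r) as.numeric(unlist(r))))
  probe_calibration(rigid_transform(m), as.numeric(doc$pixel_spacing_mm))
}

#' @rdname read_calibration
#' @param calib A `probe_calibration`.
#' @export
write_calibration <- function(calib, path) {
  # numbers are serialised at full precision (YAML writers round otherwise,
  # which breaks the rotation-orthonormality tolerance on re-read)
  fmt <- function(x) sprintf("%.17g", x)
  doc <- list(
    ms_t_us = lapply(seq_len(4), function(i) fmt(calib$ms_t_us$matrix[i, ])),
    pixel_spacing_mm = fmt(calib$pixel_spacing_mm)
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
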