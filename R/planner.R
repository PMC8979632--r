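#' Conical resection planning around a safety margin
#'
#' The tumor (a sphere from the single-slice segmentation) is inflated by the
#' chosen safety margin; a cone is fitted so that its boundary keeps at least
#' that margin from the tumor everywhere. The cone's axis points from the
#' tumor centre to the closest point on the liver surface (the shortest way
#' out), its apex sits on the axis below the tumor, and the resection line —
#' the curve the surgeon starts cutting along — is the intersection of the
#' cone's lateral surface with the liver surface mesh.
#'
#' Apex rule: with half-angle `alpha`, the distance from a point on the axis
#' to the lateral surface is `d * sin(alpha)` at axial distance `d`, so the
#' apex is placed `max((r + m) / sin(alpha), r + m + clearance)` below the
#' tumor centre (tumor radius `r`, margin `m`): the first term makes the
#' lateral wall exactly tangent to the margin sphere, the second keeps a
#' configurable depth clearance below it.
#'
#' @name resection-planner
NULL

#' Spherical tumor model
#'
#' @param center length-3 centre (mm, camera/world frame).
#' @param diameter_mm sphere diameter (mm), > 0.
#' @export
tumor_model <- function(center, diameter_mm) {
  stopifnot(length(center) == 3, all(is.finite(center)), diameter_mm > 0)
  structure(list(center = as.numeric(center), diameter_mm = diameter_mm),
            class = "tumor_model")
}

#' @export
print.tumor_model <- function(x, ...) {
  cat(sprintf("<tumor_model> centre (%.1f, %.1f, %.1f) mm, diameter %.1f mm\n",
              x$center[1], x$center[2], x$center[3], x$diameter_mm))
  invisible(x)
}

#' Fit the conical resection shape
#'
#' @param tumor a `tumor_model`.
#' @param surface liver surface `triangle_mesh` (oriented, normals away from
#'   the parenchyma).
#' @param margin_mm safety margin (mm, >= 0; 10 mm is the common choice for
#'   primary liver cancer).
#' @param half_angle_deg cone half-angle in degrees, in (0, 90) (default 45).
#' @param depth_clearance_mm extra apex depth below the margin sphere
#'   (default 2 mm).
#' @param line_config list passed on to [resection_line()].
#' @return An object of class `resection_plan`: `apex`, unit `axis`
#'   (apex-to-surface direction), `half_angle` (radians), `depth_mm` (apex
#'   distance below the tumor centre), `safety_margin_mm`, `resection_line`
#'   (closed 3D polyline, one row per vertex), `closest_surface_point`.
#' @export
fit_resection_shape <- function(tumor, surface, margin_mm,
                                half_angle_deg = 45, depth_clearance_mm = 2,
                                line_config = list()) {
  stopifnot(inherits(tumor, "tumor_model"), inherits(surface, "triangle_mesh"))
  if (margin_mm < 0) stop("margin_mm must be >= 0")
  alpha <- half_angle_deg * pi / 180
  if (!(alpha > 0 && alpha < pi / 2)) {
    stop("half_angle_deg must lie strictly between 0 and 90 degrees")
  }
  r <- tumor$diameter_mm / 2

  nn <- point_mesh_distance(tumor$center, surface, details = TRUE)
  cp <- nn$closest[1, ]
  f <- surface$faces[nn$face[1], ]
  fn <- cross3(surface$vertices[f[2], ] - surface$vertices[f[1], ],
               surface$vertices[f[3], ] - surface$vertices[f[1], ])
  fn <- fn / sqrt(sum(fn^2))
  to_surface <- cp - tumor$center
  if (sum(to_surface * fn) <= 0) {
    stop("tumor centre is above or outside the liver surface")
  }
  if (nn$dist[1] <= r) {
    stop("tumor sphere breaches the liver surface; no interior cone exists")
  }
  axis <- to_surface / sqrt(sum(to_surface^2))

  depth <- max((r + margin_mm) / sin(alpha), r + margin_mm + depth_clearance_mm)
  apex <- tumor$center - axis * depth

  plan <- structure(list(
    shape = "cone",
    apex = apex, axis = axis, half_angle = alpha,
    depth_mm = depth, safety_margin_mm = margin_mm,
    tumor = tumor, closest_surface_point = cp,
    resection_line = NULL
  ), class = "resection_plan")

  # feasibility audit: axial point at distance `depth` has lateral clearance
  # depth*sin(alpha); the margin must survive minus the tumor radius
  lateral <- depth * sin(alpha) - r
  apex_clear <- depth - r
  if (min(lateral, apex_clear) < margin_mm - 1e-6) {
    min_alpha <- asin((r + margin_mm) / depth) * 180 / pi
    stop(sprintf("cone cannot achieve a %g mm margin; minimal feasible half-angle ~ %.1f deg",
                 margin_mm, min_alpha))
  }

  plan$resection_line <- do.call(resection_line, c(list(plan, surface), line_config))
  plan
}

#' @export
print.resection_plan <- function(x, ...) {
  cat(sprintf("<resection_plan> cone, half-angle %.1f deg, apex depth %.1f mm, margin %g mm, line with %d vertices\n",
              x$half_angle * 180 / pi, x$depth_mm, x$safety_margin_mm,
              if (is.null(x$resection_line)) 0L else nrow(x$resection_line)))
  invisible(x)
}

# signed cone implicit: negative inside the (upward, one-sided) cone
cone_implicit <- function(plan, pts) {
  P <- if (is.null(dim(pts))) matrix(pts, nrow = 1) else as.matrix(pts)
  v <- sweep(P, 2, plan$apex)
  t_ax <- drop(v %*% plan$axis)
  r_perp <- sqrt(pmax(rowSums(v^2) - t_ax^2, 0))
  ifelse(t_ax > 0, r_perp - t_ax * tan(plan$half_angle),
         sqrt(rowSums(v^2)))          # below the apex: everything is outside
}

#' Resection line: cone boundary intersected with the liver surface
#'
#' Marches over the mesh edges that cross the cone's lateral surface, orders
#' the crossing points by azimuth about the cone axis, and (optionally)
#' refines the closed polyline to a maximum segment length by inserting
#' points projected back onto the cone and the mesh.
#'
#' @param plan a `resection_plan`.
#' @param surface liver `triangle_mesh`.
#' @param max_segment_mm refine the polyline until no segment exceeds this
#'   (default 1 mm; NULL keeps the raw edge crossings).
#' @return Closed polyline as an n x 3 matrix (consecutive vertices; last
#'   connects back to first).
#' @export
resection_line <- function(plan, surface, max_segment_mm = 1) {
  stopifnot(inherits(plan, "resection_plan"), inherits(surface, "triangle_mesh"))
  v <- surface$vertices; f <- surface$faces
  g <- cone_implicit(plan, v)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  cross_e <- which(g[e[, 1]] * g[e[, 2]] < 0)
  if (length(cross_e) == 0) stop("cone does not intersect the surface mesh")

  pts <- matrix(NA_real_, length(cross_e), 3)
  for (i in seq_along(cross_e)) {
    a <- v[e[cross_e[i], 1], ]; b <- v[e[cross_e[i], 2], ]
    ga <- g[e[cross_e[i], 1]]
    lo <- 0; hi <- 1
    for (it in 1:40) {                      # bisection on the segment
      mid <- (lo + hi) / 2
      gm <- cone_implicit(plan, a + mid * (b - a))
      if ((gm < 0) == (ga < 0)) lo <- mid else hi <- mid
    }
    pts[i, ] <- a + (lo + hi) / 2 * (b - a)
  }

  e1 <- pick_perp(plan$axis); e2 <- cross3(plan$axis, e1)
  rel <- sweep(pts, 2, plan$apex)
  az <- atan2(rel %*% e2, rel %*% e1)
  pts <- pts[order(az), , drop = FALSE]

  if (!is.null(max_segment_mm)) {
    pts <- refine_polyline(pts, plan, surface, max_segment_mm)
  }
  pts
}

refine_polyline <- function(pts, plan, surface, max_seg) {
  out <- list()
  n <- nrow(pts)
  tan_a <- tan(plan$half_angle)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[if (i == n) 1L else i + 1L, ]
    out[[length(out) + 1L]] <- a
    len <- sqrt(sum((b - a)^2))
    if (len > max_seg) {
      n_ins <- ceiling(len / max_seg) - 1L
      for (j in seq_len(n_ins)) {
        p <- a + (b - a) * j / (n_ins + 1)
        # project onto the cone lateral surface (radially, fixed azimuth)
        vv <- p - plan$apex
        t_ax <- sum(vv * plan$axis)
        rad <- vv - t_ax * plan$axis
        rn <- sqrt(sum(rad^2))
        if (rn > 1e-12 && t_ax > 0) p <- plan$apex + t_ax * plan$axis + rad * (t_ax * tan_a / rn)
        # then back onto the mesh
        p <- point_mesh_distance(p, surface, details = TRUE)$closest[1, ]
        out[[length(out) + 1L]] <- p
      }
    }
  }
  do.call(rbind, out)
}

#' Project plan structures onto a US frame as 2D overlay contours
#'
#' Each 3D structure is intersected with the frame's image plane and the
#' planar curves are mapped to pixel coordinates through the inverse
#' calibration chain: the tumor and margin spheres give circles (possibly
#' empty), the cone gives a conic arc, and resection-line vertices close to
#' the plane give point marks. Contours are clipped to the image bounds;
#' every structure is independently toggleable and empty intersections keep
#' their visibility flag.
#'
#' @param plan a `resection_plan`.
#' @param tumor a `tumor_model` (default: the plan's).
#' @param frame a `tracked_frame`.
#' @param calib a `probe_calibration`.
#' @param show named logical vector toggling `tumor`, `margin`, `shape`,
#'   `line`.
#' @param line_band_mm half-thickness around the plane within which
#'   resection-line vertices become marks (default 1 mm).
#' @return An object of class `overlay_projection`: list `contours` (each an
#'   n x 2 pixel matrix) and logical `visible`.
#' @export
project_overlay <- function(plan, tumor = plan$tumor, frame, calib,
                            show = c(tumor = TRUE, margin = TRUE,
                                     shape = TRUE, line = TRUE),
                            line_band_mm = 1) {
  pl <- frame_plane(frame, calib)
  w <- ncol(frame$image); h <- nrow(frame$image)

  to_px <- function(pts3) {
    if (is.null(pts3) || nrow(pts3) == 0) return(matrix(numeric(0), ncol = 2))
    px <- world_to_pixel(frame, calib, pts3)
    px <- matrix(px, ncol = 2)
    keep <- px[, 1] >= 0 & px[, 1] <= w - 1 & px[, 2] >= 0 & px[, 2] <= h - 1
    px[keep, , drop = FALSE]
  }

  sphere_slice <- function(center, radius, n = 90) {
    d <- sum((center - pl$origin) * pl$normal)
    if (abs(d) >= radius) return(matrix(numeric(0), ncol = 2))
    c_in <- center - d * pl$normal
    rr <- sqrt(radius^2 - d^2)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    to_px(t(sapply(th, function(a) c_in + rr * (cos(a) * pl$ax + sin(a) * pl$ay))))
  }

  cone_slice <- function(n = 240) {
    e1 <- pick_perp(plan$axis); e2 <- cross3(plan$axis, e1)
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    t_lim <- cone_extent_by_azimuth(plan, th)
    pts <- matrix(NA_real_, 0, 3)
    for (i in seq_along(th)) {
      d <- plan$axis * cos(plan$half_angle) +
        (e1 * cos(th[i]) + e2 * sin(th[i])) * sin(plan$half_angle)
      dn <- sum(d * pl$normal)
      if (abs(dn) < 1e-12) next
      t_star <- sum((pl$origin - plan$apex) * pl$normal) / dn
      if (t_star > 0 && t_star <= t_lim[i]) {
        pts <- rbind(pts, plan$apex + t_star * d)
      }
    }
    to_px(pts)
  }

  r <- tumor$diameter_mm / 2
  contours <- list(
    tumor = if (show[["tumor"]]) sphere_slice(tumor$center, r) else matrix(numeric(0), ncol = 2),
    margin = if (show[["margin"]]) sphere_slice(tumor$center, r + plan$safety_margin_mm) else matrix(numeric(0), ncol = 2),
    shape = if (show[["shape"]]) cone_slice() else matrix(numeric(0), ncol = 2),
    line = if (show[["line"]] && !is.null(plan$resection_line)) {
      lp <- plan$resection_line
      dist_pl <- abs(sweep(lp, 2, pl$origin) %*% pl$normal)
      to_px(lp[dist_pl <= line_band_mm, , drop = FALSE])
    } else matrix(numeric(0), ncol = 2)
  )
  structure(list(contours = contours, visible = show), class = "overlay_projection")
}

# per-azimuth generator length: to the resection line if present, else a
# generous multiple of the apex depth
cone_extent_by_azimuth <- function(plan, theta) {
  if (is.null(plan$resection_line)) {
    return(rep(2.5 * plan$depth_mm / cos(plan$half_angle), length(theta)))
  }
  e1 <- pick_perp(plan$axis); e2 <- cross3(plan$axis, e1)
  rel <- sweep(plan$resection_line, 2, plan$apex)
  az <- atan2(rel %*% e2, rel %*% e1)
  t_gen <- sqrt(rowSums(rel^2))            # distance apex -> line vertex
  ord <- order(az)
  stats::approx(x = c(az[ord] - 2 * pi, az[ord], az[ord] + 2 * pi),
                y = rep(t_gen[ord], 3),
                xout = theta, rule = 2, ties = mean)$y * 1.02
}

#' @export
print.overlay_projection <- function(x, ...) {
  n <- vapply(x$contours, nrow, integer(1))
  cat("<overlay_projection>", paste(sprintf("%s: %d px", names(n), n), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise / restore a resection plan as JSON
#'
#' @param plan a `resection_plan`.
#' @param path JSON path.
#' @export
write_plan <- function(plan, path) {
  doc <- list(
    format = "sononav-resection-plan", shape = plan$shape,
    apex = plan$apex, axis = plan$axis,
    half_angle_deg = plan$half_angle * 180 / pi,
    depth_mm = plan$depth_mm, margin_mm = plan$safety_margin_mm,
    tumor = list(center = plan$tumor$center, diameter_mm = plan$tumor$diameter_mm),
    closest_surface_point = plan$closest_surface_point,
    resection_line = if (!is.null(plan$resection_line)) {
      apply(plan$resection_line, 1, as.numeric, simplify = FALSE)
    }
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sononav-resection-plan")) stop("not a resection-plan file")
  line <- doc$resection_line
  if (!is.null(line) && !is.matrix(line)) line <- do.call(rbind, line)
  structure(list(
    shape = doc$shape, apex = as.numeric(doc$apex), axis = as.numeric(doc$axis),
    half_angle = doc$half_angle_deg * pi / 180,
    depth_mm = doc$depth_mm, safety_margin_mm = doc$margin_mm,
    tumor = tumor_model(as.numeric(doc$tumor$center), doc$tumor$diameter_mm),
    closest_surface_point = as.numeric(doc$closest_surface_point),
    resection_line = line
  ), class = "resection_plan")
}

#' @rdname write_plan
#' @param tumor a `tumor_model`.
#' @export
write_tumor_model <- function(tumor, path) {
  jsonlite::write_json(list(format = "sononav-tumor-model",
                            center = tumor$center,
                            diameter_mm = tumor$diameter_mm),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_tumor_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  tumor_model(as.numeric(doc$center), doc$diameter_mm)
}
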