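#' Triangle meshes in millimetres
#'
#' Shared geometry container for the liver surface, tumor and resection
#' specimen. Faces are 1-based vertex-index triples; degenerate (zero-area)
#' faces are rejected (or dropped on request) so downstream distance and
#' intersection code never divides by a zero edge.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param drop_degenerate drop faces with area <= 1e-12 mm^2 instead of
#'   erroring (default FALSE).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, drop_degenerate = FALSE) {
  v <- as.matrix(vertices)
  f <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(v) != 3 || any(!is.finite(v))) stop("vertices must be a finite n x 3 matrix")
  if (nrow(f) > 0 && (min(f) < 1 || max(f) > nrow(v))) stop("face indices out of range")
  if (nrow(f) > 0) {
    ar <- face_areas(v, f)
    bad <- ar <= 1e-12
    if (any(bad)) {
      if (drop_degenerate) f <- f[!bad, , drop = FALSE]
      else stop(sprintf("%d degenerate (zero-area) face(s); pass drop_degenerate = TRUE to drop", sum(bad)))
    }
  }
  structure(list(vertices = v, faces = f), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces (mm)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

face_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' UV-sphere mesh
#'
#' @param center length-3 centre (mm).
#' @param radius sphere radius (mm).
#' @param n_theta longitudinal segments (default 48).
#' @param n_phi latitudinal segments pole-to-pole (default 24).
#' @return A `triangle_mesh` with outward-oriented faces.
#' @export
mesh_uv_sphere <- function(center, radius, n_theta = 48L, n_phi = 24L) {
  stopifnot(radius > 0, n_theta >= 3, n_phi >= 2)
  phi <- seq(0, pi, length.out = n_phi + 1)      # 0 = +z pole
  theta <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  ring_ids <- vector("list", n_phi + 1)
  verts <- matrix(numeric(0), ncol = 3)
  nv <- 0L
  for (i in seq_along(phi)) {
    if (i == 1 || i == n_phi + 1) {
      z <- if (i == 1) radius else -radius
      verts <- rbind(verts, center + c(0, 0, z))
      nv <- nv + 1L
      ring_ids[[i]] <- nv
    } else {
      r <- radius * sin(phi[i]); z <- radius * cos(phi[i])
      ring <- cbind(center[1] + r * cos(theta), center[2] + r * sin(theta), center[3] + z)
      verts <- rbind(verts, ring)
      ring_ids[[i]] <- nv + seq_len(n_theta)
      nv <- nv + n_theta
    }
  }
  faces <- list()
  top <- ring_ids[[1]]; first <- ring_ids[[2]]
  nxt <- c(seq_len(n_theta)[-1], 1L)
  faces[[length(faces) + 1L]] <- cbind(top, first, first[nxt])
  for (i in 2:(n_phi - 1)) {
    a <- ring_ids[[i]]; b <- ring_ids[[i + 1]]
    faces[[length(faces) + 1L]] <- cbind(a, b, b[nxt])
    faces[[length(faces) + 1L]] <- cbind(a, b[nxt], a[nxt])
  }
  bot <- ring_ids[[n_phi + 1]]; last <- ring_ids[[n_phi]]
  faces[[length(faces) + 1L]] <- cbind(bot, last[nxt], last)
  triangle_mesh(verts, do.call(rbind, faces))
}

#' Heightfield grid mesh z = Z[x, y]
#'
#' @param x,y strictly increasing coordinate vectors (mm).
#' @param Z matrix of heights with `dim = c(length(x), length(y))` (mm).
#' @return A `triangle_mesh` oriented with normals toward +z.
#' @export
mesh_heightfield <- function(x, y, Z) {
  nx <- length(x); ny <- length(y)
  stopifnot(all(dim(Z) == c(nx, ny)), nx >= 2, ny >= 2)
  verts <- cbind(rep(x, times = ny), rep(y, each = nx), as.numeric(Z))
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1), times = ny - 1)
  j <- rep(seq_len(ny - 1), each = nx - 1)
  v00 <- idx(i, j); v10 <- idx(i + 1, j); v01 <- idx(i, j + 1); v11 <- idx(i + 1, j + 1)
  faces <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
  triangle_mesh(verts, faces, drop_degenerate = TRUE)
}

#' Subdivide a mesh until no edge exceeds a maximum length
#'
#' 1-to-4 midpoint subdivision with shared-edge vertex reuse; used to densify
#' a tumor mesh before margin sampling.
#'
#' @param mesh A `triangle_mesh`.
#' @param max_edge_mm maximum allowed edge length (mm).
#' @param max_rounds safety cap on subdivision rounds (default 8).
#' @export
densify_mesh <- function(mesh, max_edge_mm, max_rounds = 8L) {
  v <- mesh$vertices; f <- mesh$faces
  for (round in seq_len(max_rounds)) {
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    len <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
    if (max(len) <= max_edge_mm) break
    ekey <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    uk <- unique(ekey)
    mid_id <- match(ekey, uk) + nrow(v)
    ue <- e[match(uk, ekey), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    v <- rbind(v, mids)
    m <- nrow(f)
    m12 <- mid_id[seq_len(m)]
    m23 <- mid_id[m + seq_len(m)]
    m31 <- mid_id[2L * m + seq_len(m)]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(m12, f[, 2], m23),
               cbind(m31, m23, f[, 3]),
               cbind(m12, m23, m31))
  }
  triangle_mesh(v, f, drop_degenerate = TRUE)
}

# Closest point on each triangle (A, B, C as k x 3 matrices) to a single
# query point p. Returns list(dist2, points). Vectorised region-based
# closest-point-on-triangle.
closest_point_triangles <- function(p, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- sweep(-A, 2, p, "+")
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- sweep(-B, 2, p, "+")
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- sweep(-C, 2, p, "+")
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2

  k <- nrow(A)
  out <- matrix(NA_real_, k, 3)
  todo <- rep(TRUE, k)

  take <- function(cond, pts) {
    sel <- todo & cond
    if (any(sel)) {
      out[sel, ] <<- pts[sel, , drop = FALSE]
      todo[sel] <<- FALSE
    }
  }
  take(d1 <= 0 & d2 <= 0, A)                                   # vertex A
  take(d3 >= 0 & d4 <= d3, B)                                  # vertex B
  take(d6 >= 0 & d5 <= d6, C)                                  # vertex C
  tAB <- d1 / (d1 - d3)
  take(vc <= 0 & d1 >= 0 & d3 <= 0, A + ab * tAB)              # edge AB
  tAC <- d2 / (d2 - d6)
  take(vb <= 0 & d2 >= 0 & d6 <= 0, A + ac * tAC)              # edge AC
  tBC <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  take(va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0, B + (C - B) * tBC)  # edge BC
  if (any(todo)) {                                             # interior
    denom <- 1 / (va + vb + vc)
    v <- vb * denom; w <- vc * denom
    pts <- A + ab * v + ac * w
    out[todo, ] <- pts[todo, , drop = FALSE]
  }
  d2out <- rowSums(sweep(out, 2, p, "-")^2)
  list(dist2 = d2out, points = out)
}

#' Exact point-to-mesh distances
#'
#' For each query point, the exact distance to the closest point on any face
#' of the mesh. A vertex-distance lower bound prunes faces that cannot beat
#' the current best, so the search stays exact but fast on smooth meshes.
#'
#' @param points n x 3 matrix (or length-3 vector) of query points (mm).
#' @param mesh A `triangle_mesh`.
#' @param details if TRUE also return closest points and face indices
#'   (ties broken by lowest face index).
#' @return Numeric vector of distances (mm); with `details = TRUE` a list
#'   `dist`, `closest` (n x 3), `face` (integer).
#' @export
point_mesh_distance <- function(points, mesh, details = FALSE, chunk = 256L) {
  single <- is.null(dim(points))
  P <- if (single) matrix(points, nrow = 1) else as.matrix(points)
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0) stop("mesh has no faces")
  used <- sort(unique(as.integer(f)))
  if (length(used) < nrow(v)) {       # drop unreferenced vertices: the
    v <- v[used, , drop = FALSE]      # vertex-distance bound must come from
    f <- matrix(match(f, used), ncol = 3)  # face vertices only
  }
  A <- v[f[, 1], , drop = FALSE]
  B <- v[f[, 2], , drop = FALSE]
  C <- v[f[, 3], , drop = FALSE]
  # triangle diameter (longest edge) for the vertex-distance pruning bound:
  # every point of the face is within diam of each of its vertices
  diam <- sqrt(pmax(rowSums((B - A)^2), rowSums((C - A)^2), rowSums((C - B)^2)))
  n <- nrow(P)
  dist <- numeric(n)
  face <- integer(n)
  closest <- matrix(NA_real_, n, 3)
  v2 <- rowSums(v^2)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    Pc <- P[lo:hi, , drop = FALSE]
    D2 <- sweep(-2 * Pc %*% t(v), 2, v2, "+") + rowSums(Pc^2)
    D2[D2 < 0] <- 0
    ub <- sqrt(D2[cbind(seq_len(nrow(Pc)), max.col(-D2, ties.method = "first"))])
    Fmin <- sqrt(pmin(D2[, f[, 1], drop = FALSE],
                      D2[, f[, 2], drop = FALSE],
                      D2[, f[, 3], drop = FALSE]))
    for (i in seq_len(nrow(Pc))) {
      cand <- which(Fmin[i, ] <= ub[i] + diam + 1e-9)
      r <- closest_point_triangles(Pc[i, ], A[cand, , drop = FALSE],
                                   B[cand, , drop = FALSE], C[cand, , drop = FALSE])
      j <- which.min(r$dist2)       # first minimum -> lowest face index on ties
      gi <- lo + i - 1L
      dist[gi] <- sqrt(r$dist2[j])
      face[gi] <- cand[j]
      closest[gi, ] <- r$points[j, ]
    }
  }
  if (!details) return(dist)
  list(dist = dist, closest = closest, face = face)
}

#' Symmetric Hausdorff distance between two meshes
#'
#' Both meshes are densified to the given edge length and the maximum of the
#' two directed vertex-to-mesh distances is returned.
#'
#' @param a,b `triangle_mesh` objects.
#' @param max_edge_mm densification edge length (mm, default 1).
#' @export
hausdorff_mesh <- function(a, b, max_edge_mm = 1) {
  ad <- densify_mesh(a, max_edge_mm)
  bd <- densify_mesh(b, max_edge_mm)
  max(max(point_mesh_distance(ad$vertices, b)),
      max(point_mesh_distance(bd$vertices, a)))
}

#' 3D point cloud with per-point source frame traceability
#'
#' @param points n x 3 matrix (mm).
#' @param source_frame_indices integer vector parallel to `points`.
#' @export
point_cloud3d <- function(points, source_frame_indices = rep(NA_integer_, nrow(points))) {
  p <- as.matrix(points)
  if (ncol(p) != 3 || any(!is.finite(p))) stop("points must be a finite n x 3 matrix")
  if (length(source_frame_indices) != nrow(p)) {
    stop("source_frame_indices must parallel points")
  }
  structure(list(points = p, source_frame_indices = as.integer(source_frame_indices)),
            class = "point_cloud3d")
}

#' @export
print.point_cloud3d <- function(x, ...) {
  cat(sprintf("<point_cloud3d> %d points (mm)\n", nrow(x$points)))
  invisible(x)
}

#' Read / write ASCII PLY
#'
#' Writes a `triangle_mesh` (vertices + faces) or a `point_cloud3d` (points
#' with a `frame_index` scalar property). `read_ply` returns whichever the
#' file holds.
#'
#' @param x A `triangle_mesh` or `point_cloud3d`.
#' @param path file path.
#' @export
write_ply <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "triangle_mesh")) {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(x$vertices)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(x$faces)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(x$vertices, digits = 17, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, x$faces - 1L), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else if (inherits(x, "point_cloud3d")) {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(x$points)),
                 "property double x", "property double y", "property double z",
                 "property int frame_index", "end_header"), con)
    utils::write.table(cbind(format(x$points, digits = 17, scientific = TRUE, trim = TRUE),
                             x$source_frame_indices),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  } else stop("write_ply handles triangle_mesh or point_cloud3d")
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply") stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf_line <- grep("^element face", hdr, value = TRUE)
  nf <- if (length(nf_line)) as.integer(sub("element face ", "", nf_line)) else 0L
  has_idx <- any(grepl("property int frame_index", hdr))
  body <- lines[-seq_len(hdr_end)]
  vrows <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  if (nf > 0) {
    frows <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.numeric))
    triangle_mesh(vrows[, 1:3, drop = FALSE], frows[, 2:4, drop = FALSE] + 1L)
  } else if (has_idx) {
    point_cloud3d(vrows[, 1:3, drop = FALSE], as.integer(vrows[, 4]))
  } else {
    point_cloud3d(vrows[, 1:3, drop = FALSE])
  }
}

#' Write a triangle mesh as ASCII STL
#'
#' @param mesh A `triangle_mesh`.
#' @param path file path.
#' @export
write_stl <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / sqrt(rowSums(nrm^2))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid sononav", con)
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                 "  outer loop",
                 sprintf("    vertex %.9g %.9g %.9g",
                         v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                 "  endloop", "endfacet"), con)
  }
  writeLines("endsolid sononav", con)
  invisible(path)
}

#' @rdname write_stl
#' @export
read_stl <- function(path) {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  vv <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(s) as.numeric(s[2:4])))
  nf <- nrow(vv) / 3
  key <- apply(round(vv, 9), 1, paste, collapse = ",")
  uk <- unique(key)
  verts <- vv[match(uk, key), , drop = FALSE]
  faces <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  triangle_mesh(verts, faces, drop_degenerate = TRUE)
}
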