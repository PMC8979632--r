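#' Semi-automatic graph-cut tumor segmentation
#'
#' The tumor is segmented on a single frozen B-mode frame. The operator
#' supplies one click at the tumor centre and an approximate diameter; a disk
#' of that diameter is hard-labelled foreground, a surrounding annulus
#' ("probably foreground", default 20 mm wide) is left free, and everything
#' outside is background. A min-cut on the pixel grid minimises
#' `sum_p D_p(l_p) + sum_pq w_pq [l_p != l_q]`, where the data terms are
#' negative log-likelihoods under per-region intensity histograms and the
#' boundary term is a contrast-weighted Potts model. Over- or
#' under-segmentation is fixed by clicking the offending area; membership of
#' the click in the current mask decides automatically whether the area is
#' removed or added.
#'
#' @name tumor-segmentation
NULL

LBL_BG <- 0L; LBL_PROB_FG <- 1L; LBL_DEF_FG <- 2L; LBL_HARD_BG <- 3L

#' Seed for segmentation initialisation
#'
#' @param center_px length-2 pixel coordinate of the operator's centre click
#'   (0-based).
#' @param diameter_mm approximate tumor diameter (mm).
#' @param ring_margin_mm width of the "probably foreground" annulus
#'   (default 20 mm).
#' @export
seed_init <- function(center_px, diameter_mm, ring_margin_mm = 20) {
  stopifnot(length(center_px) == 2, diameter_mm > 0, ring_margin_mm > 0)
  structure(list(center_px = as.numeric(center_px), diameter_mm = diameter_mm,
                 ring_margin_mm = ring_margin_mm), class = "seed_init")
}

#' Initial label mask from a seed
#'
#' Pixels within `diameter_mm / 2` of the centre (converted to pixels via the
#' lateral pixel spacing) are definite foreground — at least the centre pixel
#' itself, for degenerate sub-pixel diameters. The annulus out to
#' `radius + ring_margin_mm` is probable foreground; the rest is background.
#'
#' @param image_dim `c(height, width)` in pixels.
#' @param seed a `seed_init`.
#' @param calib a `probe_calibration` (for the mm-to-pixel conversion).
#' @return An integer matrix of class `label_mask` (0 = background,
#'   1 = probable foreground, 2 = definite foreground, 3 = hard background
#'   added by refinement).
#' @export
init_labels <- function(image_dim, seed, calib) {
  H <- image_dim[1]; W <- image_dim[2]
  sx <- calib$pixel_spacing_mm[1]
  cx <- seed$center_px[1]; cy <- seed$center_px[2]
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1) {
    stop("seed circle lies outside the image")
  }
  r_fg <- (seed$diameter_mm / 2) / sx
  r_ring <- r_fg + seed$ring_margin_mm / sx
  px <- matrix(rep(seq_len(W) - 1L, each = H), H, W)
  py <- matrix(rep(seq_len(H) - 1L, times = W), H, W)
  d <- sqrt((px - cx)^2 + (py - cy)^2)
  lab <- matrix(LBL_BG, H, W)
  lab[d <= r_ring] <- LBL_PROB_FG
  lab[d <= r_fg] <- LBL_DEF_FG
  if (!any(lab == LBL_DEF_FG)) {
    lab[round(cy) + 1L, round(cx) + 1L] <- LBL_DEF_FG   # minimum one pixel
  }
  structure(lab, class = "label_mask", center_px = c(cx, cy))
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  kv <- stats::dnorm(seq(-half, half), 0, sigma)
  kv <- kv / sum(kv)
  pass <- function(m) {            # along rows, edge replication
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (o in seq_along(kv)) {
      sh <- o - half - 1L
      idx <- pmin(pmax(seq_len(n) + sh, 1L), n)
      out <- out + kv[o] * m[idx, , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(img))))
}

hist_model <- function(x, breaks, n_bins) {
  cnt <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  (cnt + 1) / (sum(cnt) + n_bins)          # Laplace smoothing
}

# data terms, n-link edges and capacities shared by the cut and the energy
build_cut_problem <- function(image, labels, lambda, n_bins, connectivity,
                              smooth_sigma_px, bg_mode, contrast_sigma = NULL) {
  H <- nrow(image); W <- ncol(image)
  img_s <- gaussian_blur(image, smooth_sigma_px)
  breaks <- seq(0, 255, length.out = n_bins + 1)
  breaks[n_bins + 1] <- Inf

  fg_px <- img_s[labels == LBL_DEF_FG]
  bg_px <- img_s[labels == LBL_BG | labels == LBL_HARD_BG]
  if (length(fg_px) == 0) stop("definite foreground region is empty")
  if (length(bg_px) == 0) stop("background region is empty")
  p_fg <- hist_model(fg_px, breaks, n_bins)
  p_bg <- hist_model(bg_px, breaks, n_bins)
  overlap <- sum(pmin(p_fg, p_bg))
  if (overlap >= 0.90) {
    warning(sprintf(
      "foreground and background intensity models nearly indistinguishable (overlap %.2f); result may be seed-driven",
      overlap))
  }

  bin <- findInterval(img_s, breaks, all.inside = TRUE)
  d_fg <- matrix(-log(p_fg)[bin], H, W)   # cost of labelling the pixel foreground
  d_bg <- matrix(-log(p_bg)[bin], H, W)   # cost of labelling it background
  hard_fg <- labels == LBL_DEF_FG
  hard_bg <- labels == LBL_HARD_BG
  if (bg_mode == "hard") hard_bg <- hard_bg | labels == LBL_BG

  id <- matrix(seq_len(H * W), H, W)
  pairs <- rbind(
    cbind(as.vector(id[-H, ]), as.vector(id[-1, ]), 1),
    cbind(as.vector(id[, -W]), as.vector(id[, -1]), 1)
  )
  if (connectivity == 8) {
    pairs <- rbind(pairs,
      cbind(as.vector(id[-H, -W]), as.vector(id[-1, -1]), sqrt(2)),
      cbind(as.vector(id[-1, -W]), as.vector(id[-H, -1]), sqrt(2)))
  }
  dI <- image[pairs[, 1]] - image[pairs[, 2]]
  if (is.null(contrast_sigma)) {
    contrast_sigma <- sqrt(mean(dI^2))
    if (contrast_sigma == 0) contrast_sigma <- 1
  }
  wgt <- lambda * exp(-dI^2 / (2 * contrast_sigma^2)) / pairs[, 3]

  list(H = H, W = W, d_fg = d_fg, d_bg = d_bg,
       hard_fg = hard_fg, hard_bg = hard_bg,
       pairs = pairs[, 1:2, drop = FALSE],
       wgt = wgt, overlap = overlap, INF = 1e9)
}

#' Graph-cut segmentation from an initial label mask
#'
#' @param image numeric intensity matrix (H x W).
#' @param labels a `label_mask` from [init_labels()] (possibly refined).
#' @param calib a `probe_calibration` (pixel spacing for the equivalent
#'   diameter).
#' @param lambda smoothness weight of the contrast-weighted Potts boundary
#'   term (default 8).
#' @param n_bins intensity-histogram bins for the region models (default 32).
#' @param connectivity 4 or 8 (default 8).
#' @param smooth_sigma_px Gaussian pre-smoothing of the intensities feeding
#'   the data terms, in pixels (default 1.5; 0 disables).
#' @param bg_mode "hard" pins pixels outside the probable-foreground ring to
#'   background (default); "soft" leaves them to their data terms.
#' @param component_filter keep only the connected component containing the
#'   seed centre (default TRUE); FALSE returns the raw minimum cut.
#' @return An object of class `segmentation_result`: logical `mask` (single
#'   connected component containing the seed), `center_px` (mask centroid),
#'   `equiv_diameter_mm` (circle of equal area via the pixel spacing),
#'   `energy`, plus the `labels` and configuration used (for refinement).
#' @export
graph_cut_segment <- function(image, labels, calib,
                              lambda = 8, n_bins = 32L, connectivity = 8L,
                              smooth_sigma_px = 1.5, bg_mode = c("hard", "soft"),
                              component_filter = TRUE) {
  bg_mode <- match.arg(bg_mode)
  image <- as.matrix(image)
  stopifnot(all(dim(image) == dim(labels)), all(is.finite(image)))
  prob <- build_cut_problem(image, labels, lambda, n_bins, connectivity,
                            smooth_sigma_px, bg_mode)
  H <- prob$H; W <- prob$W; npx <- H * W

  # hard-constrained pixels are merged into the terminals: only free pixels
  # become graph nodes, n-links to a merged pixel fold into the free pixel's
  # t-link, and no infinite capacity is ever needed
  hard_fg <- as.logical(prob$hard_fg)
  hard_bg <- as.logical(prob$hard_bg)
  free <- which(!hard_fg & !hard_bg)
  mask <- matrix(hard_fg, H, W)
  if (length(free) > 0) {
    fid <- integer(npx)
    fid[free] <- seq_along(free)
    nfree <- length(free)
    s <- nfree + 1L; t <- nfree + 2L

    # s -> p with the cost of labelling p background, p -> t with the cost
    # of labelling it foreground: cutting s->p puts p on the sink
    # (background) side and pays d_bg, and vice versa, so the min cut
    # minimises the labelling energy
    cap_s <- as.numeric(prob$d_bg)[free]
    cap_t <- as.numeric(prob$d_fg)[free]
    p1 <- prob$pairs[, 1]; p2 <- prob$pairs[, 2]
    f1 <- fid[p1] > 0; f2 <- fid[p2] > 0
    # free--hard_fg folds into the source t-link, free--hard_bg into sink
    sel <- f1 & hard_fg[p2]
    if (any(sel)) cap_s <- cap_s + unname(rowsum_vec(prob$wgt[sel], fid[p1[sel]], nfree))
    sel <- f2 & hard_fg[p1]
    if (any(sel)) cap_s <- cap_s + unname(rowsum_vec(prob$wgt[sel], fid[p2[sel]], nfree))
    sel <- f1 & hard_bg[p2]
    if (any(sel)) cap_t <- cap_t + unname(rowsum_vec(prob$wgt[sel], fid[p1[sel]], nfree))
    sel <- f2 & hard_bg[p1]
    if (any(sel)) cap_t <- cap_t + unname(rowsum_vec(prob$wgt[sel], fid[p2[sel]], nfree))

    both <- f1 & f2
    nl <- cbind(fid[p1[both]], fid[p2[both]])
    w_nl <- prob$wgt[both]
    edges <- rbind(cbind(rep(s, nfree), seq_len(nfree)),
                   cbind(seq_len(nfree), rep(t, nfree)),
                   nl, nl[, 2:1, drop = FALSE])
    # capacities are quantised to 2^-26 (exact in doubles, ~1.5e-8 per edge):
    # integral capacities let the max-flow solver take its fast path while
    # perturbing the optimum by far less than any data-term difference
    caps <- round(c(cap_s, cap_t, w_nl, w_nl) * 2^26)
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    fl <- igraph::max_flow(g, source = s, target = t, capacity = caps)
    fg_side <- as.integer(fl$partition1)
    if (!(s %in% fg_side)) fg_side <- as.integer(fl$partition2)
    mask[free[setdiff(fg_side, c(s, t))]] <- TRUE
  }

  # keep the connected component holding the seed centre
  if (component_filter) {
    ctr <- attr(labels, "center_px")
    if (is.null(ctr)) {
      w <- which(labels == LBL_DEF_FG, arr.ind = TRUE)
      ctr <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
    }
    comp <- EBImage::bwlabel(mask)
    seed_lab <- comp[round(ctr[2]) + 1L, round(ctr[1]) + 1L]
    if (seed_lab == 0) {
      w <- which(labels == LBL_DEF_FG & mask, arr.ind = TRUE)
      if (nrow(w) > 0) seed_lab <- comp[w[1, 1], w[1, 2]]
    }
    mask <- comp == seed_lab & mask
  }

  segmentation_result(mask, calib, labels = labels, image = image,
                      energy = labeling_energy(prob, mask),
                      config = list(lambda = lambda, n_bins = n_bins,
                                    connectivity = connectivity,
                                    smooth_sigma_px = smooth_sigma_px,
                                    bg_mode = bg_mode,
                                    component_filter = component_filter),
                      model_overlap = prob$overlap)
}

rowsum_vec <- function(x, group, n) {
  out <- numeric(n)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

labeling_energy <- function(prob, mask) {
  l <- as.logical(mask)
  e_data <- sum(prob$d_fg[l]) + sum(prob$d_bg[!l])
  e_hard <- prob$INF * (sum(prob$hard_fg & !l) + sum(prob$hard_bg & l))
  diff <- l[prob$pairs[, 1]] != l[prob$pairs[, 2]]
  e_data + e_hard + sum(prob$wgt[diff])
}

#' Energy of an arbitrary labelling under the segmentation model
#'
#' Exposes the exact objective the cut minimises, for auditing a returned
#' mask against alternative labellings.
#'
#' @inheritParams graph_cut_segment
#' @param mask logical matrix labelling (TRUE = foreground).
#' @return The scalar energy (hard-constraint violations cost 1e9 each).
#' @export
segmentation_energy <- function(image, labels, mask, lambda = 8, n_bins = 32L,
                                connectivity = 8L, smooth_sigma_px = 1.5,
                                bg_mode = c("hard", "soft")) {
  bg_mode <- match.arg(bg_mode)
  prob <- build_cut_problem(as.matrix(image), labels, lambda, n_bins,
                            connectivity, smooth_sigma_px, bg_mode)
  labeling_energy(prob, mask)
}

segmentation_result <- function(mask, calib, labels = NULL, image = NULL,
                                energy = NA_real_, config = NULL,
                                model_overlap = NA_real_) {
  if (!any(mask)) stop("empty segmentation mask")
  w <- which(mask, arr.ind = TRUE)
  center <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)     # (x, y), 0-based
  sp <- calib$pixel_spacing_mm
  area_mm2 <- sum(mask) * sp[1] * sp[2]
  structure(list(
    mask = mask,
    center_px = center,
    equiv_diameter_mm = 2 * sqrt(area_mm2 / pi),
    energy = energy,
    labels = labels, image = image, config = config,
    model_overlap = model_overlap, calib = calib
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d px, centre (%.1f, %.1f) px, equivalent diameter %.2f mm\n",
              sum(x$mask), x$center_px[1], x$center_px[2], x$equiv_diameter_mm))
  invisible(x)
}

#' Click-based refinement of a segmentation
#'
#' A click inside the current mask hard-labels a neighbourhood of the click
#' as background (the area is removed); a click outside hard-labels it as
#' definite foreground (added). The decision is exactly the click's
#' membership in the current mask; the cut is then re-run.
#'
#' @param image intensity matrix.
#' @param current the current `segmentation_result`.
#' @param click_px length-2 pixel coordinate of the correction click.
#' @param radius_mm neighbourhood radius of the re-seeded area (default 3 mm).
#' @param labels label mask to refine (default: the one in `current`).
#' @return A new `segmentation_result`.
#' @export
refine_click <- function(image, current, click_px, radius_mm = 3,
                         labels = current$labels) {
  stopifnot(inherits(current, "segmentation_result"))
  H <- nrow(image); W <- ncol(image)
  cx <- click_px[1]; cy <- click_px[2]
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1) stop("click outside image")
  sx <- current$calib$pixel_spacing_mm[1]
  r_px <- radius_mm / sx
  px <- matrix(rep(seq_len(W) - 1L, each = H), H, W)
  py <- matrix(rep(seq_len(H) - 1L, times = W), H, W)
  disk <- sqrt((px - cx)^2 + (py - cy)^2) <= r_px
  inside <- current$mask[round(cy) + 1L, round(cx) + 1L]
  labels[disk] <- if (inside) LBL_HARD_BG else LBL_DEF_FG
  cfg <- current$config
  graph_cut_segment(image, labels, current$calib,
                    lambda = cfg$lambda, n_bins = cfg$n_bins,
                    connectivity = cfg$connectivity,
                    smooth_sigma_px = cfg$smooth_sigma_px,
                    bg_mode = cfg$bg_mode,
                    component_filter = cfg$component_filter)
}

#' Lift a 2D segmentation into the 3D sphere tumor model
#'
#' The tumor is approximated from its single largest slice: the model centre
#' is the mask centroid mapped through the frame's pose and calibration, and
#' the diameter is the equivalent diameter of the mask. This single-slice
#' sphere approximation is deliberate; irregular tumors need multi-slice
#' segmentation, which is out of scope here.
#'
#' @param seg a `segmentation_result`.
#' @param frame the `tracked_frame` the segmentation was drawn on.
#' @param calib a `probe_calibration`.
#' @return A `tumor_model` (see [tumor_model()]).
#' @export
mask_to_tumor_model <- function(seg, frame, calib) {
  stopifnot(inherits(seg, "segmentation_result"))
  if (!any(seg$mask)) stop("empty segmentation mask")
  center <- pixel_to_world(frame, calib, seg$center_px)
  tumor_model(center, seg$equiv_diameter_mm)
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return Dice overlap in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Read / write binary masks as PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m > 0.5
}
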