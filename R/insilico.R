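#' One complete in-silico resection trial
#'
#' Runs the whole navigation workflow on a synthetic phantom — generate
#' anatomy, train the contact classifier on phantom frames, sweep the probe,
#' scan and reconstruct the surface, segment the tumor on the frame with the
#' largest lesion cross-section, lift it to the sphere model, fit the conical
#' resection plan, simulate executing the cut (optionally with execution
#' noise), and measure the achieved 3D margin. The operator is emulated
#' without ground-truth leakage: the seed click is the centroid of the lesion
#' visible in the chosen frame and the selected size is that lesion's
#' equivalent diameter rounded to the nearest millimetre.
#'
#' @param seed integer; drives every random component of the trial.
#' @param margin_mm planned safety margin (default 10 mm).
#' @param execution_noise_mm sd of the simulated cut deviation (default 0).
#' @param half_angle_deg cone half-angle (default 30; keeps the resection
#'   line inside a practical scan footprint).
#' @param n_frames sweep length (default 400).
#' @param image_size_px,pixel_spacing_mm imaging geometry for the trial
#'   (default 128 x 96 px at 0.5 mm/px, a 64 x 48 mm field).
#' @param n_train contact-classifier training frames (default 160).
#' @param measure_max_edge_mm tumor sampling density for the margin
#'   measurement (default 1 mm; halving it moves the minimum by well under
#'   0.1 mm on these smooth meshes).
#' @param keep_intermediates return the phantom, sweep, scan and plan objects
#'   too (default FALSE).
#' @return A list with `report` (`margin_report`), `planned_margin_mm`,
#'   `tumor_estimate` (`tumor_model`), `tumor_truth`, `dice` (segmentation
#'   overlap on the chosen frame), and optionally the intermediates.
#' @export
insilico_trial <- function(seed, margin_mm = 10, execution_noise_mm = 0,
                           half_angle_deg = 30, n_frames = 400L,
                           image_size_px = c(128L, 96L),
                           pixel_spacing_mm = c(0.5, 0.5),
                           n_train = 160L,
                           measure_max_edge_mm = 1.0,
                           keep_intermediates = FALSE) {
  cfg <- phantom_config(
    seed = seed, n_tumors = 1L,
    image_size_px = image_size_px, pixel_spacing_mm = pixel_spacing_mm,
    sweep = list(n_frames = n_frames, n_rows = 14L,
                 pose_noise_mm = 0.2, pose_noise_deg = 0.2)
  )
  gt <- generate_phantom(cfg)
  tu <- gt$tumors[1, ]
  # footprint large enough to contain the resection line of the fitted cone
  rim <- (tu$depth_mm + (tu$diameter_mm / 2 + margin_mm) /
            sin(half_angle_deg * pi / 180)) * tan(half_angle_deg * pi / 180) + 8
  cfg$sweep$region <- c(tu$cx - rim, tu$cx + rim, tu$cy - rim, tu$cy + rim)
  hx <- cfg$domain_mm[1] / 2
  cfg$sweep$region <- pmin(pmax(cfg$sweep$region, -hx + 1), hx - 1)

  tr <- phantom_training_set(gt, n = n_train, cfg, seed = seed + 1000L)
  model <- train_contact_model(tr$features, tr$labels, seed = seed)
  sw <- simulate_sweep(gt, cfg)
  scan <- scan_stream(sw$frames, sw$calib, model)

  # the operator freezes the frame showing the largest tumor cross-section
  areas <- vapply(sw$masks, function(m) if (is.null(m)) 0L else sum(m), integer(1))
  if (max(areas) == 0) stop("sweep never imaged the tumor; enlarge the sweep region")
  fi <- which.max(areas)
  frame <- sw$frames[[fi]]
  lesion <- sw$masks[[fi]]
  w <- which(lesion, arr.ind = TRUE)
  click <- c(mean(w[, 2]) - 1, mean(w[, 1]) - 1)
  approx_d <- max(1, round(2 * sqrt(sum(lesion) * prod(pixel_spacing_mm) / pi)))

  labels <- init_labels(dim(frame$image), seed_init(click, approx_d), sw$calib)
  seg <- graph_cut_segment(frame$image, labels, sw$calib)
  tumor_est <- mask_to_tumor_model(seg, frame, sw$calib)

  plan <- fit_resection_shape(tumor_est, scan$mesh, margin_mm,
                              half_angle_deg = half_angle_deg)
  cut <- simulate_resection(gt, plan, execution_noise_mm, seed = seed + 7L)
  report <- measure_margin(cut$tumor, cut$specimen,
                           max_edge_mm = measure_max_edge_mm,
                           cut_surface = cut$cut_surface)

  out <- list(
    report = report,
    planned_margin_mm = margin_mm,
    tumor_estimate = tumor_est,
    tumor_truth = tumor_model(c(tu$cx, tu$cy, tu$cz), tu$diameter_mm),
    dice = dice_coefficient(seg$mask, lesion)
  )
  if (keep_intermediates) {
    out <- c(out, list(gt = gt, config = cfg, sweep = sw, scan = scan,
                       segmentation = seg, plan = plan, cut = cut,
                       contact_model = model))
  }
  out
}
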