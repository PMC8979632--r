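#' Probe-contact classification from near-field intensity statistics
#'
#' During a surface scan only frames where the transducer has full contact
#' with the liver capsule may contribute surface points. Contact shows up in
#' the shallow part of the B-mode image: tissue speckle right at the
#' transducer face, versus a dark air/coupling gap when the probe is lifted.
#' Five order/shape statistics of the upper third of the image — minimum,
#' maximum, mean, standard deviation and kurtosis — feed a binary SVM.
#'
#' @name contact-classifier
NULL

#' Intensity features of the upper third of a frame
#'
#' Statistics are computed over rows `[0, floor(H/3))` (the shallow band
#' nearest the transducer). Kurtosis uses the excess (Fisher) convention, so
#' a normal-intensity patch scores 0; a zero-variance patch maps to 0 with a
#' warning rather than NaN, keeping train and predict consistent on
#' degenerate frames.
#'
#' @param image numeric matrix of intensities (rows = depth), height >= 3.
#' @return Named numeric vector `fmin, fmax, fmean, fstd, fkurtosis`.
#' @export
extract_contact_features <- function(image) {
  img <- as.matrix(image)
  if (length(img) == 0) stop("empty image")
  h <- nrow(img)
  if (h < 3) stop("image height must be >= 3 to take its upper third")
  band <- img[seq_len(h %/% 3L), , drop = FALSE]
  x <- as.numeric(band)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    warning("zero-variance upper band; kurtosis set to 0 by convention")
    kurt <- 0
  } else {
    n <- length(x)
    kurt <- mean((x - m)^4) / (sum((x - m)^2) / n)^2 - 3
  }
  c(fmin = min(x), fmax = max(x), fmean = m,
    fstd = if (is.na(s)) 0 else s, fkurtosis = kurt)
}

FEATURE_NAMES <- c("fmin", "fmax", "fmean", "fstd", "fkurtosis")

#' Train the contact SVM
#'
#' RBF-kernel SVM on standardised features (scaling is learned on the
#' training set and stored in the model so prediction applies the identical
#' transform).
#'
#' @param features matrix or data.frame with columns
#'   `fmin, fmax, fmean, fstd, fkurtosis` (one row per frame), e.g. rows from
#'   [extract_contact_features()].
#' @param labels character/factor vector of "contact" / "no_contact".
#' @param kernel SVM kernel (default "radial").
#' @param cost SVM regularisation constant (default 1).
#' @param gamma RBF width; default `1 / n_features`.
#' @param seed RNG seed recorded in the metadata; training itself is
#'   deterministic for a fixed input order.
#' @return An object of class `contact_model`.
#' @export
train_contact_model <- function(features, labels, kernel = "radial",
                                cost = 1, gamma = 1 / 5, seed = 1L) {
  X <- as.matrix(as.data.frame(features)[, FEATURE_NAMES])
  y <- factor(as.character(labels), levels = c("contact", "no_contact"))
  if (anyNA(y)) stop('labels must be "contact" or "no_contact"')
  if (nrow(X) != length(y)) stop("features and labels must have equal length")
  if (nlevels(droplevels(y)) < 2) {
    stop("training set must contain both contact and no_contact examples")
  }
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  sdev[sdev == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdev)
  set.seed(seed)
  fit <- e1071::svm(Xs, y, kernel = kernel, cost = cost, gamma = gamma,
                    scale = FALSE)
  structure(list(
    fit = fit,
    center = mu, scale = sdev,
    kernel = kernel, cost = cost, gamma = gamma,
    n_contact = sum(y == "contact"), n_no_contact = sum(y == "no_contact"),
    seed = seed, version = 1L
  ), class = "contact_model")
}

#' @export
print.contact_model <- function(x, ...) {
  cat(sprintf("<contact_model> %s SVM (cost %g, gamma %g), trained on %d contact / %d no_contact\n",
              x$kernel, x$cost, x$gamma, x$n_contact, x$n_no_contact))
  invisible(x)
}

#' Predict contact for a frame (or precomputed features)
#'
#' @param model A `contact_model`.
#' @param image numeric image matrix, or a named feature vector / matrix with
#'   the five feature columns.
#' @return "contact" or "no_contact" (vector if several feature rows given).
#' @export
predict_contact <- function(model, image) {
  if (!inherits(model, "contact_model")) stop("predict_contact needs a trained contact_model")
  feats <- if (is.matrix(image) && !all(FEATURE_NAMES %in% colnames(image))) {
    matrix(extract_contact_features(image), nrow = 1,
           dimnames = list(NULL, FEATURE_NAMES))
  } else if (is.null(dim(image))) {
    matrix(image[FEATURE_NAMES], nrow = 1, dimnames = list(NULL, FEATURE_NAMES))
  } else {
    as.matrix(image)[, FEATURE_NAMES, drop = FALSE]
  }
  Xs <- scale(feats, center = model$center, scale = model$scale)
  if (!is.null(model$fit)) {
    out <- as.character(stats::predict(model$fit, Xs))
  } else {
    # model restored from the JSON archive: evaluate the RBF decision
    # function directly from the stored support vectors
    dec <- rbf_decision(Xs, model$sv, model$coefs, model$rho, model$gamma)
    lab <- model$labels
    out <- ifelse(dec >= 0, lab[1], lab[2])
  }
  unname(out)
}

rbf_decision <- function(X, sv, coefs, rho, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * X %*% t(sv)
  K <- exp(-gamma * pmax(d2, 0))
  drop(K %*% coefs - rho)
}

#' Persist / restore a contact model as a versioned JSON archive
#'
#' The archive stores the feature scaling, kernel parameters, support
#' vectors, dual coefficients and training metadata. A restored model
#' evaluates the identical RBF decision function, so predictions round-trip
#' exactly.
#'
#' @param model A `contact_model` (radial kernel only).
#' @param path output JSON path.
#' @export
write_contact_model <- function(model, path) {
  if (model$kernel != "radial") stop("JSON persistence supports the radial kernel")
  fit <- model$fit
  # decision-value sign convention: positive = first class of "A/B" in the
  # decision-values column name (e1071 orders by first appearance, not level)
  pr <- stats::predict(fit, fit$SV[1, , drop = FALSE], decision.values = TRUE)
  dec_labels <- strsplit(colnames(attr(pr, "decision.values")), "/")[[1]]
  doc <- list(
    format = "sononav-contact-model", version = model$version,
    kernel = model$kernel, cost = model$cost, gamma = model$gamma,
    center = as.numeric(model$center), scale = as.numeric(model$scale),
    feature_names = FEATURE_NAMES,
    sv = apply(fit$SV, 1, as.numeric, simplify = FALSE),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    labels = dec_labels,
    n_contact = model$n_contact, n_no_contact = model$n_no_contact,
    seed = model$seed
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contact_model
#' @export
read_contact_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "sononav-contact-model")) {
    stop("not a sononav contact-model archive")
  }
  sv <- if (is.matrix(doc$sv)) doc$sv else do.call(rbind, doc$sv)
  structure(list(
    fit = NULL,
    sv = sv, coefs = as.numeric(doc$coefs), rho = as.numeric(doc$rho),
    labels = doc$labels,
    center = stats::setNames(as.numeric(doc$center), FEATURE_NAMES),
    scale = stats::setNames(as.numeric(doc$scale), FEATURE_NAMES),
    kernel = doc$kernel, cost = doc$cost, gamma = doc$gamma,
    n_contact = doc$n_contact, n_no_contact = doc$n_no_contact,
    seed = doc$seed, version = doc$version
  ), class = "contact_model")
}
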