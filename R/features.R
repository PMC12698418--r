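# The 142-feature collagen vocabulary: 8 morphological + 6 intensity +
# 128 textural (80 GLCM + 48 Gabor) features per ROI, with patient-level
# aggregation by ROI averaging.

#' The fixed 142-feature schema
#'
#' Feature order is stable across all inputs: 8 morphological, 6 intensity,
#' 80 GLCM (4 statistics x 5 distances x 4 angles) and 48 Gabor
#' (2 statistics x 4 scales x 6 orientations) features.
#'
#' Units: lengths in um, crosslink density per mm^2 of collagen, area as a
#' fraction of the ROI, arrangement in `[0, 1]` (0 = aligned); intensity and
#' texture features are in 8-bit gray units or derived dimensionless
#' quantities.
#'
#' @return character vector of 142 feature names.
#' @export
feature_schema <- function() {
  morph <- paste0("morph.", c("area", "number", "length", "width",
                              "straightness", "crosslink_density",
                              "crosslink_space", "arrangement"))
  int <- paste0("int.", c("mean", "variance", "skewness", "kurtosis",
                          "energy", "entropy"))
  glcm <- as.vector(vapply(
    c("contrast", "correlation", "energy", "uniformity"),
    function(stat) as.vector(vapply(1:5, function(d) {
      paste0("glcm.", stat, ".d", d, ".a", c(0, 45, 90, 135))
    }, character(4))), character(20)))
  gabor <- as.vector(vapply(c("mean", "variance"), function(stat) {
    as.vector(vapply(1:4, function(s) paste0("gabor.", stat, ".s", s, ".o",
                                             1:6), character(6)))
  }, character(24)))
  c(morph, int, glcm, gabor)
}

#' Morphological collagen features
#'
#' Eight features: collagen area fraction, fiber number, mean fiber length
#' (um), mean fiber width (um), mean straightness, crosslink density (per
#' mm^2 of collagen area), crosslink space (mean nearest-neighbour distance
#' among crosslinks, um), and arrangement (length-weighted circular variance
#' of doubled fiber orientations; 0 = perfectly aligned).
#'
#' Degenerate convention: with 0 fibers, number/length/width/straightness and
#' crosslink features and arrangement are all 0 and the result carries a
#' `degenerate` attribute.
#'
#' @param fibers a `fiber_set` from [extract_fibers()].
#' @param mask the `collagen_mask` of the same ROI.
#' @return named numeric vector of 8 features.
#' @export
morphological_features <- function(fibers, mask) {
  stopifnot(inherits(fibers, "fiber_set"), inherits(mask, "collagen_mask"))
  area_frac <- mean(mask$mask)
  nf <- length(fibers$fibers)
  if (nf == 0) {
    out <- c(area = area_frac, number = 0, length = 0, width = 0,
             straightness = 0, crosslink_density = 0, crosslink_space = 0,
             arrangement = 0)
    names(out) <- paste0("morph.", names(out))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  len <- vapply(fibers$fibers, `[[`, numeric(1), "length_um")
  wid <- vapply(fibers$fibers, `[[`, numeric(1), "mean_width_um")
  str <- vapply(fibers$fibers, `[[`, numeric(1), "straightness")
  ori <- vapply(fibers$fibers, `[[`, numeric(1), "orientation")
  xl <- fibers$crosslinks
  n_xl <- nrow(xl)
  area_mm2 <- mask$collagen_area_um2 / 1e6
  density <- if (area_mm2 > 0) n_xl / area_mm2 else 0
  space <- 0
  if (n_xl >= 2) {
    d <- as.matrix(stats::dist(xl))
    diag(d) <- Inf
    space <- mean(apply(d, 1, min)) * fibers$pixel_size_um
  }
  out <- c(area = area_frac, number = nf, length = mean(len),
           width = mean(wid), straightness = mean(str),
           crosslink_density = density, crosslink_space = space,
           arrangement = axial_dispersion(ori, len))
  names(out) <- paste0("morph.", c("area", "number", "length", "width",
                                   "straightness", "crosslink_density",
                                   "crosslink_space", "arrangement"))
  attr(out, "degenerate") <- FALSE
  out
}

#' Intensity features over the collagen mask
#'
#' First- to fourth-moment statistics of the masked gray values (variance and
#' moments population-style), plus energy `sum(p^2)` and entropy
#' `-sum(p log2 p)` over a 256-bin normalized histogram of the masked pixels.
#' Kurtosis is the plain fourth standardized moment (3 for a normal).
#'
#' Degenerate conventions: empty mask gives all zeros; zero-variance masked
#' region gives skewness = kurtosis = 0; both set the `degenerate` attribute.
#'
#' @param img an [roi_image()].
#' @param mask the `collagen_mask` of the same ROI.
#' @return named numeric vector of 6 features.
#' @export
intensity_features <- function(img, mask) {
  stopifnot(inherits(img, "roi_image"), inherits(mask, "collagen_mask"))
  nm <- paste0("int.", c("mean", "variance", "skewness", "kurtosis",
                         "energy", "entropy"))
  v <- img$pixels[mask$mask]
  if (length(v) == 0) {
    out <- stats::setNames(rep(0, 6), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  degenerate <- FALSE
  if (s2 < .Machine$double.eps) {
    sk <- 0; ku <- 0
    degenerate <- TRUE
  } else {
    sk <- mean((v - mu)^3) / s2^1.5
    ku <- mean((v - mu)^4) / s2^2
  }
  bins <- clamp(floor(v), 0, 255)
  p <- tabulate(bins + 1L, 256L) / length(v)
  p_pos <- p[p > 0]
  out <- stats::setNames(
    c(mu, s2, sk, ku, sum(p^2), -sum(p_pos * log2(p_pos))), nm)
  attr(out, "degenerate") <- degenerate
  out
}

# Quantize a gray image to n_gray levels, uniform over the observed range.
# Constant images map to a single level (level 1) and are flagged.
quantize_gray <- function(g, n_gray) {
  rng <- range(g)
  if (diff(rng) < .Machine$double.eps) {
    return(list(q = matrix(1L, nrow(g), ncol(g)), constant = TRUE))
  }
  q <- floor((g - rng[1]) / (rng[2] - rng[1]) * n_gray)
  q <- matrix(as.integer(pmin(q, n_gray - 1)) + 1L, nrow(g), ncol(g))
  list(q = q, constant = FALSE)
}

# Offsets (dr, dc) for GLCM angles 0, 45, 90, 135 degrees at distance d.
glcm_offsets <- function(d) {
  list(a0 = c(0L, d), a45 = c(-d, d), a90 = c(-d, 0L), a135 = c(-d, -d))
}

# Symmetric normalized GLCM for one offset; NULL when no valid pair exists.
# (Reference path; the batched extraction calls the compiled accumulator.)
glcm_matrix <- function(q, n_gray, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  ri <- max(1L, 1L - dr):min(nr, nr - dr)
  ci <- max(1L, 1L - dc):min(nc, nc - dc)
  if (length(ri) == 0 || length(ci) == 0 || ri[1] > ri[length(ri)] ||
      ci[1] > ci[length(ci)]) return(NULL)
  i <- q[ri, ci, drop = FALSE]
  j <- q[ri + dr, ci + dc, drop = FALSE]
  counts <- tabulate((i - 1L) * n_gray + j, nbins = n_gray * n_gray)
  m <- matrix(counts, n_gray, n_gray, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

#' Gray-level co-occurrence texture features
#'
#' The image is quantized to `n_gray` levels over its observed range; for
#' each pixel distance 1..5 and angle 0/45/90/135 degrees a symmetric,
#' normalized GLCM is built and summarized by contrast, correlation, energy
#' (angular second moment) and uniformity (inverse difference moment,
#' homogeneity), giving 80 features.
#'
#' Degenerate conventions (flagged): a constant image gives contrast 0,
#' correlation 0, energy 1, uniformity 1 for every configuration; an offset
#' with no valid pixel pair uses the same convention.
#'
#' @param img an [roi_image()] or gray matrix.
#' @param n_gray number of quantization levels.
#' @return named numeric vector of 80 features.
#' @export
glcm_features <- function(img, n_gray = 32) {
  g <- if (inherits(img, "roi_image")) img$pixels else img
  qz <- quantize_gray(g, n_gray)
  drv <- integer(20); dcv <- integer(20)
  k <- 0
  for (d in 1:5) {
    for (off in glcm_offsets(d)) {
      k <- k + 1
      drv[k] <- off[1]; dcv[k] <- off[2]
    }
  }
  if (qz$constant) {
    st <- matrix(rep(c(0, 0, 1, 1), each = 20), 20, 4,
                 dimnames = list(NULL, c("contrast", "correlation", "energy",
                                         "uniformity")))
    degenerate <- TRUE
  } else {
    st <- cpp_glcm_stats(qz$q, as.integer(n_gray), drv, dcv)
    degenerate <- anyNA(st)
    if (degenerate) {
      # offsets with no valid pair take the constant-image convention
      bad <- which(is.na(st[, 1]))
      st[bad, ] <- rep(c(0, 0, 1, 1), each = length(bad))
    }
  }
  ang <- c(0, 45, 90, 135)
  nm <- character(80); val <- numeric(80)
  i <- 0
  for (stat in c("contrast", "correlation", "energy", "uniformity")) {
    k <- 0
    for (d in 1:5) {
      for (a in 1:4) {
        k <- k + 1
        i <- i + 1
        nm[i] <- paste0("glcm.", stat, ".d", d, ".a", ang[a])
        val[i] <- st[k, stat]
      }
    }
  }
  out <- stats::setNames(val, nm)
  attr(out, "degenerate") <- degenerate
  out
}

# --- Gabor filter bank -------------------------------------------------------

#' Spatial Gabor kernel used by the filter bank
#'
#' Complex Gabor kernel in the circular-convolution layout (center at pixel
#' (1,1) with wrap-around): Gaussian envelope with bandwidth 1 octave
#' (`sigma_x = 0.5622 lambda`), aspect ratio 0.5 (`sigma_y = 2 sigma_x`), and
#' a complex carrier along the filter orientation. Image rows grow downward,
#' so the math y-axis is the negated row coordinate. Exposed so the filter
#' definition is inspectable and checkable against direct convolution.
#'
#' @param nr,nc kernel (= image) dimensions.
#' @param lambda wavelength in pixels.
#' @param theta orientation in radians.
#' @return complex `nr x nc` matrix.
#' @export
gabor_kernel <- function(nr, nc, lambda, theta) {
  sx <- 0.5622 * lambda
  sy <- sx / 0.5
  x0 <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1))
  y0 <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1))
  X <- matrix(x0, nr, nc, byrow = TRUE)
  Y <- matrix(y0, nr, nc)
  xr <- X * cos(theta) + (-Y) * sin(theta)
  yr <- -X * sin(theta) + (-Y) * cos(theta)
  env <- exp(-(xr^2 / (2 * sx^2) + yr^2 / (2 * sy^2)))
  env * exp(1i * 2 * pi * xr / lambda)
}

#' Gabor filter bank texture features
#'
#' Convolves the `[0, 1]`-normalized image with a complex Gabor bank at four
#' scales (wavelengths 2, 4, 8, 16 px) and six orientations (0, 30, ..., 150
#' degrees; bandwidth 1 octave, aspect ratio 0.5) via FFT (circular boundary)
#' and records the mean and variance of each response magnitude image:
#' 48 features.
#'
#' A warning is issued when the image is smaller than twice the largest
#' wavelength (the wrapped kernel is then effectively clipped).
#'
#' @param img an [roi_image()] or gray matrix (8-bit gray values).
#' @param lambdas wavelengths in pixels, one per scale.
#' @param n_orientations number of evenly spaced orientations over 180
#'   degrees.
#' @return named numeric vector of 48 features (means first, then
#'   variances).
#' @export
gabor_features <- function(img, lambdas = c(2, 4, 8, 16),
                           n_orientations = 6) {
  g <- if (inherits(img, "roi_image")) img$pixels else img
  g <- g / 255
  nr <- nrow(g); nc <- ncol(g)
  if (min(nr, nc) < 2 * max(lambdas)) {
    warning("image smaller than twice the largest Gabor wavelength; ",
            "kernel support is clipped by wrap-around")
  }
  thetas <- (seq_len(n_orientations) - 1) * pi / n_orientations
  st <- cpp_gabor_stats(g, lambdas, thetas)
  nm <- as.vector(t(outer(seq_along(lambdas), seq_along(thetas),
                          function(s, o) paste0(".s", s, ".o", o))))
  stats::setNames(c(st[, "mean"], st[, "variance"]),
                  c(paste0("gabor.mean", nm), paste0("gabor.variance", nm)))
}

#' Extract the full 142-feature vector of one ROI
#'
#' Runs segmentation, fiber tracing and all four feature families on one ROI
#' image and returns the named 142-vector in schema order
#' (see [feature_schema()]). Degenerate images (e.g., all background) yield
#' the documented convention values with the `degenerate_flags` attribute
#' set.
#'
#' @param img an [roi_image()], gray matrix, or 3-channel array.
#' @param pixel_size_um pixel size when `img` is a bare matrix/array.
#' @param min_object_px,spur_min_um,node_merge_um,merge_angle_tol,fiber_min_um
#'   segmentation and tracing parameters, see [segment_collagen()] and
#'   [extract_fibers()].
#' @param n_gray GLCM quantization levels.
#' @return named numeric vector of length 142 with attribute
#'   `degenerate_flags` (named logical).
#' @export
extract_feature_vector <- function(img, pixel_size_um = 1,
                                   min_object_px = 16,
                                   spur_min_um = 4, node_merge_um = 3,
                                   merge_angle_tol = 20, fiber_min_um = 10,
                                   n_gray = 32) {
  img <- to_grayscale(img, pixel_size_um)
  mask <- withCallingHandlers(
    segment_collagen(img, min_object_px = min_object_px),
    warning = function(w) invokeRestart("muffleWarning"))
  fibers <- extract_fibers(mask, img, spur_min_um = spur_min_um,
                           node_merge_um = node_merge_um,
                           merge_angle_tol = merge_angle_tol,
                           fiber_min_um = fiber_min_um)
  morph <- morphological_features(fibers, mask)
  int <- intensity_features(img, mask)
  glcm <- glcm_features(img, n_gray = n_gray)
  gabor <- withCallingHandlers(gabor_features(img),
                               warning = function(w)
                                 invokeRestart("muffleWarning"))
  out <- c(morph, int, glcm, gabor)
  stopifnot(identical(names(out), feature_schema()))
  out[!is.finite(out)] <- 0
  attr(out, "degenerate_flags") <- c(
    mask = isTRUE(mask$degenerate),
    morphology = isTRUE(attr(morph, "degenerate")),
    intensity = isTRUE(attr(int, "degenerate")),
    glcm = isTRUE(attr(glcm, "degenerate"))
  )
  out
}

#' Aggregate ROI feature vectors to the patient level
#'
#' Element-wise arithmetic mean of the ROI vectors. The study design expects
#' five ROIs per patient; fewer are accepted with a warning.
#'
#' @param rois list of feature vectors with identical schema.
#' @param expected expected ROI count (default 5).
#' @return named numeric vector of 142 patient-level features.
#' @export
aggregate_patient <- function(rois, expected = 5) {
  stopifnot(length(rois) >= 1)
  nm <- names(rois[[1]])
  for (r in rois) {
    if (!identical(names(r), nm)) stop("ROI feature schemas differ")
  }
  if (length(rois) < expected) {
    warning("aggregating ", length(rois), " ROIs (expected ", expected, ")")
  }
  colMeans(do.call(rbind, rois))
}

#' Extract patient-level features for a whole cohort
#'
#' Renders each patient's ROIs (from a simulated cohort), extracts the
#' 142-feature vector per ROI and averages them per patient.
#'
#' @param cohort a `collagen_cohort` from [simulate_cohort()].
#' @param ... parameters forwarded to [extract_feature_vector()].
#' @return matrix (patients x 142) with patient ids as row names.
#' @export
cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "collagen_cohort"))
  n <- nrow(cohort$patients)
  out <- matrix(NA_real_, n, length(feature_schema()),
                dimnames = list(cohort$patients$patient_id, feature_schema()))
  for (i in seq_len(n)) {
    imgs <- patient_roi_images(cohort, i)
    fv <- lapply(imgs, extract_feature_vector, ...)
    out[i, ] <- aggregate_patient(fv, expected = cohort$cparams$rois_per_patient)
  }
  out
}

#' Write a feature table with its schema sidecar
#'
#' @param features matrix or data.frame of feature values (rows = ROIs or
#'   patients) with feature-named columns.
#' @param path CSV output path; a JSON sidecar `<path>.schema.json` fixes the
#'   feature order and units.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  df <- as.data.frame(features)
  df <- cbind(id = rownames(df) %||% seq_len(nrow(df)), df)
  utils::write.csv(df, path, row.names = FALSE)
  schema <- list(
    features = feature_schema(),
    n_features = length(feature_schema()),
    partition = list(morphological = 8, intensity = 6, glcm = 80, gabor = 48),
    units = list(length = "um", density = "per mm^2 collagen",
                 area = "fraction of ROI", intensity = "8-bit gray")
  )
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE)
  invisible(path)
}
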