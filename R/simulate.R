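# Synthetic SHG-like collagen image and cohort simulation.
#
# The simulator provides the ground-truth substrate for testing the whole
# pipeline: bright curvilinear fibers on a dark background, branch-point
# crosslinks, additive sensor noise, and a patient cohort whose latent stromal
# aggressiveness drives both the fiber architecture and the binary metastasis
# outcome.

#' Fiber field simulation parameters
#'
#' Parameter container for [simulate_fiber_image()]. Defaults emulate a
#' 1000 um x 1000 um SHG field of view rendered at desk-scale resolution
#' (512 px, ~1.95 um/px) with 8-bit gray levels.
#'
#' @param n_fibers number of primary fibers (>= 0).
#' @param length_mean,length_sd fiber length distribution, um.
#' @param width_mean fiber width (full width at half maximum of the Gaussian
#'   cross-profile), um.
#' @param orientation_mode modal fiber axis, radians in `[0, pi)`.
#' @param orientation_kappa concentration of the doubled-angle von Mises axis
#'   distribution; 0 = isotropic, large = aligned.
#' @param curvature_sd standard deviation of the per-step heading increment of
#'   the fiber random walk, radians per pixel step.
#' @param crosslink_rate expected number of branch fibers seeded per primary
#'   fiber (>= 0); each branch point is a ground-truth crosslink.
#' @param fiber_intensity_mean,fiber_intensity_sd per-fiber peak brightness,
#'   8-bit gray units.
#' @param background_noise_sd additive Gaussian noise, gray units.
#' @param speckle logical; add Poisson-like multiplicative speckle.
#' @param image_size_px image side, pixels.
#' @param pixel_size_um physical pixel size, um/pixel. The default preserves a
#'   1000 um field of view for any `image_size_px`.
#' @return object of class `fiber_field_params`.
#' @export
fiber_field_params <- function(n_fibers = 60,
                               length_mean = 300, length_sd = 80,
                               width_mean = 6,
                               orientation_mode = 0,
                               orientation_kappa = 2,
                               curvature_sd = 0.05,
                               crosslink_rate = 0.5,
                               fiber_intensity_mean = 160,
                               fiber_intensity_sd = 30,
                               background_noise_sd = 10,
                               speckle = FALSE,
                               image_size_px = 512,
                               pixel_size_um = 1000 / image_size_px) {
  p <- list(
    n_fibers = n_fibers, length_mean = length_mean, length_sd = length_sd,
    width_mean = width_mean, orientation_mode = orientation_mode,
    orientation_kappa = orientation_kappa, curvature_sd = curvature_sd,
    crosslink_rate = crosslink_rate,
    fiber_intensity_mean = fiber_intensity_mean,
    fiber_intensity_sd = fiber_intensity_sd,
    background_noise_sd = background_noise_sd, speckle = isTRUE(speckle),
    image_size_px = as.integer(image_size_px), pixel_size_um = pixel_size_um
  )
  if (p$image_size_px <= 0) stop("image_size_px must be positive")
  if (p$pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (p$n_fibers < 0) stop("n_fibers must be >= 0")
  if (p$crosslink_rate < 0) stop("crosslink_rate must be >= 0")
  if (p$orientation_kappa < 0) stop("orientation_kappa must be >= 0")
  for (f in c("length_sd", "curvature_sd", "fiber_intensity_sd",
              "background_noise_sd")) {
    if (p[[f]] < 0) stop(f, " must be >= 0")
  }
  class(p) <- "fiber_field_params"
  p
}

#' Construct an ROI image object
#'
#' @param pixels numeric matrix of gray values (rows = image rows).
#' @param pixel_size_um physical pixel size, um/pixel.
#' @param source_id free-text identifier.
#' @return object of class `roi_image`.
#' @export
roi_image <- function(pixels, pixel_size_um, source_id = "") {
  stopifnot(is.matrix(pixels), pixel_size_um > 0)
  if (any(pixels < 0)) stop("gray values must be >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 source_id = source_id),
            class = "roi_image")
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image %dx%d px, %.3f um/px, gray [%.0f, %.0f]%s>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              min(x$pixels), max(x$pixels),
              if (nzchar(x$source_id)) paste0(", ", x$source_id) else ""))
  invisible(x)
}

# Trace one fiber centerline as a unit-step random walk.
# Returns a data.frame of (row, col) pixel coordinates (1-based, fractional)
# plus the initial axis angle.
trace_fiber_path <- function(start_rc, theta0, n_steps, curvature_sd) {
  n_steps <- max(1L, as.integer(n_steps))
  dtheta <- if (curvature_sd > 0) stats::rnorm(n_steps, 0, curvature_sd) else
    numeric(n_steps)
  theta <- theta0 + cumsum(dtheta) - dtheta[1]
  # image convention: col ~ x (cos), row ~ -y (sin); angles are axis angles
  cols <- start_rc[2] + cumsum(c(0, cos(theta[-1])))
  rows <- start_rc[1] - cumsum(c(0, sin(theta[-1])))
  list(rows = rows, cols = cols, theta = theta)
}

# Stamp a polyline onto `img` with an isotropic Gaussian footprint per vertex.
# Accumulation is by pixelwise max, giving a ridge with Gaussian cross-profile
# and peak `amp`. Vertices are interpolated to quarter-pixel spacing so the
# max-envelope does not bead along shallow diagonals.
render_polyline <- function(img, rows, cols, sigma_px, amp) {
  if (length(rows) > 1) {
    t0 <- seq_along(rows)
    ti <- seq(1, length(rows), by = 0.25)
    rows <- stats::approx(t0, rows, ti)$y
    cols <- stats::approx(t0, cols, ti)$y
  }
  cpp_render_polyline(img, rows, cols, sigma_px, amp)
}

#' Simulate one SHG-like collagen ROI image
#'
#' Renders `n_fibers` random-walk fibers with Gaussian cross-profiles, seeds
#' branch fibers at crosslink points, and adds background noise, clipped to
#' the 8-bit range `[0, 255]`. The output is a pure function of
#' `(params, seed)`.
#'
#' @param params a [fiber_field_params()] object.
#' @param seed integer seed.
#' @return a list with elements `image` (an [roi_image()]) and `ground_truth`
#'   (class `fiber_ground_truth`): per-fiber centerlines, true axis
#'   orientations, lengths and widths (um), true crosslink pixel coordinates,
#'   and the generating parameters.
#' @export
simulate_fiber_image <- function(params, seed) {
  stopifnot(inherits(params, "fiber_field_params"))
  with_seed(seed, {
    n <- params$image_size_px
    px <- params$pixel_size_um
    img <- matrix(0, n, n)
    fibers <- list()
    crosslinks <- NULL

    add_fiber <- function(start_rc, theta0) {
      len_um <- max(2 * px, stats::rnorm(1, params$length_mean,
                                         params$length_sd))
      n_steps <- max(2L, as.integer(round(len_um / px)))
      trace_fiber_path(start_rc, theta0, n_steps, params$curvature_sd)
    }

    if (params$n_fibers > 0) {
      for (i in seq_len(params$n_fibers)) {
        start <- stats::runif(2, 1, n)
        theta0 <- (rvonmises(1, 2 * params$orientation_mode,
                             params$orientation_kappa) / 2) %% pi
        if (stats::runif(1) < 0.5) theta0 <- theta0 + pi # undirected axis
        fibers[[length(fibers) + 1L]] <- add_fiber(start, theta0)
      }
      n_branch <- stats::rpois(1, params$crosslink_rate * params$n_fibers)
      for (b in seq_len(n_branch)) {
        host <- fibers[[sample.int(length(fibers), 1)]]
        j <- sample.int(length(host$rows), 1)
        seed_rc <- c(host$rows[j], host$cols[j])
        theta0 <- (rvonmises(1, 2 * params$orientation_mode,
                             params$orientation_kappa) / 2) %% pi
        if (stats::runif(1) < 0.5) theta0 <- theta0 + pi
        fibers[[length(fibers) + 1L]] <- add_fiber(seed_rc, theta0)
        crosslinks <- rbind(crosslinks, seed_rc)
      }
      sigma_px <- (params$width_mean / 2.355) / px # FWHM -> sd, in pixels
      for (f in fibers) {
        amp <- clamp(stats::rnorm(1, params$fiber_intensity_mean,
                                  params$fiber_intensity_sd), 20, 255)
        img <- render_polyline(img, f$rows, f$cols, sigma_px, amp)
      }
    }

    if (params$speckle) {
      img <- img + sqrt(pmax(img, 0)) * stats::rnorm(length(img))
    }
    if (params$background_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, params$background_noise_sd)
    }
    img <- clamp(img, 0, 255)

    gt_fibers <- lapply(fibers, function(f) {
      step <- sqrt(diff(f$rows)^2 + diff(f$cols)^2)
      inside <- f$rows >= 1 & f$rows <= n & f$cols >= 1 & f$cols <= n
      step_in <- step[inside[-length(inside)] & inside[-1]]
      list(rows = f$rows, cols = f$cols,
           orientation = axial_mean(f$theta),
           length_um = sum(step) * px,
           length_in_um = sum(step_in) * px, # in-image (rendered) portion
           width_um = params$width_mean)
    })
    gt <- structure(list(
      fibers = gt_fibers,
      n_fibers = length(gt_fibers),
      crosslinks = crosslinks,
      n_crosslinks = if (is.null(crosslinks)) 0L else nrow(crosslinks),
      params = params, seed = seed
    ), class = "fiber_ground_truth")

    list(image = roi_image(img, px, sprintf("sim-seed%d", seed)),
         ground_truth = gt)
  })
}

#' Cohort simulation parameters
#'
#' Defines a synthetic patient cohort in which a latent standard-normal
#' stromal aggressiveness score drives both the collagen architecture of each
#' patient's ROIs and (together with clinical covariates) the log-odds of
#' central lymph node metastasis (CLNM).
#'
#' Default covariate prevalences follow the pooled cohort of the study design
#' this package emulates (tumor size > 1 cm: 0.47; upper-lobe location: 0.26;
#' thyroid capsular invasion: 0.49), and default outcome coefficients give a
#' CLNM prevalence near 41% with positive effects of aggressiveness, size,
#' upper location and capsular invasion.
#'
#' @param n_patients cohort size (>= 1).
#' @param rois_per_patient ROIs imaged per patient (study design: 5).
#' @param prevalence_covariates named probabilities for `size_gt1cm`,
#'   `location_upper`, `tci`.
#' @param outcome_coefficients named log-odds weights: `intercept`,
#'   `aggressiveness`, `size_gt1cm`, `location_upper`, `tci`.
#' @param aggressiveness_to_fiber_map deterministic function mapping a latent
#'   aggressiveness scalar to a [fiber_field_params()] object. The default map
#'   increases crosslink_rate, decreases orientation_kappa and decreases
#'   fiber_intensity_mean as aggressiveness rises.
#' @param image_size_px image side passed to the default fiber map.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 350,
                          rois_per_patient = 5,
                          prevalence_covariates = c(size_gt1cm = 0.47,
                                                    location_upper = 0.26,
                                                    tci = 0.49),
                          outcome_coefficients = c(intercept = -1.5,
                                                   aggressiveness = 1.2,
                                                   size_gt1cm = 1.1,
                                                   location_upper = 0.95,
                                                   tci = 0.8),
                          aggressiveness_to_fiber_map = NULL,
                          image_size_px = 512) {
  stopifnot(n_patients >= 1)
  if (rois_per_patient < 1) stop("rois_per_patient must be >= 1")
  pv <- prevalence_covariates
  if (any(pv < 0 | pv > 1)) stop("prevalences must be in [0, 1]")
  need <- c("size_gt1cm", "location_upper", "tci")
  if (!all(need %in% names(pv))) stop("prevalence_covariates must name ",
                                      paste(need, collapse = ", "))
  oc <- outcome_coefficients
  need_oc <- c("intercept", "aggressiveness", need)
  if (!all(need_oc %in% names(oc))) stop("outcome_coefficients must name ",
                                         paste(need_oc, collapse = ", "))
  map <- aggressiveness_to_fiber_map %||%
    default_aggressiveness_map(image_size_px)
  structure(list(n_patients = as.integer(n_patients),
                 rois_per_patient = as.integer(rois_per_patient),
                 prevalence_covariates = pv,
                 outcome_coefficients = oc,
                 aggressiveness_to_fiber_map = map,
                 image_size_px = as.integer(image_size_px)),
            class = "cohort_params")
}

#' Default aggressiveness-to-fiber-architecture map
#'
#' Returns a deterministic function of a latent aggressiveness scalar `a`
#' (standard-normal scale) producing [fiber_field_params()]: crosslink_rate
#' rises (`0.5 * exp(0.5 a)`), orientation_kappa falls (`2 * exp(-0.6 a)`),
#' and fiber peak brightness falls (`175 - 35 * plogis(a)`) with
#' aggressiveness — more crosslinked, more disordered, dimmer collagen in
#' aggressive stroma.
#'
#' @param image_size_px image side in pixels for the generated fields.
#' @param n_fibers primary fiber count per field.
#' @return function `a -> fiber_field_params`.
#' @export
default_aggressiveness_map <- function(image_size_px = 512, n_fibers = 60) {
  force(image_size_px); force(n_fibers)
  scale <- image_size_px / 512 # keep fiber geometry proportional to the FOV
  function(a) {
    fiber_field_params(
      n_fibers = max(1L, as.integer(round(n_fibers))),
      length_mean = 300, length_sd = 80,
      width_mean = 6 / scale, # keep the rendered cross-profile ~1.3 px wide

      orientation_mode = 0,
      orientation_kappa = 2 * exp(-0.6 * a),
      curvature_sd = 0.05,
      crosslink_rate = 0.5 * exp(0.5 * a),
      fiber_intensity_mean = 175 - 35 * stats::plogis(a),
      fiber_intensity_sd = 20,
      background_noise_sd = 10,
      image_size_px = image_size_px
    )
  }
}

#' Simulate a patient cohort with ground truth
#'
#' Each patient draws a latent aggressiveness `a ~ N(0, 1)`, independent
#' Bernoulli clinical covariates, a CLNM label from the logistic outcome
#' model, and `rois_per_patient` ROI fiber fields whose architecture is the
#' deterministic image of `a` under the aggressiveness map. Reproducible:
#' the output is a pure function of `(cparams, seed)`.
#'
#' Balance covariates with no outcome effect (age > 50, male sex, BMI > 23,
#' multifocality) are simulated at the pooled study prevalences for use in
#' association analyses.
#'
#' @param cparams a [cohort_params()] object.
#' @param seed integer seed.
#' @param keep_images logical; if `TRUE`, render and store all ROI images (can
#'   be large). If `FALSE`, images are re-rendered on demand by
#'   [patient_roi_images()] from the recorded per-ROI seeds.
#' @return object of class `collagen_cohort`: `patients` data.frame
#'   (patient_id, covariates, aggressiveness, p_true, clnm), `fiber_params`
#'   (per-patient), `roi_seeds` (patients x ROIs matrix), optional `images`.
#' @export
simulate_cohort <- function(cparams, seed, keep_images = FALSE) {
  stopifnot(inherits(cparams, "cohort_params"))
  n <- cparams$n_patients
  with_seed(derive_seed(seed, 1), {
    a <- stats::rnorm(n)
    pv <- cparams$prevalence_covariates
    size <- stats::rbinom(n, 1, pv[["size_gt1cm"]])
    loc <- stats::rbinom(n, 1, pv[["location_upper"]])
    tci <- stats::rbinom(n, 1, pv[["tci"]])
    age <- stats::rbinom(n, 1, 0.20)
    male <- stats::rbinom(n, 1, 0.41)
    bmi <- stats::rbinom(n, 1, 0.45)
    multi <- stats::rbinom(n, 1, 0.25)
    oc <- cparams$outcome_coefficients
    lp <- oc[["intercept"]] + oc[["aggressiveness"]] * a +
      oc[["size_gt1cm"]] * size + oc[["location_upper"]] * loc +
      oc[["tci"]] * tci
    p_true <- inv_logit(lp)
    clnm <- stats::rbinom(n, 1, p_true)
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      age_gt50 = age, male = male, bmi_gt23 = bmi, multifocal = multi,
      size_gt1cm = size, location_upper = loc, tci = tci,
      aggressiveness = a, p_true = p_true, clnm = clnm,
      stringsAsFactors = FALSE
    )
    fparams <- lapply(a, cparams$aggressiveness_to_fiber_map)
    roi_seeds <- matrix(
      derive_seed(seed, 2) + outer((seq_len(n) - 1L) * cparams$rois_per_patient,
                                   seq_len(cparams$rois_per_patient) - 1L, "+"),
      nrow = n
    )
    roi_seeds <- roi_seeds %% 2147483629L + 1L
    out <- structure(list(patients = patients, fiber_params = fparams,
                          roi_seeds = roi_seeds, cparams = cparams,
                          seed = seed),
                     class = "collagen_cohort")
    if (keep_images) {
      out$images <- lapply(seq_len(n), function(i) patient_roi_images(out, i))
    }
    out
  })
}

#' Render (or fetch) the ROI images of one patient
#'
#' @param cohort a `collagen_cohort` from [simulate_cohort()].
#' @param i patient index.
#' @param with_ground_truth logical; also return per-ROI ground truth.
#' @return list of `roi_image` objects (one per ROI), or, if
#'   `with_ground_truth`, a list of `list(image, ground_truth)`.
#' @export
patient_roi_images <- function(cohort, i, with_ground_truth = FALSE) {
  stopifnot(inherits(cohort, "collagen_cohort"))
  if (!with_ground_truth && !is.null(cohort$images)) return(cohort$images[[i]])
  sims <- lapply(cohort$roi_seeds[i, ], function(s) {
    simulate_fiber_image(cohort$fiber_params[[i]], s)
  })
  if (with_ground_truth) sims else lapply(sims, `[[`, "image")
}

#' @export
print.collagen_cohort <- function(x, ...) {
  cat(sprintf(
    "<collagen_cohort: %d patients x %d ROIs, CLNM prevalence %.3f>\n",
    nrow(x$patients), x$cparams$rois_per_patient, mean(x$patients$clnm)))
  invisible(x)
}

#' Write an ROI image and its ground truth to disk
#'
#' The image is written as a single-channel 8-bit TIFF (gray values rescaled
#' from `[0, 255]` to `[0, 1]` for the writer) with a JSON sidecar holding the
#' ground truth in 0-based (row, col) pixel coordinates and um units.
#'
#' @param sim output of [simulate_fiber_image()].
#' @param path TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_roi_image <- function(sim, path) {
  img <- sim$image
  EBImage::writeImage(EBImage::Image(t(img$pixels) / 255), path, type = "tiff",
                      bits.per.sample = 8L)
  gt <- sim$ground_truth
  side <- list(
    pixel_size_um = img$pixel_size_um,
    n_fibers = gt$n_fibers,
    n_crosslinks = gt$n_crosslinks,
    crosslinks_rc0 = if (gt$n_crosslinks > 0) unname(gt$crosslinks - 1) else
      list(),
    fibers = lapply(gt$fibers, function(f) list(
      orientation = f$orientation, length_um = f$length_um,
      width_um = f$width_um,
      centerline_rc0 = cbind(f$rows - 1, f$cols - 1)
    ))
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an ROI image from a TIFF or PNG file
#'
#' Multi-channel images are collapsed with [to_grayscale()]. Pixel values are
#' rescaled to 8-bit gray `[0, 255]`.
#'
#' @param path image file path.
#' @param pixel_size_um physical pixel size, um/pixel.
#' @return an [roi_image()].
#' @export
read_roi_image <- function(path, pixel_size_um) {
  x <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(x)) == 3) {
    arr <- aperm(x, c(2, 1, 3))
    return(to_grayscale(arr * 255, pixel_size_um, source_id = path))
  }
  roi_image(t(x) * 255, pixel_size_um, source_id = path)
}
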