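# SHG-like fiber image and cohort simulation.

test_that("empty field renders an identically zero image with empty truth", {
  p <- fiber_field_params(n_fibers = 0, background_noise_sd = 0)
  sim <- simulate_fiber_image(p, 1)
  expect_true(all(sim$image$pixels == 0))
  expect_equal(sim$ground_truth$n_fibers, 0)
  expect_equal(sim$ground_truth$n_crosslinks, 0)
})

test_that("simulation is a pure function of (params, seed)", {
  p <- fiber_field_params(n_fibers = 15, image_size_px = 96)
  a <- simulate_fiber_image(p, 7)
  b <- simulate_fiber_image(p, 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth$crosslinks, b$ground_truth$crosslinks)
  c_ <- simulate_fiber_image(p, 8)
  expect_false(identical(a$image$pixels, c_$image$pixels))
})

test_that("a noiseless straight fiber renders as one straight segment", {
  sim <- straight_fiber_sim()
  gt <- sim$ground_truth$fibers[[1]]
  # analytic straight-line geometry: endpoint distance equals path length
  chord <- sqrt((gt$rows[length(gt$rows)] - gt$rows[1])^2 +
                  (gt$cols[length(gt$cols)] - gt$cols[1])^2)
  path <- sum(sqrt(diff(gt$rows)^2 + diff(gt$cols)^2))
  expect_equal(chord / path, 1, tolerance = 0.02)
  # and traces back as a single straight fiber
  fs <- extract_fibers(segment_collagen(sim$image))
  expect_length(fs$fibers, 1)
  expect_gte(fs$fibers[[1]]$straightness, 0.98)
  expect_equal(fs$fibers[[1]]$length_um, gt$length_in_um, tolerance = 0.05)
  expect_equal(nrow(fs$crosslinks), 0)
})

test_that("invalid fiber field parameters are rejected", {
  expect_error(fiber_field_params(image_size_px = 0), "image_size_px")
  expect_error(fiber_field_params(n_fibers = -1), "n_fibers")
  expect_error(fiber_field_params(crosslink_rate = -0.1), "crosslink_rate")
  expect_error(fiber_field_params(background_noise_sd = -1), "noise")
})

test_that("true crosslink count rises with crosslink_rate", {
  counts <- vapply(c(0.2, 1, 3), function(cr) {
    mean(vapply(1:20, function(s) {
      p <- fiber_field_params(n_fibers = 10, crosslink_rate = cr,
                              image_size_px = 96)
      simulate_fiber_image(p, s)$ground_truth$n_crosslinks
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("cohort simulation matches its design", {
  cp <- cohort_params(n_patients = 40, image_size_px = 48)
  co <- simulate_cohort(cp, 5)
  expect_equal(nrow(co$patients), 40)
  expect_equal(ncol(co$roi_seeds), 5)
  imgs <- patient_roi_images(co, 3)
  expect_length(imgs, 5)
  expect_s3_class(imgs[[1]], "roi_image")
  # deterministic under seed, including lazily rendered images
  co2 <- simulate_cohort(cp, 5)
  expect_identical(co$patients, co2$patients)
  expect_identical(patient_roi_images(co2, 3)[[2]]$pixels, imgs[[2]]$pixels)
  expect_error(cohort_params(rois_per_patient = 0), "rois_per_patient")
})

test_that("null outcome model gives 50% prevalence and aggressiveness drives AUC", {
  cp <- cohort_params(
    n_patients = 2000,
    outcome_coefficients = c(intercept = 0, aggressiveness = 0,
                             size_gt1cm = 0, location_upper = 0, tci = 0))
  co <- simulate_cohort(cp, 11)
  prev <- mean(co$patients$clnm)
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / 2000))

  cp2 <- cohort_params(
    n_patients = 500,
    outcome_coefficients = c(intercept = 0, aggressiveness = 5,
                             size_gt1cm = 0, location_upper = 0, tci = 0))
  aucs <- vapply(1:5, function(s) {
    co2 <- simulate_cohort(cp2, s)
    roc_auc(co2$patients$aggressiveness, co2$patients$clnm)
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("the aggressiveness map is deterministic and monotone", {
  map <- default_aggressiveness_map(64)
  a <- c(-2, -1, 0, 1, 2)
  ps <- lapply(a, map)
  expect_identical(map(0.3), map(0.3))
  xr <- vapply(ps, `[[`, numeric(1), "crosslink_rate")
  kp <- vapply(ps, `[[`, numeric(1), "orientation_kappa")
  im <- vapply(ps, `[[`, numeric(1), "fiber_intensity_mean")
  expect_true(all(diff(xr) > 0))
  expect_true(all(diff(kp) < 0))
  expect_true(all(diff(im) < 0))
})

test_that("ROI images round-trip through TIFF with ground-truth sidecar", {
  p <- fiber_field_params(n_fibers = 5, image_size_px = 64)
  sim <- simulate_fiber_image(p, 2)
  path <- file.path(tempdir(), "roi.tif")
  write_roi_image(sim, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$n_fibers, sim$ground_truth$n_fibers)
  back <- read_roi_image(path, sim$image$pixel_size_um)
  expect_equal(dim(back$pixels), dim(sim$image$pixels))
  # 8-bit quantization only
  expect_lt(max(abs(back$pixels - sim$image$pixels)), 1)
  unlink(c(path, paste0(path, ".json")))
})
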