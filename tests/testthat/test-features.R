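# The 142-feature vocabulary.

test_that("the schema is fixed at 142 features partitioned 8/6/80/48", {
  nm <- feature_schema()
  expect_length(nm, 142)
  expect_equal(sum(startsWith(nm, "morph.")), 8)
  expect_equal(sum(startsWith(nm, "int.")), 6)
  expect_equal(sum(startsWith(nm, "glcm.")), 80)
  expect_equal(sum(startsWith(nm, "gabor.")), 48)
  expect_false(anyDuplicated(nm) > 0)
})

test_that("every image yields the full finite schema in order", {
  p <- fiber_field_params(n_fibers = 8, image_size_px = 96)
  for (s in 1:2) {
    sim <- simulate_fiber_image(p, s)
    fv <- extract_feature_vector(sim$image,
                                 pixel_size_um = sim$image$pixel_size_um)
    expect_identical(names(fv), feature_schema())
    expect_true(all(is.finite(fv)))
  }
  # all-background image: convention values, flags set
  fv0 <- extract_feature_vector(matrix(0, 64, 64), pixel_size_um = 2)
  expect_identical(names(fv0), feature_schema())
  expect_true(all(is.finite(fv0)))
  expect_true(all(attr(fv0, "degenerate_flags")))
})

test_that("morphological features follow their definitions and conventions", {
  # parallel horizontal fibers: aligned, no crosslinks
  n <- 128
  g <- matrix(0, n, n)
  for (r in c(20, 50, 80, 110)) for (d in -1:1) g[r + d, 10:118] <- 180
  mask <- segment_collagen(roi_image(g, 2), min_object_px = 4)
  fs <- extract_fibers(mask)
  mf <- morphological_features(fs, mask)
  expect_equal(mf[["morph.number"]], 4)
  expect_lte(mf[["morph.arrangement"]], 0.05)
  expect_equal(mf[["morph.crosslink_density"]], 0)
  expect_equal(mf[["morph.area"]], mean(mask$mask))
  # X crossing: one crosslink per measured collagen area
  im2 <- matrix(0, n, n)
  for (i in 10:118) for (d in -1:1) {
    im2[i + d, i] <- 200; im2[i + d, n + 1 - i] <- 200
  }
  mask2 <- segment_collagen(roi_image(im2, 2), min_object_px = 4)
  fs2 <- extract_fibers(mask2)
  mf2 <- morphological_features(fs2, mask2)
  expect_equal(mf2[["morph.crosslink_density"]],
               1 / (mask2$collagen_area_um2 / 1e6))
  # 0 fibers -> convention zeros with flag
  empty <- suppressWarnings(segment_collagen(roi_image(matrix(0, 8, 8), 1)))
  mf0 <- morphological_features(extract_fibers(empty), empty)
  expect_true(all(mf0[-1] == 0))
  expect_true(attr(mf0, "degenerate"))
})

test_that("arrangement approaches 1 for isotropic fiber orientations", {
  # circular-variance Monte-Carlo at kappa = 0 needs many fibers
  vals <- vapply(1:3, function(s) {
    p <- fiber_field_params(n_fibers = 120, orientation_kappa = 0,
                            length_mean = 120, length_sd = 20,
                            background_noise_sd = 0, crosslink_rate = 0)
    sim <- simulate_fiber_image(p, s)
    fv <- extract_feature_vector(sim$image,
                                 pixel_size_um = sim$image$pixel_size_um)
    fv[["morph.arrangement"]]
  }, numeric(1))
  expect_gte(mean(vals), 0.8)
})

test_that("intensity features match closed forms on two-level images", {
  g <- matrix(c(100, 200), 16, 16)
  mask <- structure(list(mask = matrix(TRUE, 16, 16), pixel_size_um = 1,
                         collagen_area_um2 = 256, degenerate = FALSE),
                    class = "collagen_mask")
  iv <- intensity_features(roi_image(g, 1), mask)
  expect_equal(iv[["int.mean"]], 150)
  expect_equal(iv[["int.variance"]], 2500)
  expect_equal(iv[["int.skewness"]], 0)   # symmetric two-level
  expect_equal(iv[["int.entropy"]], 1)    # two equiprobable bins -> 1 bit
  expect_equal(iv[["int.energy"]], 0.5)
  # constant masked region: conventions
  gc <- matrix(100, 8, 8)
  maskc <- structure(list(mask = matrix(TRUE, 8, 8), pixel_size_um = 1,
                          collagen_area_um2 = 64, degenerate = FALSE),
                     class = "collagen_mask")
  ic <- intensity_features(roi_image(gc, 1), maskc)
  expect_equal(ic[["int.mean"]], 100)
  expect_equal(ic[["int.variance"]], 0)
  expect_equal(ic[["int.skewness"]], 0)
  expect_equal(ic[["int.kurtosis"]], 0)
  expect_equal(ic[["int.energy"]], 1)
  expect_equal(ic[["int.entropy"]], 0)
  expect_true(attr(ic, "degenerate"))
})

test_that("GLCM statistics match brute-force pair enumeration", {
  # 4x4 two-level checkerboard plus random small images
  cb <- matrix(rep(c(0, 255), 8), 4, 4)
  set.seed(3)
  imgs <- c(list(cb),
            lapply(1:5, function(i) matrix(sample(0:255, 36, TRUE), 6)))
  for (img in imgs) {
    fv <- glcm_features(img)
    for (d in 1:2) {
      for (a in c(0, 45, 90, 135)) {
        off <- oracle_glcm_offset(d, a)
        o <- oracle_glcm_stats(img, off[1], off[2])
        if (is.null(o)) next
        for (st in names(o)) {
          expect_equal(fv[[paste0("glcm.", st, ".d", d, ".a", a)]],
                       unname(o[[st]]), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("GLCM conventions hold on constant images and stripes are anisotropic", {
  fv <- glcm_features(matrix(7, 16, 16))
  for (d in 1:5) for (a in c(0, 45, 90, 135)) {
    expect_equal(fv[[paste0("glcm.contrast.d", d, ".a", a)]], 0)
    expect_equal(fv[[paste0("glcm.energy.d", d, ".a", a)]], 1)
    expect_equal(fv[[paste0("glcm.uniformity.d", d, ".a", a)]], 1)
    expect_equal(fv[[paste0("glcm.correlation.d", d, ".a", a)]], 0)
  }
  expect_true(attr(fv, "degenerate"))
  # vertical stripes vary along columns: contrast at 0 deg, none at 90 deg
  g <- matrix(rep(c(0, 255), each = 16), 16, 32, byrow = TRUE)
  fv2 <- glcm_features(g)
  expect_equal(fv2[["glcm.contrast.d1.a90"]], 0)
  expect_gt(fv2[["glcm.contrast.d1.a0"]], 0)
})

test_that("Gabor features match direct convolution and detect gratings", {
  n <- 64
  g <- matrix(0, n, n)
  for (c in 1:n) g[, c] <- 128 + 100 * sin(2 * pi * c / 8)
  gn <- g / 255
  fv <- gabor_features(g)
  # response magnitudes at sample pixels vs direct circular convolution
  K <- fft(gabor_kernel(n, n, 8, 0))
  resp <- fft(fft(gn) * K, inverse = TRUE) / (n * n)
  for (pt in list(c(9, 17), c(33, 50), c(60, 5))) {
    expect_equal(Mod(oracle_gabor_response(gn, 8, 0, pt[1], pt[2])),
                 Mod(resp[pt[1], pt[2]]), tolerance = 1e-6)
  }
  expect_equal(fv[["gabor.mean.s3.o1"]], mean(Mod(resp)), tolerance = 1e-6)
  # the orientation/scale-matched filter wins among all 24
  means <- unlist(lapply(1:4, function(s) {
    vapply(1:6, function(o) fv[[paste0("gabor.mean.s", s, ".o", o)]],
           numeric(1))
  }))
  expect_equal(which.max(means), 13) # s3 (lambda 8), o1 (0 deg)
  # constant image: no structure
  fvc <- gabor_features(matrix(100, 32, 32))
  for (s in 1:4) for (o in 1:6) {
    expect_lt(fvc[[paste0("gabor.variance.s", s, ".o", o)]], 1e-6)
  }
  # determinism
  expect_identical(gabor_features(g), fv)
})

test_that("90-degree rotation permutes GLCM angles and Gabor orientations", {
  set.seed(4)
  g <- matrix(runif(65 * 65, 0, 255), 65)
  gr <- rot90ccw(g)
  f1 <- glcm_features(g); f2 <- glcm_features(gr)
  for (st in c("contrast", "correlation", "energy", "uniformity")) {
    for (d in 1:5) {
      nm <- function(a) paste0("glcm.", st, ".d", d, ".a", a)
      expect_equal(f1[[nm(0)]], f2[[nm(90)]], tolerance = 1e-9)
      expect_equal(f1[[nm(90)]], f2[[nm(0)]], tolerance = 1e-9)
      expect_equal(f1[[nm(45)]], f2[[nm(135)]], tolerance = 1e-9)
      expect_equal(f1[[nm(135)]], f2[[nm(45)]], tolerance = 1e-9)
    }
  }
  g1 <- gabor_features(g); g2 <- gabor_features(gr)
  perm <- c(4, 5, 6, 1, 2, 3) # theta -> theta + 90 mod 180
  for (s in 1:4) for (o in 1:6) for (st in c("mean", "variance")) {
    expect_equal(g1[[paste0("gabor.", st, ".s", s, ".o", o)]],
                 g2[[paste0("gabor.", st, ".s", s, ".o", perm[o])]],
                 tolerance = 1e-9)
  }
  # intensity features are rotation-invariant
  mask1 <- segment_collagen(roi_image(g, 1), min_object_px = 1)
  mask2 <- segment_collagen(roi_image(gr, 1), min_object_px = 1)
  expect_equal(intensity_features(roi_image(g, 1), mask1),
               intensity_features(roi_image(gr, 1), mask2),
               ignore_attr = TRUE)
})

test_that("patient aggregation is the element-wise ROI mean", {
  v <- stats::setNames(rep(1, 142), feature_schema())
  expect_equal(aggregate_patient(replicate(5, v, simplify = FALSE)), v)
  vs <- lapply(c(0, 0, 0, 0, 10), function(x) {
    w <- v; w[["int.mean"]] <- x; w
  })
  expect_equal(aggregate_patient(vs)[["int.mean"]], 2)
  expect_warning(aggregate_patient(vs[1:3]), "expected 5")
  bad <- v; names(bad)[1] <- "other"
  expect_error(suppressWarnings(aggregate_patient(list(v, bad))), "schema")
})

test_that("feature monotonicity tracks the generative parameters", {
  # over seeds: crosslink_density rises with crosslink_rate,
  # arrangement falls with orientation_kappa (Spearman)
  rates <- c(0.1, 0.5, 1, 2)
  dens <- vapply(rates, function(cr) {
    mean(vapply(1:20, function(s) {
      p <- fiber_field_params(n_fibers = 12, crosslink_rate = cr,
                              image_size_px = 128)
      sim <- simulate_fiber_image(p, s)
      fv <- extract_feature_vector(sim$image,
                                   pixel_size_um = sim$image$pixel_size_um,
                                   spur_min_um = 12, fiber_min_um = 25)
      fv[["morph.crosslink_density"]]
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(rates, dens, method = "spearman"), 0.8)
  kappas <- c(0, 0.5, 2, 8)
  arr <- vapply(kappas, function(k) {
    mean(vapply(1:20, function(s) {
      p <- fiber_field_params(n_fibers = 12, orientation_kappa = k,
                              image_size_px = 128)
      sim <- simulate_fiber_image(p, s)
      fv <- extract_feature_vector(sim$image,
                                   pixel_size_um = sim$image$pixel_size_um,
                                   spur_min_um = 12, fiber_min_um = 25)
      fv[["morph.arrangement"]]
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(kappas, arr, method = "spearman"), -0.8)
})
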