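# Mask, skeleton, fiber tracing and crosslink detection.

test_that("grayscale conversion follows the channel-mean contract", {
  rgb <- array(10, c(4, 4, 3))
  expect_equal(to_grayscale(rgb, 1)$pixels, matrix(10, 4, 4))
  rgb2 <- array(0, c(2, 2, 3)); rgb2[, , 2] <- 30
  expect_equal(to_grayscale(rgb2, 1)$pixels, matrix(10, 2, 2))
  g <- matrix(runif(9), 3)
  expect_identical(to_grayscale(g, 1)$pixels, g)
  expect_error(to_grayscale(array(1, c(2, 2, 4)), 1), "channel")
})

test_that("Otsu segmentation separates a bimodal image exactly", {
  g <- matrix(0, 20, 20)
  g[, 11:20] <- 200
  m <- segment_collagen(roi_image(g, 2), min_object_px = 1)
  expect_identical(m$mask, g == 200)
  expect_equal(m$collagen_area_um2, 200 * 4)
})

test_that("degenerate images give an empty mask with a warning", {
  expect_warning(m <- segment_collagen(roi_image(matrix(0, 8, 8), 1)),
                 "constant|empty")
  expect_false(any(m$mask))
  expect_equal(m$collagen_area_um2, 0)
  expect_true(m$degenerate)
  fs <- extract_fibers(m)
  expect_length(fs$fibers, 0)
  expect_equal(nrow(fs$crosslinks), 0)
})

test_that("small objects are removed by component size", {
  g <- matrix(0, 30, 30)
  g[2:3, 2:3] <- 200          # 4 px blob
  g[10:20, 10:15] <- 200      # 66 px blob
  m <- segment_collagen(roi_image(g, 1), min_object_px = 16)
  expect_equal(sum(m$mask), 66)
})

test_that("segmentation covers simulated fiber pixels", {
  sim <- straight_fiber_sim()
  m <- segment_collagen(sim$image)
  gt <- sim$ground_truth$fibers[[1]]
  rc <- cbind(round(gt$rows), round(gt$cols))
  rc <- rc[rc[, 1] >= 1 & rc[, 1] <= 512 & rc[, 2] >= 1 & rc[, 2] <= 512, ]
  expect_gte(mean(m$mask[rc]), 0.95)
})

test_that("skeleton is thin, inside the mask, and spans fibers", {
  g <- matrix(0, 40, 40)
  g[18:22, 5:35] <- 200
  mask <- g > 100
  S <- skeletonize(mask)
  expect_true(all(mask[S]))
  expect_lt(sum(S), sum(mask) / 3)
  # all fiber centerline pixels lie on the skeleton
  fs <- extract_fibers(segment_collagen(roi_image(g, 2), min_object_px = 4))
  for (f in fs$fibers) {
    expect_true(all(fs$skeleton[f$centerline]))
  }
})

test_that("crossing fibers are merged through the junction", {
  n <- 128
  # plus: one horizontal and one vertical bar
  im <- matrix(0, n, n)
  for (d in -1:1) { im[64 + d, ] <- 200; im[, 64 + d] <- 200 }
  fs <- extract_fibers(segment_collagen(roi_image(im, 2), min_object_px = 4))
  expect_length(fs$fibers, 2)
  expect_equal(nrow(fs$crosslinks), 1)
  # X: two diagonals
  im2 <- matrix(0, n, n)
  for (i in 10:118) for (d in -1:1) {
    im2[i + d, i] <- 200; im2[i + d, n + 1 - i] <- 200
  }
  fs2 <- extract_fibers(segment_collagen(roi_image(im2, 2), min_object_px = 4))
  expect_length(fs2$fibers, 2)
  expect_equal(nrow(fs2$crosslinks), 1)
  expect_equal(detect_crosslinks(fs2), fs2$crosslinks)
})

test_that("a 2x2 fiber grid yields four crosslinks", {
  n <- 128
  im <- matrix(0, n, n)
  for (d in -1:1) {
    im[40 + d, ] <- 200; im[90 + d, ] <- 200
    im[, 40 + d] <- 200; im[, 90 + d] <- 200
  }
  fs <- extract_fibers(segment_collagen(roi_image(im, 2), min_object_px = 4))
  expect_length(fs$fibers, 4)
  expect_equal(nrow(fs$crosslinks), 4)
  # each crosslink sits near a true intersection
  truth <- rbind(c(40, 40), c(40, 90), c(90, 40), c(90, 90))
  d <- as.matrix(dist(rbind(fs$crosslinks, truth)))[1:4, 5:8]
  expect_lt(max(apply(d, 1, min)), 3)
})

test_that("rotating disjoint fibers by 90 degrees preserves the tracing", {
  n <- 200
  g <- matrix(0, n, n)
  for (d in -1:1) { g[30 + d, 20:120] <- 180; g[60:160, 150 + d] <- 180 }
  for (i in 100:180) for (d in -1:1) g[i + d, i - 60] <- 180
  f1 <- extract_fibers(segment_collagen(roi_image(g, 2)))
  f2 <- extract_fibers(segment_collagen(roi_image(rot90ccw(g), 2)))
  expect_equal(length(f1$fibers), length(f2$fibers))
  l1 <- mean(vapply(f1$fibers, `[[`, numeric(1), "length_um"))
  l2 <- mean(vapply(f2$fibers, `[[`, numeric(1), "length_um"))
  expect_lt(abs(l1 - l2) / l1, 0.02)
})

test_that("adding a disjoint fiber never decreases the fiber count", {
  n <- 128
  g <- matrix(0, n, n)
  for (d in -1:1) g[30 + d, 10:110] <- 180
  n1 <- length(extract_fibers(segment_collagen(roi_image(g, 2)))$fibers)
  g2 <- g
  for (d in -1:1) g2[90 + d, 10:110] <- 180
  n2 <- length(extract_fibers(segment_collagen(roi_image(g2, 2)))$fibers)
  expect_gte(n2, n1 + 1)
})

test_that("fiber width tracks the rendered profile and JSON export works", {
  sim <- straight_fiber_sim()
  fs <- extract_fibers(segment_collagen(sim$image))
  w <- fs$fibers[[1]]$mean_width_um
  expect_gt(w, 1)          # plausible physical width for a ~6 um fiber
  expect_lt(w, 15)
  path <- file.path(tempdir(), "fibers.json")
  write_fiber_set(fs, path)
  out <- jsonlite::read_json(path)
  expect_equal(out$n_fibers, 1)
  expect_equal(out$fibers[[1]]$length_um, fs$fibers[[1]]$length_um)
  unlink(path)
})
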