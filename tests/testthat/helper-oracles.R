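# Independent oracles and fixture builders shared across the suite.
# Everything here is deliberately written from first principles (pair
# enumeration, direct convolution, explicit formulas) so it can never share a
# code path with the implementation it checks.

rot90ccw <- function(m) t(m)[, nrow(m):1]

# Brute-force GLCM statistics by pair enumeration for one offset.
# Quantization: uniform binning of the observed range into G levels.
# Returns NULL for a constant image or an offset with no valid pair.
oracle_glcm_stats <- function(img, dr, dc, G = 32) {
  rng <- range(img)
  if (diff(rng) == 0) return(NULL)
  q <- floor((img - rng[1]) / (rng[2] - rng[1]) * G)
  q <- matrix(pmin(q, G - 1) + 1, nrow(img))
  pairs <- NULL
  for (r in seq_len(nrow(q))) {
    for (c in seq_len(ncol(q))) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        pairs <- rbind(pairs, c(q[r, c], q[r2, c2]), c(q[r2, c2], q[r, c]))
      }
    }
  }
  if (is.null(pairs)) return(NULL)
  P <- matrix(0, G, G)
  for (k in seq_len(nrow(pairs))) {
    P[pairs[k, 1], pairs[k, 2]] <- P[pairs[k, 1], pairs[k, 2]] + 1
  }
  P <- P / sum(P)
  i <- matrix(seq_len(G), G, G); j <- t(i)
  pi_ <- rowSums(P)
  mu <- sum(seq_len(G) * pi_)
  v <- sum((seq_len(G) - mu)^2 * pi_)
  c(contrast = sum((i - j)^2 * P),
    correlation = if (v < 1e-300) 0 else sum((i - mu) * (j - mu) * P) / v,
    energy = sum(P^2),
    uniformity = sum(P / (1 + (i - j)^2)))
}

# GLCM offsets by (distance, angle) in the package's convention.
oracle_glcm_offset <- function(d, angle) {
  switch(as.character(angle),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# Direct circular convolution of a [0,1] image with the Gabor kernel,
# evaluated at a single pixel. O(N^2) per pixel; only for tiny checks.
oracle_gabor_response <- function(gn, lambda, theta, r, c) {
  n <- nrow(gn)
  k <- gabor_kernel(n, n, lambda, theta)
  ridx <- ((r - seq_len(n)) %% n) + 1
  cidx <- ((c - seq_len(n)) %% n) + 1
  sum(gn * k[ridx, cidx])
}

# AUC by explicit enumeration of all positive-negative pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Clinical record generator with a continuous signature and known log-odds.
make_records <- function(n, seed,
                         beta = c(intercept = -1.5, signature = 1.6,
                                  size_gt1cm = 1.1, location_upper = 0.95,
                                  tci = 0.8)) {
  set.seed(seed)
  sig <- rnorm(n)
  size <- rbinom(n, 1, 0.47)
  loc <- rbinom(n, 1, 0.26)
  tci <- rbinom(n, 1, 0.49)
  lp <- beta[["intercept"]] + beta[["signature"]] * sig +
    beta[["size_gt1cm"]] * size + beta[["location_upper"]] * loc +
    beta[["tci"]] * tci
  data.frame(signature = sig, size_gt1cm = size, location_upper = loc,
             tci = tci, clnm = rbinom(n, 1, plogis(lp)))
}

# Synthetic 142-feature cohort: standard-normal features, five informative
# columns (named after the collagen features the original study retained,
# with matching coefficient signs), logistic outcome.
synth_feature_cohort <- function(n, seed, effect = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 142), n, 142,
              dimnames = list(NULL, feature_schema()))
  informative <- c("morph.crosslink_density", "morph.arrangement",
                   "int.mean", "glcm.contrast.d2.a45",
                   "gabor.variance.s2.o5")
  w <- c(1, -1, -0.8, -0.7, 0.9) * effect
  lp <- as.vector(X[, informative] %*% w)
  list(X = X, y = rbinom(n, 1, plogis(lp)), informative = informative,
       weights = w)
}

# A clean noiseless straight-fiber ROI at the default 512 resolution with the
# fiber fully inside the canvas (searches a few seeds).
straight_fiber_sim <- function(max_seed = 20) {
  p <- fiber_field_params(n_fibers = 1, curvature_sd = 0,
                          background_noise_sd = 0, length_sd = 0,
                          fiber_intensity_sd = 0, crosslink_rate = 0)
  for (s in seq_len(max_seed)) {
    sim <- simulate_fiber_image(p, s)
    gt <- sim$ground_truth$fibers[[1]]
    if (abs(gt$length_in_um - gt$length_um) < 1e-9 && gt$length_um > 150) {
      return(sim)
    }
  }
  stop("no fully inside straight fiber found")
}
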