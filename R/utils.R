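# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package operations do not
#' disturb the caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic integer mixing so that pipeline stages draw from decoupled
#' streams. Result is always in [1, 2^31 - 2].
#' @param seed master integer seed.
#' @param k stage index (any non-negative integer).
#' @return integer seed.
#' @export
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.numeric(k))
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.numeric(seed) %% m)
  for (i in seq_len(length(k))) {
    s <- (s * 48271 + as.numeric(k[i]) * 16807 + 1) %% m
  }
  as.integer(s + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Axial (undirected) angular difference between two axis angles, result in
# [0, pi/2]. Axes are equivalent mod pi.
axial_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# Mean axis of a set of angles (undirected), via the doubled-angle resultant.
# Returns angle in [0, pi).
axial_mean <- function(theta, w = NULL) {
  if (length(theta) == 0) return(0)
  if (is.null(w)) w <- rep(1, length(theta))
  s <- sum(w * sin(2 * theta))
  c_ <- sum(w * cos(2 * theta))
  (atan2(s, c_) / 2) %% pi
}

# Circular variance of doubled angles, weighted; in [0, 1]; 0 = aligned.
axial_dispersion <- function(theta, w = NULL) {
  if (length(theta) == 0) return(0)
  if (is.null(w)) w <- rep(1, length(theta))
  sw <- sum(w)
  if (sw <= 0) return(0)
  r <- sqrt(sum(w * cos(2 * theta))^2 + sum(w * sin(2 * theta))^2) / sw
  1 - r
}

# Sample from a von Mises distribution by Best & Fisher (1979) rejection.
# kappa = 0 reduces to uniform on (-pi, pi].
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    return(stats::runif(n, -pi, pi) + mu)
  }
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u1 <- stats::runif(1)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      u2 <- stats::runif(1)
      if (c_ * (2 - c_) - u2 > 0 || log(c_ / u2) + 1 - c_ >= 0) break
    }
    u3 <- stats::runif(1)
    out[i] <- sign(u3 - 0.5) * acos(f)
  }
  out + mu
}

# Inverse logit.
inv_logit <- function(x) 1 / (1 + exp(-x))
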