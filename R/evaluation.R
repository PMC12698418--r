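# Discrimination, calibration, comparison and clinical-utility metrics for
# probability-producing models.

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance that a random positive
#' outscores a random negative, with half credit for ties. Computed from
#' midranks.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance index for binary outcomes
#'
#' For a binary outcome the C-index equals the ROC AUC; this alias exists to
#' match reporting conventions.
#'
#' @inheritParams roc_auc
#' @return the C-index.
#' @export
c_index <- function(scores, labels) roc_auc(scores, labels)

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples positives and negatives separately (preserving prevalence) and
#' returns the 2.5/97.5 percentile interval of the metric over `B`
#' resamples. Resamples degenerating to a single class are redrawn (counted,
#' capped at `10 * B` attempts).
#'
#' @param metric_fn function of `(scores, labels)` returning a scalar.
#' @param scores,labels the data.
#' @param B number of resamples (study design: 1000).
#' @param seed integer seed.
#' @param level confidence level.
#' @return list: `low`, `high`, `point`, `B`, `redraws`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 1000, seed = 1,
                         level = 0.95) {
  stopifnot(B >= 100)
  labels <- as.integer(labels)
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  with_seed(seed, {
    vals <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- c(sample(pos, length(pos), replace = TRUE),
                 sample(neg, length(neg), replace = TRUE))
        if (length(unique(labels[idx])) == 2 || length(pos) == 0 ||
            length(neg) == 0) break
        redraws <- redraws + 1L
        if (redraws > 10L * B) stop("too many degenerate resamples")
      }
      vals[b] <- metric_fn(scores[idx], labels[idx])
    }
    a <- (1 - level) / 2
    # undefined resample metrics (e.g. PPV with no predicted positives)
    # drop out of the percentile computation
    q <- stats::quantile(vals, c(a, 1 - a), names = FALSE, type = 7,
                         na.rm = TRUE)
    list(low = q[1], high = q[2],
         point = metric_fn(scores, labels), B = B, redraws = redraws)
  })
}

# Placement values for DeLong: for each positive, the fraction of negatives
# it beats (ties half); and symmetrically for negatives.
delong_placements <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  rx <- rank(x)
  ry <- rank(y)
  v10 <- (r[seq_len(m)] - rx) / n          # per-positive placements
  v01 <- 1 - (r[m + seq_len(n)] - ry) / m  # per-negative placements
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for paired AUCs
#'
#' Compares the AUCs of two score vectors measured on the same subjects via
#' the DeLong placement-value covariance estimate and a two-sided normal
#' test. Degenerate zero-variance differences with zero AUC difference give
#' p = 1.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels (0/1).
#' @return list: `auc_a`, `auc_b`, `delta`, `se`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels))
  if (length(unique(labels)) < 2) stop("both outcome classes must be present")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- sum(labels == 1); n <- sum(labels == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- pa$auc - pb$auc
  if (var_delta <= .Machine$double.eps) {
    p <- if (abs(delta) <= .Machine$double.eps) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = 0,
                z = if (p == 1) 0 else sign(delta) * Inf, p = p))
  }
  z <- delta / sqrt(var_delta)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, se = sqrt(var_delta),
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Decision curve analysis
#'
#' Net benefit of treating at each threshold probability t:
#' `TP/n - FP/n * t/(1-t)`, classifying positive when the predicted
#' probability is >= t. Reference strategies: treat-all
#' (`prevalence - (1-prevalence) * t/(1-t)`) and treat-none (0).
#'
#' @param probs predicted probabilities in `[0, 1]`.
#' @param labels binary labels (0/1).
#' @param thresholds threshold grid, strictly inside (0, 1).
#' @return data.frame: threshold, net_benefit, treat_all, treat_none.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(all(probs >= 0 & probs <= 1))
  if (any(thresholds <= 0 | thresholds >= 1)) {
    stop("thresholds must lie strictly inside (0, 1)")
  }
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(thresholds, function(t) {
    pos <- probs >= t
    tp <- sum(pos & labels == 1)
    fp <- sum(pos & labels == 0)
    tp / n - fp / n * t / (1 - t)
  }, numeric(1))
  data.frame(
    threshold = thresholds,
    net_benefit = nb,
    treat_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    treat_none = 0
  )
}

#' Youden-optimal threshold
#'
#' The candidate threshold maximizing sensitivity + specificity - 1 over the
#' observed probabilities (midpoints between consecutive unique values).
#' Ties break toward the lower threshold.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @return threshold in (0, 1).
#' @export
youden_threshold <- function(probs, labels) {
  labels <- as.integer(labels)
  u <- sort(unique(probs))
  cand <- if (length(u) == 1) u else (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(t) {
    sens <- mean(probs[labels == 1] >= t)
    spec <- mean(probs[labels == 0] < t)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Confusion-matrix performance metrics with bootstrap CIs
#'
#' Sensitivity, specificity, PPV, NPV and accuracy at a decision threshold,
#' each with a stratified percentile bootstrap CI. The threshold is either a
#' fixed probability or Youden's J maximizer on a (training) set.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold in (0, 1) (e.g., from
#'   [youden_threshold()] on the training cohort).
#' @param B bootstrap resamples for the CIs.
#' @param seed integer seed.
#' @return object of class `classification_report`: data.frame `metrics`
#'   (metric, value, ci_low, ci_high), `threshold`, `confusion` (tp, fn, fp,
#'   tn).
#' @export
classification_metrics <- function(probs, labels, threshold, B = 1000,
                                   seed = 1) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must lie strictly inside (0, 1)")
  }
  labels <- as.integer(labels)
  conf <- function(p, y) {
    pos <- p >= threshold
    c(tp = sum(pos & y == 1), fn = sum(!pos & y == 1),
      fp = sum(pos & y == 0), tn = sum(!pos & y == 0))
  }
  metric_fns <- list(
    sensitivity = function(p, y) { k <- conf(p, y); k["tp"] / (k["tp"] + k["fn"]) },
    specificity = function(p, y) { k <- conf(p, y); k["tn"] / (k["tn"] + k["fp"]) },
    ppv = function(p, y) { k <- conf(p, y); k["tp"] / (k["tp"] + k["fp"]) },
    npv = function(p, y) { k <- conf(p, y); k["tn"] / (k["tn"] + k["fn"]) },
    accuracy = function(p, y) { k <- conf(p, y); (k["tp"] + k["tn"]) / sum(k) }
  )
  rows <- lapply(seq_along(metric_fns), function(i) {
    fn <- metric_fns[[i]]
    ci <- bootstrap_ci(function(s, l) unname(fn(s, l)), probs, labels, B = B,
                       seed = derive_seed(seed, i))
    data.frame(metric = names(metric_fns)[i], value = unname(ci$point),
               ci_low = ci$low, ci_high = ci$high, stringsAsFactors = FALSE)
  })
  structure(list(metrics = do.call(rbind, rows), threshold = threshold,
                 confusion = conf(probs, labels)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report at threshold %.3f>\n", x$threshold))
  m <- x$metrics
  cat(sprintf("  %-12s %5.1f%% (%.1f-%.1f)\n", m$metric, 100 * m$value,
              100 * m$ci_low, 100 * m$ci_high))
  invisible(x)
}

#' Calibration curve by risk quantile bins
#'
#' Bins predicted probabilities into quantile bins and compares the mean
#' prediction with the observed event frequency per bin. Empty bins are
#' merged with their neighbour by construction of quantile breaks.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param bins number of bins (>= 3).
#' @return data.frame: bin, n, predicted, observed.
#' @export
calibration_curve <- function(probs, labels, bins = 10) {
  stopifnot(bins >= 3)
  labels <- as.integer(labels)
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) br <- c(br - 1e-9, br + 1e-9)
  g <- cut(probs, br, include.lowest = TRUE)
  agg <- lapply(levels(g), function(lv) {
    i <- which(g == lv)
    data.frame(bin = lv, n = length(i), predicted = mean(probs[i]),
               observed = mean(labels[i]), stringsAsFactors = FALSE)
  })
  do.call(rbind, agg[vapply(agg, function(a) a$n > 0, logical(1))])
}

#' Full evaluation report for one model on one cohort
#'
#' AUC (= C-index for a binary outcome) with bootstrap CI, classification
#' metrics at the supplied threshold, calibration curve and decision curve.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param threshold decision threshold (typically Youden on training).
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return object of class `evaluation_report`.
#' @export
evaluate_model <- function(probs, labels, threshold, B = 1000, seed = 1) {
  auc_ci <- bootstrap_ci(roc_auc, probs, labels, B = B,
                         seed = derive_seed(seed, 101))
  structure(list(
    auc = auc_ci$point, auc_ci = c(auc_ci$low, auc_ci$high),
    c_index = c_index(probs, labels),
    classification = classification_metrics(probs, labels, threshold, B = B,
                                            seed = derive_seed(seed, 102)),
    calibration = calibration_curve(probs, labels),
    decision = decision_curve(probs, labels),
    threshold = threshold
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: AUC %.3f (%.3f-%.3f), threshold %.3f>\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$threshold))
  print(x$classification)
  invisible(x)
}
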