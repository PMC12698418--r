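# Discrimination, comparison, calibration and clinical-utility metrics.

test_that("AUC matches pairwise enumeration, ties get half credit", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(1)
  for (i in 1:10) {
    n <- sample(6:30, 1)
    s <- sample(1:8, n, replace = TRUE) # ties on purpose
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(roc_auc(s, y), oracle_auc(s, y))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both outcome classes")
  # invariance under strictly monotone transforms
  set.seed(2)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5)
  expect_equal(roc_auc(s, y), roc_auc(exp(3 * s) + 2, y))
  # C-index alias
  expect_identical(c_index(s, y), roc_auc(s, y))
})

test_that("bootstrap CI is seeded, stratified, and sane", {
  set.seed(5)
  s <- c(rnorm(60), rnorm(60, 1.2))
  y <- rep(c(0, 1), each = 60)
  ci1 <- bootstrap_ci(roc_auc, s, y, B = 300, seed = 4)
  ci2 <- bootstrap_ci(roc_auc, s, y, B = 300, seed = 4)
  expect_identical(ci1, ci2)
  expect_lt(ci1$low, ci1$point)
  expect_gt(ci1$high, ci1$point)
  # constant metric -> zero-width interval
  cic <- bootstrap_ci(function(s, l) 0.7, s, y, B = 100, seed = 1)
  expect_equal(cic$low, 0.7)
  expect_equal(cic$high, 0.7)
  # midpoint agrees with the asymptotic (Hanley-McNeil) interval
  auc <- roc_auc(s, y)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + 59 * (q1 - auc^2) + 59 * (q2 - auc^2)) /
               (60 * 60))
  expect_lt(ci1$low, auc)
  expect_gt(ci1$high, auc)
  expect_lt(abs((ci1$low + ci1$high) / 2 - auc), se)
})

test_that("DeLong test matches its contracts and a permutation oracle", {
  set.seed(6)
  y <- rep(c(0, 1), each = 25)
  a <- rnorm(50) + y
  expect_equal(delong_test(a, a, y)$p, 1)
  expect_equal(delong_test(a, a, y)$delta, 0)
  b <- rnorm(50) + 0.5 * y
  d1 <- delong_test(a, b, y)
  d2 <- delong_test(b, a, y)
  expect_equal(d1$delta, -d2$delta)
  expect_equal(d1$p, d2$p)
  # small-sample agreement with a sign-flip permutation oracle
  set.seed(7)
  y20 <- rep(c(0, 1), each = 10)
  s_a <- rnorm(20) + 0.8 * y20
  s_b <- rnorm(20) + 0.3 * y20
  obs <- abs(delong_test(s_a, s_b, y20)$delta)
  perm <- replicate(1e5, {
    swap <- runif(20) < 0.5
    pa <- ifelse(swap, s_b, s_a)
    pb <- ifelse(swap, s_a, s_b)
    abs(roc_auc(pa, y20) - roc_auc(pb, y20))
  })
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(delong_test(s_a, s_b, y20)$p - p_perm), 0.02)
})

test_that("AUC and the DeLong test agree with an established reference", {
  set.seed(33)
  y <- rep(c(0, 1), each = 40)
  a <- rnorm(80) + 0.9 * y
  b <- rnorm(80) + 0.4 * y
  ra <- pROC::roc(y, a, levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(y, b, levels = c(0, 1), direction = "<", quiet = TRUE)
  expect_equal(roc_auc(a, y), as.numeric(pROC::auc(ra)))
  dl <- delong_test(a, b, y)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-12)
  expect_equal(dl$delta,
               as.numeric(pROC::auc(ra)) - as.numeric(pROC::auc(rb)),
               tolerance = 1e-12)
})

test_that("decision curves follow the closed forms", {
  set.seed(8)
  y <- rbinom(200, 1, 0.41)
  p <- runif(200)
  dc <- decision_curve(p, y, thresholds = c(0.1, 0.3, 0.5))
  prev <- mean(y)
  expect_equal(dc$treat_none, rep(0, 3))
  expect_equal(dc$treat_all,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  expect_true(all(dc$net_benefit <= prev + 1e-12))
  # perfect predictor: net benefit = prevalence below every positive prob
  pp <- ifelse(y == 1, 0.9, 0.05)
  dcp <- decision_curve(pp, y, thresholds = c(0.1, 0.3, 0.5))
  expect_equal(dcp$net_benefit, rep(prev, 3))
  # probs identically 1 reproduce treat-all
  dca <- decision_curve(rep(1, 200), y, thresholds = c(0.2, 0.4))
  expect_equal(dca$net_benefit, dca$treat_all)
  expect_error(decision_curve(p, y, thresholds = c(0, 0.5)), "strictly")
})

test_that("classification metrics match hand arithmetic on a fixed table", {
  # confusion (TP, FN, FP, TN) = (76, 10, 30, 71) at threshold 0.5
  probs <- c(rep(0.9, 76), rep(0.1, 10), rep(0.9, 30), rep(0.1, 71))
  labels <- c(rep(1, 86), rep(0, 101))
  rep_ <- classification_metrics(probs, labels, threshold = 0.5, B = 200,
                                 seed = 1)
  m <- rep_$metrics
  expect_equal(unname(rep_$confusion), c(76, 10, 30, 71))
  expect_equal(m$value[m$metric == "sensitivity"], 76 / 86)
  expect_equal(m$value[m$metric == "specificity"], 71 / 101)
  expect_equal(m$value[m$metric == "ppv"], 76 / 106)
  expect_equal(m$value[m$metric == "npv"], 71 / 81)
  expect_equal(m$value[m$metric == "accuracy"], 147 / 187)
  expect_true(all(m$ci_low <= m$value & m$value <= m$ci_high))
  # perfect classifier
  pperf <- classification_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0),
                                  threshold = 0.5, B = 100, seed = 2)
  expect_true(all(pperf$metrics$value == 1))
  expect_error(classification_metrics(probs, labels, threshold = 1.2),
               "threshold")
})

test_that("Youden threshold maximizes sensitivity + specificity - 1", {
  probs <- c(0.1, 0.2, 0.6, 0.7, 0.8)
  labels <- c(0, 0, 1, 1, 1)
  t <- youden_threshold(probs, labels)
  expect_gt(t, 0.2)
  expect_lt(t, 0.6)
})

test_that("calibration curves sit on the diagonal when probabilities are true", {
  set.seed(9)
  p <- runif(2000)
  y <- rbinom(2000, 1, p)
  cal <- calibration_curve(p, y, bins = 10)
  expect_lte(max(abs(cal$predicted - cal$observed)), 0.1)
  expect_equal(sum(cal$n), 2000)
  # constant prob p with prevalence p: single point (p, ~p)
  calc <- calibration_curve(rep(0.4, 500), rbinom(500, 1, 0.4))
  expect_equal(nrow(calc), 1)
  expect_equal(calc$predicted, 0.4)
  expect_error(calibration_curve(p, y, bins = 2), "bins")
})

test_that("random rankings give chance-level concordance", {
  set.seed(10)
  cs <- replicate(20, c_index(rnorm(1000), rbinom(1000, 1, 0.5)))
  expect_lt(max(abs(cs - 0.5)), 0.05)
})
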