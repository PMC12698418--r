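# Clinical modeling: cohort splitting, univariate and multivariate logistic
# association with CLNM, and the points-based nomogram re-parameterization of
# the multivariate model.

#' Split a cohort into training and testing sets
#'
#' Simple random assignment with `round(ratio * n)` patients in training,
#' seeded and recorded.
#'
#' @param records data.frame of patient records.
#' @param ratio training fraction (study design: 0.6).
#' @param seed integer seed.
#' @return list with `train`, `test` (data.frames) and `train_idx`.
#' @export
split_cohort <- function(records, ratio = 0.6, seed = 1) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("need at least 2 records to split")
  n_train <- round(ratio * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  idx <- sort(idx)
  list(train = records[idx, , drop = FALSE],
       test = records[-idx, , drop = FALSE],
       train_idx = idx)
}

# One Wald association row from a fitted glm, for the named coefficient.
wald_row <- function(fit, term, level = 0.95) {
  sm <- summary(fit)$coefficients
  est <- sm[term, "Estimate"]
  se <- sm[term, "Std. Error"]
  zq <- stats::qnorm(1 - (1 - level) / 2)
  unstable <- !is.finite(se) || se > 10 || abs(est) > 10
  data.frame(
    variable = term,
    or = exp(est),
    ci_low = exp(est - zq * se),
    ci_high = exp(est + zq * se),
    p = sm[term, "Pr(>|z|)"],
    log_or = est, se = se,
    unstable = unstable,
    stringsAsFactors = FALSE
  )
}

#' Univariate logistic association with the outcome
#'
#' Single-predictor logistic regression of the binary outcome on one
#' variable; reports the Wald odds ratio, 95% CI and p-value. Perfect or
#' quasi-perfect separation is flagged via the `unstable` column rather than
#' silently reported.
#'
#' @param records data.frame.
#' @param variable predictor column name (binary or scalar).
#' @param outcome outcome column name (0/1).
#' @return one-row data.frame: variable, or, ci_low, ci_high, p, log_or, se,
#'   unstable.
#' @export
univariate_logistic <- function(records, variable, outcome = "clnm") {
  x <- records[[variable]]
  y <- records[[outcome]]
  if (is.null(x)) stop("unknown variable: ", variable)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (length(unique(x)) < 2) stop("predictor '", variable, "' is constant")
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(variable, response = outcome),
               data = records, family = stats::binomial()))
  row <- wald_row(fit, variable)
  if (!fit$converged) row$unstable <- TRUE
  row
}

#' Multivariate logistic model of CLNM
#'
#' Joint logistic fit of the outcome on a set of variables (the prespecified
#' study set is collagen signature, tumor location, tumor size and thyroid
#' capsular invasion), with per-variable adjusted Wald OR/CI/p.
#' Separation and collinearity are flagged, not hidden.
#'
#' @param records data.frame.
#' @param variables character vector of predictor column names.
#' @param outcome outcome column name (0/1).
#' @return object of class `clnm_model`: `fit` (glm), `associations`
#'   (data.frame, one row per variable), `variables`, `outcome`.
#' @export
multivariate_logistic <- function(records, variables, outcome = "clnm") {
  stopifnot(length(variables) >= 1)
  missing <- setdiff(c(variables, outcome), names(records))
  if (length(missing) > 0) stop("unknown column(s): ",
                                paste(missing, collapse = ", "))
  if (nrow(records) <= length(variables)) {
    stop("need more records than predictors")
  }
  X <- as.matrix(records[, variables, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    stop("collinear predictors: design matrix is rank-deficient")
  }
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(variables, response = outcome),
               data = records, family = stats::binomial()))
  assoc <- do.call(rbind, lapply(variables, function(v) wald_row(fit, v)))
  if (!fit$converged) assoc$unstable <- TRUE
  structure(list(fit = fit, associations = assoc, variables = variables,
                 outcome = outcome),
            class = "clnm_model")
}

#' @export
print.clnm_model <- function(x, ...) {
  cat(sprintf("<clnm_model: %s ~ %s>\n", x$outcome,
              paste(x$variables, collapse = " + ")))
  a <- x$associations
  cat(sprintf("  %-18s OR %6.3f (%.3f-%.3f)  p=%.4g%s\n", a$variable, a$or,
              a$ci_low, a$ci_high, a$p,
              ifelse(a$unstable, "  [unstable]", "")))
  invisible(x)
}

#' Predicted probabilities from a CLNM model
#'
#' @param object a `clnm_model`.
#' @param newdata data.frame with the model's variables.
#' @param ... unused.
#' @return numeric vector of predicted probabilities.
#' @export
predict.clnm_model <- function(object, newdata, ...) {
  as.vector(stats::predict(object$fit, newdata = newdata, type = "response"))
}

#' Build a points-based nomogram from a fitted logistic model
#'
#' Standard construction: each variable's contribution `beta * x` is mapped
#' linearly to points, anchored so the least risky observed value scores 0
#' points, and scaled so the variable with the largest coefficient span over
#' the training data gets 100 points. Total points map back to probability
#' through the logistic function; by construction the nomogram probability
#' is identical to the model's.
#'
#' @param model a `clnm_model` (fitted on the training cohort).
#' @param data data.frame fixing the observed variable ranges (defaults to
#'   the model's training frame).
#' @return object of class `clnm_nomogram`: per-variable `ref` (zero-point
#'   anchor value of `beta * x`), `points_per_unit` scale, coefficient table,
#'   and the `total points -> probability` map parameters.
#' @export
build_nomogram <- function(model, data = NULL) {
  stopifnot(inherits(model, "clnm_model"))
  data <- data %||% model$fit$model
  beta <- stats::coef(model$fit)
  vars <- model$variables
  contrib_range <- vapply(vars, function(v) {
    r <- range(beta[[v]] * data[[v]])
    r
  }, numeric(2))
  span <- contrib_range[2, ] - contrib_range[1, ]
  max_span <- max(span)
  if (max_span <= 0) stop("all variables are constant in 'data'")
  scale <- 100 / max_span # points per log-odds unit
  structure(list(
    variables = vars,
    beta = beta,
    ref = contrib_range[1, ], # beta*x at the 0-point anchor, per variable
    scale = scale,
    span_points = span * scale,
    intercept = unname(beta["(Intercept)"])
  ), class = "clnm_nomogram")
}

#' Per-variable nomogram points for records
#'
#' @param nomo a `clnm_nomogram`.
#' @param records data.frame with the nomogram's variables.
#' @return matrix of points, one column per variable plus a `total` column.
#' @export
nomogram_points <- function(nomo, records) {
  stopifnot(inherits(nomo, "clnm_nomogram"))
  pts <- vapply(nomo$variables, function(v) {
    (nomo$beta[[v]] * records[[v]] - nomo$ref[[v]]) * nomo$scale
  }, numeric(nrow(records)))
  pts <- matrix(pts, nrow = nrow(records),
                dimnames = list(NULL, nomo$variables))
  cbind(pts, total = rowSums(pts))
}

#' Nomogram-predicted probability
#'
#' Maps total points back to probability; equals the underlying logistic
#' model's prediction to numerical precision.
#'
#' @param nomo a `clnm_nomogram`.
#' @param records data.frame with the nomogram's variables.
#' @return numeric vector of probabilities.
#' @export
nomogram_predict <- function(nomo, records) {
  total <- nomogram_points(nomo, records)[, "total"]
  lp <- nomo$intercept + sum(nomo$ref) + total / nomo$scale
  inv_logit(lp)
}

#' Association table across a set of variables
#'
#' Convenience wrapper running [univariate_logistic()] for each variable.
#'
#' @param records data.frame.
#' @param variables character vector.
#' @param outcome outcome column name.
#' @return data.frame, one row per variable.
#' @export
univariate_table <- function(records, variables, outcome = "clnm") {
  do.call(rbind, lapply(variables, function(v) {
    univariate_logistic(records, v, outcome)
  }))
}
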