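# Collagen signature: training-cohort-only Z-score normalization and
# 5-fold cross-validated LASSO logistic feature selection; the signature is
# the linear predictor of the selected, standardized features.

#' Fit a train-only Z-score normalizer
#'
#' Per-feature means and sample standard deviations are estimated on the
#' training rows only and then applied unchanged to any other cohort (the
#' no-leakage contract). Zero-variance features are dropped with a warning
#' and recorded.
#'
#' @param train_features numeric matrix, patients x features, with column
#'   names.
#' @return object of class `collagen_normalizer`: `mean`, `sd` (named, for
#'   retained features) and `dropped` (names of zero-variance features).
#' @export
fit_normalizer <- function(train_features) {
  stopifnot(is.matrix(train_features), nrow(train_features) >= 2,
            !is.null(colnames(train_features)))
  mu <- colMeans(train_features)
  sd_ <- apply(train_features, 2, stats::sd)
  dropped <- colnames(train_features)[sd_ <= .Machine$double.eps]
  if (length(dropped) > 0) {
    warning("dropping ", length(dropped), " zero-variance feature(s): ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ..." else "")
  }
  keep <- setdiff(colnames(train_features), dropped)
  structure(list(mean = mu[keep], sd = sd_[keep], dropped = dropped),
            class = "collagen_normalizer")
}

#' Apply a fitted normalizer
#'
#' @param normalizer a `collagen_normalizer`.
#' @param features matrix (rows = patients) or single named vector containing
#'   at least the retained features.
#' @return matrix of Z-scores over the retained features (in normalizer
#'   order).
#' @export
apply_normalizer <- function(normalizer, features) {
  stopifnot(inherits(normalizer, "collagen_normalizer"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL,
                                                                 names(features)))
  nm <- names(normalizer$mean)
  missing <- setdiff(nm, colnames(features))
  if (length(missing) > 0) stop("missing features: ",
                                paste(utils::head(missing, 5), collapse = ", "))
  x <- features[, nm, drop = FALSE]
  sweep(sweep(x, 2, normalizer$mean, "-"), 2, normalizer$sd, "/")
}

#' @export
print.collagen_normalizer <- function(x, ...) {
  cat(sprintf("<collagen_normalizer: %d features retained, %d dropped>\n",
              length(x$mean), length(x$dropped)))
  invisible(x)
}

# Stratified fold assignment: labels of each class are dealt round-robin to
# folds in a seeded random order.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      foldid[idx] <- rep_len(seq_len(k), length(idx))
    }
    foldid
  })
}

#' Fit the LASSO logistic collagen signature
#'
#' L1-penalized logistic regression (via glmnet) on the standardized training
#' matrix. The penalty grid has `n_lambda` values log-spaced from the
#' smallest all-zero penalty down by a factor of `lambda_min_ratio`; the
#' optimum minimizes the mean cross-validated binomial deviance over
#' `folds` label-stratified, seeded folds. Nonzero-coefficient features at
#' the optimum form the selected set.
#'
#' @param x standardized numeric matrix, training patients x features.
#' @param y binary outcome vector (0/1).
#' @param folds number of CV folds (study design: 5).
#' @param seed integer seed controlling fold assignment.
#' @param n_lambda grid size.
#' @param lambda_min_ratio ratio of smallest to largest penalty.
#' @param lambda optional explicit penalty grid overriding the automatic one.
#' @return object of class `collagen_signature`: `features` (selected names),
#'   `coefficients`, `intercept`, `lambda`, `log_lambda`, `folds`, `foldid`,
#'   `seed`, `cv_deviance` (mean CV deviance per grid point) and the glmnet
#'   fit.
#' @export
fit_lasso_signature <- function(x, y, folds = 5, seed = 1,
                                n_lambda = 100, lambda_min_ratio = 1e-4,
                                lambda = NULL) {
  stopifnot(is.matrix(x), length(y) == nrow(x))
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome has a single class")
  if (nrow(x) < folds) stop("fewer patients than folds")
  if (is.null(lambda)) {
    # smallest penalty that zeroes all coefficients for centered y
    lmax <- max(abs(crossprod(x, y - mean(y)))) / nrow(x)
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = n_lambda))
  }
  foldid <- stratified_folds(y, folds, seed)
  cv <- glmnet::cv.glmnet(x, y, family = "binomial", lambda = lambda,
                          foldid = foldid, type.measure = "deviance",
                          standardize = FALSE)
  lam <- cv$lambda.min
  cf <- as.matrix(stats::coef(cv$glmnet.fit, s = lam))
  sel <- rownames(cf)[-1][abs(cf[-1, 1]) > 0]
  structure(list(
    features = sel,
    coefficients = stats::setNames(cf[-1, 1][abs(cf[-1, 1]) > 0], sel),
    intercept = cf[1, 1],
    lambda = lam, log_lambda = log(lam),
    folds = folds, foldid = foldid, seed = seed,
    cv_deviance = stats::setNames(cv$cvm, signif(cv$lambda, 6)),
    fit = cv$glmnet.fit
  ), class = "collagen_signature")
}

#' @export
print.collagen_signature <- function(x, ...) {
  cat(sprintf(
    "<collagen_signature: %d features selected, log(lambda) = %.3f>\n",
    length(x$features), x$log_lambda))
  if (length(x$features) > 0) {
    print(round(x$coefficients, 4))
  }
  invisible(x)
}

#' Compute the scalar collagen signature
#'
#' The standard linear formula: intercept plus the sum of the selected
#' features' coefficients times their Z-scores under the (training-fitted)
#' normalizer. A pure function of its inputs.
#'
#' @param model a `collagen_signature`.
#' @param features raw feature matrix or single named vector.
#' @param normalizer the `collagen_normalizer` fitted on the training cohort.
#' @return numeric vector of signatures, one per row of `features`.
#' @export
compute_signature <- function(model, features, normalizer) {
  stopifnot(inherits(model, "collagen_signature"),
            inherits(normalizer, "collagen_normalizer"))
  z <- apply_normalizer(normalizer, features)
  missing <- setdiff(model$features, colnames(z))
  if (length(missing) > 0) stop("missing selected feature(s): ",
                                paste(missing, collapse = ", "))
  if (length(model$features) == 0) {
    return(rep(model$intercept, nrow(z)))
  }
  as.vector(model$intercept +
              z[, model$features, drop = FALSE] %*% model$coefficients)
}

#' Serialize a signature model and normalizer to JSON
#'
#' @param model a `collagen_signature`.
#' @param normalizer a `collagen_normalizer`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_signature_model <- function(model, normalizer, path) {
  out <- list(
    selected_features = model$features,
    coefficients = as.list(model$coefficients),
    intercept = model$intercept,
    lambda = model$lambda, log_lambda = model$log_lambda,
    cv_folds = model$folds, foldid = model$foldid, seed = model$seed,
    normalizer = list(mean = as.list(normalizer$mean),
                      sd = as.list(normalizer$sd),
                      dropped = normalizer$dropped)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
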