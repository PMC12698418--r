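# End-to-end orchestration: simulate (or load) -> extract -> split -> fit
# signature -> fit clinical models -> evaluate, with a validated config, a
# master seed spawning per-stage seeds, and all intermediates persisted.

pipeline_defaults <- function() {
  list(
    seed = 1,
    simulation = list(
      n_patients = 350, rois_per_patient = 5, image_size_px = 512,
      n_fibers = 60
    ),
    segmentation = list(
      min_object_px = 16, spur_min_um = 4, node_merge_um = 3,
      merge_angle_tol = 20, fiber_min_um = 10
    ),
    texture = list(n_gray = 32),
    split = list(ratio = 0.6),
    signature = list(folds = 5, n_lambda = 100, lambda_min_ratio = 1e-4),
    model = list(
      variables = c("signature", "location_upper", "size_gt1cm", "tci"),
      clinical_variables = c("location_upper", "size_gt1cm", "tci"),
      full_variable_entry = FALSE
    ),
    evaluation = list(bootstrap = 1000, threshold_rule = "youden_on_train",
                      fixed_threshold = NA),
    output = list(write_images = FALSE, figures = FALSE)
  )
}

check_config_keys <- function(config, defaults, path = "") {
  extra <- setdiff(names(config), names(defaults))
  if (length(extra) > 0) {
    stop("unknown config key(s): ",
         paste0(path, extra, collapse = ", "))
  }
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(config[[k]])) stop("config key '", path, k,
                                      "' must be a list")
      check_config_keys(config[[k]], defaults[[k]], paste0(path, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(config, defaults) {
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(config[[k]], defaults[[k]])
    } else {
      defaults[[k]] <- config[[k]]
    }
  }
  defaults
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults and overrides them with the supplied
#' nested list; unknown keys are rejected with a message. The config plus the
#' master seed fully reproduce a run.
#'
#' @param ... nested named overrides, e.g.
#'   `simulation = list(n_patients = 100)`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  override <- list(...)
  defaults <- pipeline_defaults()
  check_config_keys(override, defaults)
  cfg <- merge_config(override, defaults)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full collagen-signature pipeline
#'
#' Simulates a cohort (or consumes a supplied one), extracts the 142
#' collagen features per ROI, averages to patient level, splits 6:4,
#' standardizes on the training cohort only, fits the LASSO signature, fits
#' the integrated (signature + clinical) and clinical-only logistic models,
#' builds the nomogram and evaluates both models on both cohorts. All
#' intermediates are written under `out_dir` when given.
#'
#' Per-stage seeds are derived deterministically from the master seed so the
#' stages draw from decoupled streams.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; created if missing.
#' @param cohort optional pre-built `collagen_cohort` (overrides the
#'   simulation stage).
#' @return object of class `pipeline_result`: cohort, features, split,
#'   normalizer, signature model, clinical models, nomogram, evaluation
#'   reports and the threshold used.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  if (is.null(cohort)) {
    cp <- cohort_params(
      n_patients = config$simulation$n_patients,
      rois_per_patient = config$simulation$rois_per_patient,
      image_size_px = config$simulation$image_size_px,
      aggressiveness_to_fiber_map = default_aggressiveness_map(
        config$simulation$image_size_px, config$simulation$n_fibers)
    )
    cohort <- simulate_cohort(cp, derive_seed(seed, 11))
  }
  seg <- config$segmentation
  feats <- cohort_features(
    cohort,
    min_object_px = seg$min_object_px, spur_min_um = seg$spur_min_um,
    node_merge_um = seg$node_merge_um,
    merge_angle_tol = seg$merge_angle_tol,
    fiber_min_um = seg$fiber_min_um, n_gray = config$texture$n_gray
  )
  records <- cohort$patients
  sp <- split_cohort(records, ratio = config$split$ratio,
                     seed = derive_seed(seed, 12))
  train_idx <- sp$train_idx
  normalizer <- fit_normalizer(feats[train_idx, , drop = FALSE])
  sig_model <- fit_lasso_signature(
    apply_normalizer(normalizer, feats[train_idx, , drop = FALSE]),
    records$clnm[train_idx],
    folds = config$signature$folds, seed = derive_seed(seed, 13),
    n_lambda = config$signature$n_lambda,
    lambda_min_ratio = config$signature$lambda_min_ratio
  )
  records$signature <- compute_signature(sig_model, feats, normalizer)
  train <- records[train_idx, , drop = FALSE]
  test <- records[-train_idx, , drop = FALSE]

  vars <- if (isTRUE(config$model$full_variable_entry)) {
    c("signature", "age_gt50", "male", "bmi_gt23", "multifocal",
      "size_gt1cm", "location_upper", "tci")
  } else config$model$variables
  integrated <- multivariate_logistic(train, vars)
  clinical <- multivariate_logistic(train, config$model$clinical_variables)
  nomogram <- build_nomogram(integrated, train)

  p_int_train <- predict(integrated, train)
  p_int_test <- predict(integrated, test)
  p_cli_train <- predict(clinical, train)
  p_cli_test <- predict(clinical, test)

  thr <- if (identical(config$evaluation$threshold_rule, "fixed")) {
    config$evaluation$fixed_threshold
  } else {
    youden_threshold(p_int_train, train$clnm)
  }
  B <- config$evaluation$bootstrap
  reports <- list(
    integrated_train = evaluate_model(p_int_train, train$clnm, thr, B = B,
                                      seed = derive_seed(seed, 21)),
    integrated_test = evaluate_model(p_int_test, test$clnm, thr, B = B,
                                     seed = derive_seed(seed, 22)),
    clinical_train = evaluate_model(p_cli_train, train$clnm,
                                    clamp(thr, 0.01, 0.99), B = B,
                                    seed = derive_seed(seed, 23)),
    clinical_test = evaluate_model(p_cli_test, test$clnm,
                                   clamp(thr, 0.01, 0.99), B = B,
                                   seed = derive_seed(seed, 24))
  )
  sig_auc <- list(
    train = roc_auc(train$signature, train$clnm),
    test = roc_auc(test$signature, test$clnm)
  )
  delong <- list(
    train = delong_test(p_int_train, p_cli_train, train$clnm),
    test = delong_test(p_int_test, p_cli_test, test$clnm)
  )

  result <- structure(list(
    config = config, cohort = cohort, features = feats, split = sp,
    records = records, normalizer = normalizer, signature_model = sig_model,
    integrated_model = integrated, clinical_model = clinical,
    nomogram = nomogram, threshold = thr, signature_auc = sig_auc,
    reports = reports, delong = delong
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir)
    if (isTRUE(config$output$write_images)) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
      for (i in seq_len(nrow(cohort$patients))) {
        sims <- patient_roi_images(cohort, i, with_ground_truth = TRUE)
        for (r in seq_along(sims)) {
          write_roi_image(sims[[r]], file.path(img_dir, sprintf(
            "%s_roi%d.tif", cohort$patients$patient_id[i], r)))
        }
      }
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    paste0("<pipeline_result: %d patients (train %d / test %d), ",
           "%d features selected>\n"),
    nrow(x$records), nrow(x$split$train), nrow(x$split$test),
    length(x$signature_model$features)))
  cat(sprintf("  signature AUC: train %.3f, test %.3f\n",
              x$signature_auc$train, x$signature_auc$test))
  cat(sprintf("  integrated vs clinical test AUC: %.3f vs %.3f (p=%.3g)\n",
              x$reports$integrated_test$auc, x$reports$clinical_test$auc,
              x$delong$test$p))
  invisible(x)
}

# Persist every pipeline intermediate under out_dir.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)
  write_feature_table(result$features, fp("features_patient.csv"))
  cohort_df <- result$records
  utils::write.csv(cohort_df, fp("cohort.csv"), row.names = FALSE)
  write_signature_model(result$signature_model, result$normalizer,
                        fp("signature_model.json"))
  utils::write.csv(result$integrated_model$associations,
                   fp("multivariate_associations.csv"), row.names = FALSE)
  t3 <- rbind(
    cbind(cohort = "train",
          result$reports$integrated_train$classification$metrics),
    cbind(cohort = "test",
          result$reports$integrated_test$classification$metrics)
  )
  utils::write.csv(t3, fp("performance_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$reports$integrated_train$decision,
                   fp("decision_curve_train.csv"), row.names = FALSE)
  utils::write.csv(result$reports$integrated_test$decision,
                   fp("decision_curve_test.csv"), row.names = FALSE)
  utils::write.csv(result$reports$integrated_train$calibration,
                   fp("calibration_train.csv"), row.names = FALSE)
  utils::write.csv(result$reports$integrated_test$calibration,
                   fp("calibration_test.csv"), row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("collagensig")),
    seed = result$config$seed,
    config = unclass(result$config),
    n_patients = nrow(result$records),
    n_train = nrow(result$split$train), n_test = nrow(result$split$test),
    threshold = result$threshold,
    selected_features = result$signature_model$features,
    log_lambda = result$signature_model$log_lambda,
    auc = list(
      signature_train = result$signature_auc$train,
      signature_test = result$signature_auc$test,
      integrated_train = result$reports$integrated_train$auc,
      integrated_test = result$reports$integrated_test$auc,
      clinical_train = result$reports$clinical_train$auc,
      clinical_test = result$reports$clinical_test$auc
    ),
    delong_p = list(train = result$delong$train$p,
                    test = result$delong$test$p)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  if (isTRUE(result$config$output$figures)) {
    write_pipeline_figures(result, out_dir)
  }
  invisible(out_dir)
}

# Diagnostic figures (ROC, calibration, decision curves) as PNG.
write_pipeline_figures <- function(result, out_dir) {
  fp <- function(...) file.path(out_dir, ...)
  test <- result$records[-result$split$train_idx, ]
  p_int <- predict(result$integrated_model, test)
  p_cli <- predict(result$clinical_model, test)
  grDevices::png(fp("roc_test.png"), width = 600, height = 600)
  plot_roc(list(integrated = p_int, clinical = p_cli), test$clnm)
  grDevices::dev.off()
  grDevices::png(fp("calibration_test.png"), width = 600, height = 600)
  cal <- result$reports$integrated_test$calibration
  plot(cal$predicted, cal$observed, xlim = 0:1, ylim = 0:1,
       xlab = "Predicted probability", ylab = "Observed frequency",
       pch = 19, main = "Calibration (test)")
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  grDevices::png(fp("decision_test.png"), width = 600, height = 600)
  dc <- result$reports$integrated_test$decision
  plot(dc$threshold, dc$net_benefit, type = "l", lwd = 2,
       xlab = "Threshold probability", ylab = "Net benefit",
       main = "Decision curve (test)",
       ylim = range(c(dc$net_benefit, dc$treat_all, 0)))
  graphics::lines(dc$threshold, dc$treat_all, col = "grey50")
  graphics::abline(h = 0, lty = 2)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Empirical ROC curve plot for one or more score vectors
#'
#' @param scores named list of score vectors (or a single vector).
#' @param labels binary labels (0/1).
#' @return invisibly, the AUCs.
#' @export
plot_roc <- function(scores, labels) {
  if (!is.list(scores)) scores <- list(model = scores)
  labels <- as.integer(labels)
  cols <- seq_along(scores)
  plot(c(0, 1), c(0, 1), type = "n", xlab = "1 - Specificity",
       ylab = "Sensitivity", main = "ROC")
  graphics::abline(0, 1, lty = 3, col = "grey")
  aucs <- numeric(0)
  for (i in seq_along(scores)) {
    s <- scores[[i]]
    th <- c(Inf, sort(unique(s), decreasing = TRUE))
    fpr <- vapply(th, function(t) mean(s[labels == 0] >= t), numeric(1))
    tpr <- vapply(th, function(t) mean(s[labels == 1] >= t), numeric(1))
    graphics::lines(fpr, tpr, col = cols[i], lwd = 2)
    aucs[names(scores)[i] %||% i] <- roc_auc(s, labels)
  }
  graphics::legend("bottomright", legend = sprintf("%s (AUC %.3f)",
                                                   names(scores), aucs),
                   col = cols, lwd = 2, bty = "n")
  invisible(aucs)
}
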