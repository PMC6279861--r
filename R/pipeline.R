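#' The three tissue contrasts
#'
#' Model 1 discriminates control white matter from developing NAWM, Model 2
#' non-developing from developing NAWM, and Model 3 control white matter
#' from non-developing NAWM. The second label of each pair is the positive
#' (more diseased) class.
#'
#' @return Named list of `c(negative, positive)` ROI-label pairs.
#' @export
pipeline_contrasts <- function() {
  list(
    model1 = c("NWM", "dNAWM"),
    model2 = c("non_dNAWM", "dNAWM"),
    model3 = c("NWM", "non_dNAWM")
  )
}

#' Assemble a pipeline run configuration
#'
#' One nested configuration drives simulate, extract, select, fit and
#' evaluate; every output artifact embeds its MD5 hash for provenance.
#'
#' @param cohort arguments for [cohort_spec()].
#' @param extraction arguments for [battery_config()].
#' @param selection list: `alpha`, `rho_max`, `n_folds`, `mode`,
#'   `lambda_rule`.
#' @param modeling list: `train_fraction`, `seed` (split + fold seed).
#' @param evaluation list: `ci_method`, `hl_groups`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = list(), extraction = list(),
                       selection = list(), modeling = list(),
                       evaluation = list()) {
  cfg <- list(
    cohort = utils::modifyList(
      list(n_cases = 51, n_controls = 51, image_size = c(96, 96),
           roi_min_pixels = 100, seed = 1),
      cohort
    ),
    extraction = utils::modifyList(
      list(ng = 16, offsets = c(1, 4, 7), log_base = 2), extraction
    ),
    selection = utils::modifyList(
      list(alpha = 0.05, rho_max = 0.9, n_folds = 10, mode = "both",
           lambda_rule = "min"),
      selection
    ),
    modeling = utils::modifyList(
      list(train_fraction = 0.7, seed = 1), modeling
    ),
    evaluation = utils::modifyList(
      list(ci_method = "delong", hl_groups = 10), evaluation
    )
  )
  structure(cfg, class = c("run_config", "list"))
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  writeLines(yaml::as.yaml(unclass(config)), f)
  unname(tools::md5sum(f))
}

#' Fit and evaluate one contrast on an extracted feature matrix
#'
#' Restricts the feature matrix to the contrast's two ROI classes, runs the
#' three-stage selection cascade on the training rows, refits an unpenalized
#' multivariable logistic model on the surviving features (falling back to
#' the stage-2 survivors, flagged, when the LASSO keeps nothing), and
#' evaluates train and test ROC plus training calibration.
#'
#' @param features data.frame from [extract_cohort_features()].
#' @param contrast `c(negative_label, positive_label)`.
#' @param is_train logical split flag aligned with `features` rows.
#' @param config a [run_config()].
#' @return A list of class `model_result`: `contrast`, `selection`, `model`,
#'   `fallback`, per-split probabilities and labels, `roc_train`,
#'   `roc_test`, `hl_train`.
#' @export
fit_contrast_model <- function(features, contrast, is_train,
                               config = run_config()) {
  sel_cfg <- config$selection
  keep <- features$roi_label %in% contrast
  fx <- features[keep, , drop = FALSE]
  tr <- is_train[keep]
  meta_cols <- c("subject_id", "group", "roi_label")
  x <- as.matrix(fx[, setdiff(colnames(fx), meta_cols), drop = FALSE])
  y <- as.integer(fx$roi_label == contrast[2])
  sel <- run_cascade(
    x, y, train = tr, alpha = sel_cfg$alpha, rho_max = sel_cfg$rho_max,
    n_folds = sel_cfg$n_folds, seed = config$modeling$seed,
    mode = sel_cfg$mode, lambda_rule = sel_cfg$lambda_rule
  )
  fallback <- length(sel$stage3) == 0L
  model_feats <- if (fallback) sel$stage2 else sel$stage3
  if (length(model_feats) == 0L) {
    stop(errorCondition(
      sprintf("no feature survived selection for contrast %s vs %s",
              contrast[1], contrast[2]),
      class = c("nawmrad_empty_selection", "nawmrad_error")
    ))
  }
  if (fallback) {
    warning("LASSO kept no feature; model refit on stage-2 survivors")
  }
  model <- fit_logistic(x[tr, , drop = FALSE], y[tr], features = model_feats)
  p_train <- predict_prob(model, x[tr, , drop = FALSE])
  p_test <- predict_prob(model, x[!tr, , drop = FALSE])
  ev <- config$evaluation
  structure(
    list(
      contrast = contrast, selection = sel, model = model,
      fallback = fallback,
      train = list(probs = p_train, labels = y[tr]),
      test = list(probs = p_test, labels = y[!tr]),
      roc_train = roc_auc(p_train, y[tr], ci_method = ev$ci_method),
      roc_test = roc_auc(p_test, y[!tr], ci_method = ev$ci_method),
      hl_train = hosmer_lemeshow(p_train, y[tr], groups = ev$hl_groups)
    ),
    class = "model_result"
  )
}

#' Run the full pipeline: simulate, extract, select, fit, evaluate
#'
#' Generates the seeded synthetic cohort, extracts the texture battery for
#' every analysis ROI, splits subjects 7:3 stratified by group (the one
#' split is shared by the three contrasts), then for each contrast runs the
#' selection cascade, the logistic refit, and the ROC/calibration
#' evaluation. Artifacts written to `out_dir`: `features.csv`,
#' `table1.csv`, and per contrast `selection_<m>.json`, `model_<m>.json`,
#' `report_<m>.json`, plus `manifest.json` with the config hash. Re-running
#' with the same configuration reproduces every artifact.
#'
#' @param config a [run_config()].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @return A list of class `pipeline_result`: `cohort_spec`, `features`,
#'   `is_train`, `models` (one `model_result` per contrast), `table1`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  spec <- do.call(cohort_spec, config$cohort)
  cohort <- generate_cohort(spec)
  bat_cfg <- do.call(battery_config, config$extraction)
  features <- extract_cohort_features(cohort, bat_cfg)
  # subject-level split shared across contrasts (both ROIs of a case subject
  # stay on the same side of the split)
  subj <- unique(features[, c("subject_id", "group")])
  subj_train <- split_train_test(
    subj$group, train_fraction = config$modeling$train_fraction,
    seed = config$modeling$seed
  )
  is_train <- features$subject_id %in% subj$subject_id[subj_train]
  models <- lapply(pipeline_contrasts(), function(ct) {
    fit_contrast_model(features, ct, is_train, config)
  })
  tab1 <- cohort_table(cohort)
  manifest <- list(
    package_version = as.character(utils::packageVersion("nawmrad")),
    config = unclass(config),
    config_hash = config_hash(config),
    n_subjects = length(cohort$subjects),
    n_rois = nrow(features),
    n_train = sum(is_train), n_test = sum(!is_train),
    contrasts = lapply(models, function(m) {
      list(
        negative = m$contrast[1], positive = m$contrast[2],
        n_selected = length(m$selection$stage3),
        fallback = m$fallback,
        auc_train = m$roc_train$auc, auc_test = m$roc_test$auc,
        hl_p_train = m$hl_train$p_value
      )
    })
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(tab1, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    for (m in names(models)) {
      mod <- models[[m]]
      jsonlite::write_json(
        list(
          contrast = mod$contrast, stage1 = mod$selection$stage1,
          stage2 = mod$selection$stage2, stage3 = mod$selection$stage3,
          lasso_lambda = mod$selection$lasso_lambda,
          lasso_weights = as.list(mod$selection$nonzero_weights),
          config_hash = manifest$config_hash
        ),
        file.path(out_dir, sprintf("selection_%s.json", m)),
        auto_unbox = TRUE, digits = NA
      )
      jsonlite::write_json(
        list(
          contrast = mod$contrast, intercept = mod$model$intercept,
          weights = as.list(mod$model$weights),
          center = as.list(mod$model$center),
          scale = as.list(mod$model$scale),
          fallback = mod$fallback, n_train = mod$model$n_train,
          config_hash = manifest$config_hash
        ),
        file.path(out_dir, sprintf("model_%s.json", m)),
        auto_unbox = TRUE, digits = NA
      )
      jsonlite::write_json(
        list(
          contrast = mod$contrast,
          auc_train = mod$roc_train$auc,
          auc_train_ci = as.list(mod$roc_train$auc_ci),
          auc_test = mod$roc_test$auc,
          auc_test_ci = as.list(mod$roc_test$auc_ci),
          operating_point_test = as.list(mod$roc_test$operating_point),
          hl_statistic = mod$hl_train$statistic,
          hl_df = mod$hl_train$df, hl_p = mod$hl_train$p_value,
          config_hash = manifest$config_hash
        ),
        file.path(out_dir, sprintf("report_%s.json", m)),
        auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(
    list(cohort_spec = spec, features = features, is_train = is_train,
         models = models, table1 = tab1, manifest = manifest),
    class = "pipeline_result"
  )
}
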