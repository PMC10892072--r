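#' Simulate a substance table
#'
#' Pipeline verb wrapping [simulate_substances()]; optionally writes
#' the canonical CSV.
#'
#' @param config A [synthetic_config()].
#' @param path Optional CSV output path.
#' @return Substance tibble.
#' @export
sens_simulate <- function(config = synthetic_config(seed = 1), path = NULL) {
  data <- simulate_substances(config)
  if (!is.null(path)) write_substances(data, path)
  data
}

#' Train the two-stage model and its reports
#'
#' Fits the cascade on the supplied (training) substances and attaches
#' the per-stage averaged importance tables and a plain-text manifest
#' echoing the resolved configuration and seed, so a run can be
#' reproduced exactly.
#'
#' @param data Training substance tibble with labels.
#' @param config A [cascade_config()].
#' @param seed Integer seed.
#' @return A `sens_cascade` with `importance` (list of two
#'   `sens_importance` tables) and `manifest` fields added.
#' @export
sens_train <- function(data, config = cascade_config(), seed) {
  model <- fit_cascade(data, config, seed = seed)
  model$importance <- list(
    hazard = average_importance(model$stage1$model),
    potency = average_importance(model$stage2$model)
  )
  model$manifest <- c(
    seed = seed,
    n_train = model$n_train,
    n_train_sensitizers = model$n_train_sensitizers,
    n_subsets = config$n_subsets,
    subset_fraction = config$subset_fraction,
    cv_folds = config$folds,
    prune_threshold = config$prune_threshold,
    grid_points_hazard = nrow(config$grid_hazard),
    grid_points_potency = nrow(config$grid_potency),
    stage1_features = paste(model$stage1$preprocess$features, collapse = ","),
    stage2_features = paste(model$stage2$preprocess$features, collapse = ","),
    embedding_backend = attr(config$provider, "backend") %||% "custom"
  )
  model
}

#' Write the manifest of a trained model
#'
#' Key-value lines; identical config and seed give byte-identical
#' manifests.
#'
#' @param model A `sens_cascade` from [sens_train()].
#' @param path Output text file.
#' @return The path, invisibly.
#' @export
write_manifest <- function(model, path) {
  if (is.null(model$manifest)) {
    abort("model has no manifest; train it with sens_train()",
          class = "skinsens_validation_error")
  }
  writeLines(paste0(names(model$manifest), "\t", model$manifest), path)
  invisible(path)
}

#' Predict with a trained two-stage model
#'
#' @param model A `sens_cascade`.
#' @param data Substance tibble.
#' @param mode `"cascaded"` or `"independent"` (see
#'   [predict.sens_cascade()]).
#' @param path Optional CSV output (`id`, `final_class`, vote
#'   fractions; stage-2 fields empty where stage 2 did not run).
#' @return Prediction tibble.
#' @export
sens_predict <- function(model, data, mode = "cascaded", path = NULL) {
  pred <- predict(model, data, mode = mode)
  if (!is.null(path)) readr::write_csv(pred, path, na = "", progress = FALSE)
  pred
}

#' Evaluate predictions against human potency categories
#'
#' Computes the full report: stage-1 hazard metrics (all substances),
#' stage-2 potency metrics restricted to the true sensitizers whose
#' stage-2 prediction is available, both AUC variants per stage, and
#' the 3-class potency table with under/over-prediction rates.
#'
#' @param predictions Tibble from [sens_predict()].
#' @param truth Substance tibble with `potency_category` (matched by
#'   id), or an integer category vector aligned with `predictions`.
#' @return Object of class `sens_evaluation`: list with `stage1`,
#'   `stage2` (one-row metric tibbles with confusion attributes) and
#'   `potency` (a `sens_potency`).
#' @export
sens_evaluate <- function(predictions, truth) {
  if (is.data.frame(truth)) {
    m <- match(predictions$id, truth$id)
    if (anyNA(m)) {
      abort("every predicted id must appear in the truth table",
            class = "skinsens_validation_error")
    }
    categories <- truth$potency_category[m]
  } else {
    categories <- truth
    if (length(categories) != nrow(predictions)) {
      abort("truth vector length must match predictions",
            class = "skinsens_validation_error")
    }
  }
  labels <- derive_labels(categories)

  truth_hazard <- factor(as.character(labels$hazard),
                         levels = c("non_sensitizer", "sensitizer"))
  stage1 <- stage_metrics(truth_hazard, predictions$stage1_pred,
                          predictions$stage1_vote_fraction)

  is_sens <- labels$hazard == "sensitizer"
  has2 <- is_sens & !is.na(predictions$stage2_pred)
  stage2 <- NULL
  if (any(has2) && length(unique(labels$potency[has2])) > 1) {
    truth_pot <- factor(as.character(labels$potency[has2]), levels = c("1B", "1A"))
    stage2 <- stage_metrics(truth_pot, predictions$stage2_pred[has2],
                            predictions$stage2_vote_fraction[has2])
  }

  truth3 <- ifelse(!is_sens, "NC", as.character(labels$potency))
  potency <- potency_table(confusion_matrix3(predictions$final_class, truth3))

  structure(list(stage1 = stage1, stage2 = stage2, potency = potency),
            class = "sens_evaluation")
}

#' @export
print.sens_evaluation <- function(x, ...) {
  cat("Stage 1 - sensitizer vs non-sensitizer:\n")
  print(as.data.frame(round(x$stage1, 4)), row.names = FALSE)
  if (!is.null(x$stage2)) {
    cat("Stage 2 - strong (1A) vs weak (1B), true sensitizers:\n")
    print(as.data.frame(round(x$stage2, 4)), row.names = FALSE)
  }
  cat("\n")
  print(x$potency)
  invisible(x)
}

#' @method tidy sens_evaluation
#' @export
tidy.sens_evaluation <- function(x, ...) {
  rows <- list(dplyr::mutate(x$stage1, stage = "hazard", .before = 1))
  if (!is.null(x$stage2)) {
    rows <- c(rows, list(dplyr::mutate(x$stage2, stage = "potency", .before = 1)))
  }
  dplyr::bind_rows(rows)
}

#' @method glance sens_evaluation
#' @export
glance.sens_evaluation <- function(x, ...) {
  tibble::tibble(
    overall_potency_accuracy = x$potency$overall_accuracy,
    stage1_balanced_accuracy = x$stage1$balanced_accuracy,
    stage2_balanced_accuracy = if (is.null(x$stage2)) NA_real_ else
      x$stage2$balanced_accuracy
  )
}

#' Export a metrics report as JSON
#'
#' @param evaluation A `sens_evaluation`.
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_evaluation_json <- function(evaluation, path) {
  rlang::check_installed("jsonlite")
  payload <- list(
    stage1 = as.list(evaluation$stage1),
    stage2 = if (is.null(evaluation$stage2)) NULL else as.list(evaluation$stage2),
    potency = list(
      overall_accuracy = evaluation$potency$overall_accuracy,
      per_class = evaluation$potency$per_class,
      counts = unclass(evaluation$potency$counts)
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Averaged SHAP attributions for one stage
#'
#' Runs the substances through the requested stage's preprocessing and
#' returns averaged attributions plus the vote/attribution concordance
#' flags.
#'
#' @param model A `sens_cascade`.
#' @param data Substance tibble.
#' @param stage `"hazard"` (default) or `"potency"`.
#' @param path Optional CSV path for the per-substance averaged
#'   attributions (long format).
#' @return List: `attributions` (`sens_shap`), `ranking`
#'   ([shap_summary_ranking()] tibble), `concordance`
#'   ([vote_shap_concordance()] tibble).
#' @export
sens_explain <- function(model, data, stage = c("hazard", "potency"),
                         path = NULL) {
  stage <- match.arg(stage)
  st <- if (stage == "hazard") model$stage1 else model$stage2
  feats <- build_feature_table(data, provider = model$config$provider)
  sin <- apply_stage_preprocess(st$preprocess, feats)
  attribs <- shap_attributions(st$model, sin)
  pred <- predict_vote(st$model, sin)
  out <- list(
    attributions = attribs,
    ranking = shap_summary_ranking(attribs),
    concordance = vote_shap_concordance(attribs, pred)
  )
  if (!is.null(path)) readr::write_csv(tidy(attribs), path, progress = FALSE)
  out
}

#' Serialize a trained model to a directory
#'
#' Writes per-learner model files (xgboost JSON), per-stage scaler and
#' feature lists, and the manifest, as plain text. For in-session
#' persistence of the full object use `saveRDS()`.
#'
#' @param model A `sens_cascade` from [sens_train()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_bundle <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in c("stage1", "stage2")) {
    st <- model[[stage]]
    for (i in seq_along(st$model$learners)) {
      xgboost::xgb.save(st$model$learners[[i]],
                        file.path(dir, sprintf("%s_learner%d.json", stage, i)))
    }
    if (!is.null(st$preprocess$scaler)) {
      write_scaler(st$preprocess$scaler,
                   file.path(dir, paste0(stage, "_scaler.tsv")))
    }
    writeLines(st$preprocess$features,
               file.path(dir, paste0(stage, "_features.txt")))
    readr::write_csv(st$model$chosen_params,
                     file.path(dir, paste0(stage, "_params.csv")),
                     progress = FALSE)
  }
  if (!is.null(model$manifest)) write_manifest(model, file.path(dir, "manifest.txt"))
  invisible(dir)
}
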