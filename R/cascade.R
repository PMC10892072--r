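#' Configuration for the two-stage classifier
#'
#' Bundles the tuning grids and preprocessing settings used by
#' [fit_cascade()]. Each stage preprocesses independently: descriptor
#' pruning and standardization are fitted on that stage's own training
#' rows (stage 2 trains only on true sensitizers, whose descriptor
#' correlation structure differs from the full set).
#'
#' @param grid_hazard,grid_potency Tuning grids from [hyper_grid()];
#'   defaults are the full stage-specific grids.
#' @param prune_threshold Pearson threshold for descriptor pruning
#'   (applied to descriptors only, never to assay or embedding
#'   features); default 0.75.
#' @param n_subsets Base learners per stage; default 5.
#' @param subset_fraction Bootstrap fraction; default 0.8.
#' @param folds CV folds in tuning; default 5.
#' @param stage1_features,stage2_features Optional explicit feature
#'   lists (e.g. from [top_k_features()]); `NULL` means all assay +
#'   embedding features plus pruned descriptors.
#' @param provider Embedding provider used when the table lacks a
#'   precomputed embedding column.
#' @return A list of class `sens_cascade_config`.
#' @export
cascade_config <- function(grid_hazard = hyper_grid("hazard"),
                           grid_potency = hyper_grid("potency"),
                           prune_threshold = 0.75,
                           n_subsets = 5,
                           subset_fraction = 0.8,
                           folds = 5,
                           stage1_features = NULL,
                           stage2_features = NULL,
                           provider = fallback_provider()) {
  structure(list(
    grid_hazard = grid_hazard, grid_potency = grid_potency,
    prune_threshold = prune_threshold, n_subsets = n_subsets,
    subset_fraction = subset_fraction, folds = folds,
    stage1_features = stage1_features, stage2_features = stage2_features,
    provider = provider
  ), class = "sens_cascade_config")
}

fit_stage_preprocess <- function(feats, selected, prune_threshold) {
  feature_cols <- setdiff(names(feats), "id")
  if (is.null(selected)) {
    desc <- setdiff(feature_cols, c(.assay_features, .embedding_feature))
    if (length(desc) > 0) {
      pruned <- prune_correlated(feats[, desc, drop = FALSE],
                                 threshold = prune_threshold)
      keep_desc <- pruned$kept
      report <- pruned$report
    } else {
      keep_desc <- character(0)
      report <- tibble::tibble(dropped = character(), representative = character(),
                               r = numeric(), reason = character())
    }
    selected <- c(intersect(.assay_features, feature_cols),
                  intersect(.embedding_feature, feature_cols), keep_desc)
  } else {
    stray <- setdiff(selected, feature_cols)
    if (length(stray) > 0) {
      abort(paste0("selected feature(s) absent: ", paste(stray, collapse = ", ")),
            class = "skinsens_schema_error")
    }
    report <- tibble::tibble(dropped = character(), representative = character(),
                             r = numeric(), reason = character())
  }
  # standardize descriptors + embedding; leave assay readouts on their
  # native scales (binary calls and bounded percentages)
  scale_cols <- setdiff(selected, .assay_features)
  scaler <- if (length(scale_cols) > 0) {
    fit_standardizer(feats[, scale_cols, drop = FALSE])
  } else NULL
  list(features = selected, scaler = scaler, prune_report = report)
}

apply_stage_preprocess <- function(state, feats) {
  out <- feats
  if (!is.null(state$scaler)) out <- apply_standardizer(state$scaler, out)
  missing_cols <- setdiff(state$features, names(out))
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature(s): ", paste(missing_cols, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  out[, c("id", state$features), drop = FALSE]
}

#' Fit the two-stage sensitization classifier
#'
#' Stage 1 (hazard: sensitizer vs non-sensitizer) is trained on all
#' complete training substances; stage 2 (potency: 1A vs 1B) is trained
#' on the substances whose *true* label is sensitizer, independently of
#' stage-1 predictions. Each stage prunes and standardizes its own
#' features and fits a bagged majority-vote ensemble ([fit_bagged()]).
#'
#' @param data Substance tibble with `potency_category` labels.
#' @param config A [cascade_config()].
#' @param seed Integer seed; stage seeds are derived from it.
#' @return Object of class `sens_cascade`.
#' @export
#' @examples
#' \donttest{
#' d <- simulate_substances(synthetic_config(n = 150, seed = 1))
#' cfg <- cascade_config(
#'   grid_hazard = hyper_grid("hazard", learning_rate = 0.1,
#'                            n_estimators = 50, max_depth = 3,
#'                            subsample = 0.8),
#'   grid_potency = hyper_grid("potency", learning_rate = 0.1,
#'                             n_estimators = 50, max_depth = 3,
#'                             subsample = 0.8))
#' m <- fit_cascade(d, cfg, seed = 42)
#' }
fit_cascade <- function(data, config = cascade_config(), seed) {
  stopifnot(inherits(config, "sens_cascade_config"))
  if (!"potency_category" %in% names(data) || anyNA(data$potency_category)) {
    abort("training data must have complete potency_category labels",
          class = "skinsens_validation_error")
  }
  labels <- derive_labels(data$potency_category)
  feats <- build_feature_table(data, provider = config$provider)
  feats <- drop_incomplete(feats)
  keep <- match(feats$id, data$id)
  labels <- labels[keep, ]

  n_sens <- sum(labels$hazard == "sensitizer")
  if (n_sens == nrow(feats) || n_sens == 0) {
    abort("training data must contain both sensitizers and non-sensitizers",
          class = "skinsens_domain_error")
  }
  if (n_sens < 10) warn(paste0("only ", n_sens, " sensitizers in training"))
  pot <- labels$potency[labels$hazard == "sensitizer"]
  if (sum(pot == "1A") < 2 || sum(pot == "1B") < 2) {
    abort("need at least 2 sensitizers of each potency class (1A, 1B)",
          class = "skinsens_domain_error")
  }

  s1_state <- fit_stage_preprocess(feats, config$stage1_features,
                                   config$prune_threshold)
  s1_feats <- apply_stage_preprocess(s1_state, feats)
  s1_label <- factor(ifelse(labels$hazard == "sensitizer", "sensitizer",
                            "non_sensitizer"),
                     levels = c("non_sensitizer", "sensitizer"))
  stage1 <- fit_bagged(s1_feats, s1_label, config$grid_hazard,
                       k = config$n_subsets, fraction = config$subset_fraction,
                       folds = config$folds, seed = seed)

  sens_rows <- labels$hazard == "sensitizer"
  feats2 <- feats[sens_rows, , drop = FALSE]
  s2_state <- fit_stage_preprocess(feats2, config$stage2_features,
                                   config$prune_threshold)
  s2_feats <- apply_stage_preprocess(s2_state, feats2)
  s2_label <- factor(as.character(labels$potency[sens_rows]),
                     levels = c("1B", "1A"))
  stage2 <- fit_bagged(s2_feats, s2_label, config$grid_potency,
                       k = config$n_subsets, fraction = config$subset_fraction,
                       folds = config$folds, seed = seed + 20011L)

  structure(list(
    stage1 = list(model = stage1, preprocess = s1_state),
    stage2 = list(model = stage2, preprocess = s2_state),
    config = config,
    seed = seed,
    n_train = nrow(feats),
    n_train_sensitizers = n_sens
  ), class = "sens_cascade")
}

#' Predict NC / 1B / 1A with the two-stage classifier
#'
#' In `cascaded` mode stage 2 runs only on substances stage 1 calls
#' sensitizer (the deployment flow: a predicted non-sensitizer is never
#' graded). In `independent` mode stage 2 runs on every substance,
#' which is how the potency stage is evaluated on all true sensitizers
#' of a test set.
#'
#' @param object A `sens_cascade`.
#' @param data Substance tibble to predict (labels not required).
#' @param mode `"cascaded"` (default) or `"independent"`.
#' @param ... Unused.
#' @return Tibble: `id`, `final_class` (factor NC/1B/1A), `stage1_pred`,
#'   `stage1_vote_fraction`, `stage2_pred`, `stage2_vote_fraction`
#'   (stage-2 fields `NA` where stage 2 did not run).
#' @export
predict.sens_cascade <- function(object, data, mode = c("cascaded", "independent"),
                                 ...) {
  mode <- tryCatch(match.arg(mode),
                   error = function(e) abort("mode must be 'cascaded' or 'independent'",
                                             class = "skinsens_domain_error"))
  feats <- build_feature_table(data, provider = object$config$provider)
  s1_in <- apply_stage_preprocess(object$stage1$preprocess, feats)
  s1 <- predict_vote(object$stage1$model, s1_in)
  is_sens <- s1$.pred == "sensitizer"

  s2_pred <- factor(rep(NA_character_, nrow(feats)), levels = c("1B", "1A"))
  s2_frac <- rep(NA_real_, nrow(feats))
  run2 <- if (mode == "independent") rep(TRUE, nrow(feats)) else is_sens
  if (any(run2)) {
    s2_in <- apply_stage_preprocess(object$stage2$preprocess,
                                    feats[run2, , drop = FALSE])
    s2 <- predict_vote(object$stage2$model, s2_in)
    s2_pred[run2] <- s2$.pred
    s2_frac[run2] <- s2$vote_fraction
  }

  final <- ifelse(!is_sens, "NC", as.character(s2_pred))
  tibble::tibble(
    id = as.character(feats$id),
    final_class = factor(final, levels = c("NC", "1B", "1A")),
    stage1_pred = s1$.pred,
    stage1_vote_fraction = s1$vote_fraction,
    stage2_pred = s2_pred,
    stage2_vote_fraction = s2_frac
  )
}

#' @export
print.sens_cascade <- function(x, ...) {
  cat("Two-stage skin sensitization classifier\n")
  cat("  stage 1 (hazard):", length(x$stage1$preprocess$features),
      "features,", x$n_train, "training substances\n")
  cat("  stage 2 (potency):", length(x$stage2$preprocess$features),
      "features,", x$n_train_sensitizers, "training sensitizers\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @method tidy sens_cascade
#' @export
tidy.sens_cascade <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tidy(x$stage1$model), stage = "hazard", .before = 1),
    dplyr::mutate(tidy(x$stage2$model), stage = "potency", .before = 1)
  )
}

#' @method glance sens_cascade
#' @export
glance.sens_cascade <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_train_sensitizers = x$n_train_sensitizers,
    stage1_features = length(x$stage1$preprocess$features),
    stage2_features = length(x$stage2$preprocess$features),
    stage1_mean_cv_ba = mean(x$stage1$model$cv_balanced_accuracy),
    stage2_mean_cv_ba = mean(x$stage2$model$cv_balanced_accuracy),
    seed = x$seed
  )
}
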