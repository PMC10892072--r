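#' Balanced accuracy of hard predictions
#'
#' Mean per-class recall (for two classes, the mean of sensitivity and
#' specificity). Classes absent from `truth` are skipped.
#'
#' @param truth,pred Vectors of 0/1 labels of equal length.
#' @return Balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(truth))
  recalls <- vapply(classes, function(cl) mean(pred[truth == cl] == cl),
                    numeric(1))
  mean(recalls)
}

#' Hyperparameter grid for one classification stage
#'
#' The tuning grid searched for every base learner: learning rate,
#' boosting rounds, tree depth, row subsampling, and the positive-class
#' weight. The positive-class weight set is stage-dependent - the
#' hazard stage (positive = sensitizer, the majority class in the
#' emulated data) searches \{0.5, 1\}, the potency stage (positive =
#' strong/1A, the minority) searches \{1, 2\}. Grid rows are enumerated
#' lexicographically in the argument order below; ties in tuning are
#' broken by this order.
#'
#' @param stage `"hazard"` or `"potency"`; sets the default
#'   `scale_pos_weight` values.
#' @param learning_rate,n_estimators,max_depth,subsample,scale_pos_weight
#'   Candidate values; override to shrink or extend the search.
#' @return A tibble of grid points with class `sens_grid`.
#' @export
#' @examples
#' nrow(hyper_grid("hazard"))           # 360
#' hyper_grid("potency", n_estimators = 100, max_depth = 3)
hyper_grid <- function(stage = c("hazard", "potency"),
                       learning_rate = c(0.01, 0.1, 0.2),
                       n_estimators = c(50, 100, 200, 300, 500),
                       max_depth = c(3, 5, 7, 9),
                       subsample = c(0.6, 0.8, 1.0),
                       scale_pos_weight = NULL) {
  stage <- match.arg(stage)
  if (is.null(scale_pos_weight)) {
    scale_pos_weight <- if (stage == "hazard") c(0.5, 1.0) else c(1.0, 2.0)
  }
  stopifnot(length(learning_rate) > 0, length(n_estimators) > 0,
            length(max_depth) > 0, length(subsample) > 0,
            length(scale_pos_weight) > 0)
  if (any(c(learning_rate, n_estimators, max_depth, subsample,
            scale_pos_weight) <= 0)) {
    abort("grid values must be positive", class = "skinsens_domain_error")
  }
  g <- expand.grid(
    scale_pos_weight = scale_pos_weight,
    subsample = subsample,
    max_depth = max_depth,
    n_estimators = n_estimators,
    learning_rate = learning_rate,
    KEEP.OUT.ATTRS = FALSE
  )
  g <- tibble::as_tibble(g[, c("learning_rate", "n_estimators", "max_depth",
                               "subsample", "scale_pos_weight")])
  g <- g[order(g$learning_rate, g$n_estimators, g$max_depth, g$subsample,
               g$scale_pos_weight), , drop = FALSE]
  structure(g, class = c("sens_grid", class(tibble::as_tibble(g))), stage = stage)
}

#' Bootstrap subsets for bagging
#'
#' Draws `k` subsets from the training ids by sampling with
#' replacement, each of size `round(fraction * n)` (half away from
#' zero). Draws are keyed to the sorted id vector, so the result does
#' not depend on row order.
#'
#' @param train_ids Character vector of training substance ids.
#' @param k Number of subsets; default 5.
#' @param fraction Subset size as a fraction of the training set;
#'   default 0.8.
#' @param seed Integer seed.
#' @return List of `k` character vectors (multisets of ids).
#' @export
make_subsets <- function(train_ids, k = 5, fraction = 0.8, seed) {
  if (length(train_ids) == 0) {
    abort("train_ids must be non-empty", class = "skinsens_domain_error")
  }
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must be in (0, 1]", class = "skinsens_domain_error")
  }
  ids <- sort(as.character(train_ids))
  size <- as.integer(floor(fraction * length(ids) + 0.5))
  lapply(seq_len(k), function(i) {
    set.seed((seed + 1009L * i) %% .Machine$integer.max)
    sample(ids, size, replace = TRUE)
  })
}

xgb_params <- function(point, seed) {
  list(
    objective = "binary:logistic",
    eta = point$learning_rate,
    max_depth = as.integer(point$max_depth),
    subsample = point$subsample,
    scale_pos_weight = point$scale_pos_weight,
    nthread = 1,
    seed = as.integer(seed %% .Machine$integer.max)
  )
}

fit_xgb <- function(X, y, point, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = xgb_params(point, seed), data = dtrain,
                     nrounds = as.integer(point$n_estimators), verbose = 0)
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assignment <- integer(length(y))
  for (cl in sort(unique(y))) {
    idx <- which(y == cl)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}

#' Tune one base learner by cross-validated balanced accuracy
#'
#' Exhaustive grid search: every grid point is scored by stratified
#' k-fold cross-validation on the subset, the score being the mean
#' across folds of the balanced accuracy of hard (0.5-threshold)
#' predictions. The best point (ties broken by grid enumeration order)
#' is refitted on the whole subset. If the minority class has fewer
#' members than `folds`, the fold count is reduced to that class count
#' with a warning.
#'
#' @param X Numeric feature matrix with column names.
#' @param y 0/1 label vector (1 = positive class).
#' @param grid A [hyper_grid()] tibble.
#' @param folds Number of CV folds; default 5.
#' @param seed Integer seed driving fold assignment and fits.
#' @return List: `booster` (fitted on the full subset), `params` (the
#'   chosen grid row), `cv_balanced_accuracy`, `cv_scores` (per grid
#'   point).
#' @export
tune_base_learner <- function(X, y, grid, folds = 5, seed) {
  if (length(unique(y)) < 2) {
    abort("both classes must be present in the subset",
          class = "skinsens_domain_error")
  }
  min_class <- min(table(y))
  if (min_class < folds) {
    warn(paste0("minority class has ", min_class, " members; reducing CV folds from ",
                folds, " to ", min_class))
    folds <- max(2L, as.integer(min_class))
  }
  fold_id <- stratified_folds(y, folds, seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    point <- grid[g, ]
    fold_ba <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      booster <- fit_xgb(X[tr, , drop = FALSE], y[tr], point,
                         seed = seed + 131L * g + 7L * f)
      prob <- predict(booster, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE]))
      fold_ba[f] <- balanced_accuracy(y[!tr], as.integer(prob > 0.5))
    }
    scores[g] <- mean(fold_ba)
  }
  best <- which.max(scores)  # first maximum = grid enumeration order
  booster <- fit_xgb(X, y, grid[best, ], seed = seed + 997L)
  list(booster = booster, params = grid[best, ],
       cv_balanced_accuracy = scores[best], cv_scores = scores)
}

#' Fit a bagged stage model
#'
#' One classification stage of the defined approach: five bootstrap
#' subsets of the training substances, an independently tuned
#' gradient-boosted tree classifier per subset, and majority voting at
#' prediction time. All randomness derives from `seed`; rows are
#' canonically ordered by id before sampling and fitting, so the fit is
#' invariant to the row order of the input table.
#'
#' @param features Feature tibble with an `id` column plus numeric
#'   feature columns.
#' @param label Binary label vector aligned with `features` rows:
#'   0/1, logical, or a two-level factor whose second level is the
#'   positive class.
#' @param grid A [hyper_grid()].
#' @param k Number of base learners; default 5.
#' @param fraction Bootstrap subset fraction; default 0.8.
#' @param folds CV folds per grid point; default 5.
#' @param seed Integer seed.
#' @return Object of class `sens_bagged`.
#' @export
fit_bagged <- function(features, label, grid, k = 5, fraction = 0.8,
                       folds = 5, seed) {
  if (!"id" %in% names(features)) {
    abort("features must carry an 'id' column", class = "skinsens_schema_error")
  }
  lv <- c("negative", "positive")
  if (is.factor(label)) {
    lv <- levels(label)
    if (length(lv) != 2) abort("label factor must have 2 levels",
                               class = "skinsens_domain_error")
    y_all <- as.integer(label) - 1L
  } else {
    y_all <- as.integer(label)
    if (!all(y_all %in% c(0L, 1L))) {
      abort("label must be binary 0/1", class = "skinsens_domain_error")
    }
  }
  ids <- as.character(features$id)
  ord <- order(ids)
  ids <- ids[ord]
  y_all <- y_all[ord]
  feature_names <- setdiff(names(features), "id")
  X_all <- as.matrix(features[ord, feature_names, drop = FALSE])
  rownames(X_all) <- ids
  if (!is.numeric(X_all)) abort("features must be numeric",
                                class = "skinsens_domain_error")
  if (anyNA(X_all)) {
    abort("missing feature values: drop incomplete rows before fitting",
          class = "skinsens_validation_error")
  }
  subsets <- make_subsets(ids, k = k, fraction = fraction, seed = seed)
  learners <- vector("list", k)
  chosen <- vector("list", k)
  cv_ba <- numeric(k)
  for (i in seq_len(k)) {
    rows <- match(subsets[[i]], ids)
    Xi <- X_all[rows, , drop = FALSE]
    yi <- y_all[rows]
    if (length(unique(yi)) < 2) {
      abort(paste0("bootstrap subset ", i, " contains a single class; ",
                   "training set too small or too imbalanced"),
            class = "skinsens_domain_error")
    }
    tuned <- tune_base_learner(Xi, yi, grid, folds = folds,
                               seed = seed + 7919L * i)
    learners[[i]] <- tuned$booster
    chosen[[i]] <- tuned$params
    cv_ba[i] <- tuned$cv_balanced_accuracy
  }
  structure(list(
    learners = learners,
    chosen_params = dplyr::bind_rows(chosen, .id = "learner"),
    cv_balanced_accuracy = cv_ba,
    subset_ids = subsets,
    feature_names = feature_names,
    levels = lv,
    seed = seed,
    k = k,
    fraction = fraction
  ), class = "sens_bagged")
}

bagged_matrix <- function(model, features) {
  nm <- if (is.matrix(features)) colnames(features) else names(features)
  missing_cols <- setdiff(model$feature_names, nm)
  if (length(missing_cols) > 0) {
    abort(paste0("missing feature(s): ", paste(missing_cols, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  X <- as.matrix(as.data.frame(features)[, model$feature_names, drop = FALSE])
  if (anyNA(X)) abort("missing feature values in prediction rows",
                      class = "skinsens_validation_error")
  X
}

#' Majority-vote prediction from a bagged stage model
#'
#' Each of the five base learners casts a hard vote (predicted
#' probability > 0.5); the stage label is the class with the majority
#' of votes. With five voters the vote fraction lies in
#' \{0, 0.2, 0.4, 0.6, 0.8, 1\} and the positive label is returned iff
#' the fraction is at least 0.6 - a tie is impossible.
#'
#' @param model A `sens_bagged` from [fit_bagged()].
#' @param features Tibble (with `id`) or matrix covering the model's
#'   feature names.
#' @return Tibble: `id` (if supplied), `.pred` (factor on the model's
#'   levels), `vote_fraction`, and `votes` (list-column of per-learner
#'   0/1 votes).
#' @export
predict_vote <- function(model, features) {
  stopifnot(inherits(model, "sens_bagged"))
  X <- bagged_matrix(model, features)
  d <- xgboost::xgb.DMatrix(X)
  votes <- vapply(model$learners,
                  function(l) as.integer(predict(l, d) > 0.5),
                  integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  frac <- rowMeans(votes)
  label <- factor(model$levels[(frac >= 0.6) + 1L], levels = model$levels)
  out <- tibble::tibble(
    .pred = label,
    vote_fraction = frac,
    votes = lapply(seq_len(nrow(votes)), function(i) votes[i, ])
  )
  if (!is.matrix(features) && "id" %in% names(features)) {
    out <- dplyr::bind_cols(tibble::tibble(id = as.character(features$id)), out)
  }
  out
}

#' Per-learner raw margins
#'
#' Log-odds margins of every base learner, used for SHAP additivity
#' checks and vote/attribution concordance.
#'
#' @inheritParams predict_vote
#' @return Numeric matrix, rows = substances, columns = learners.
#' @export
predict_margins <- function(model, features) {
  stopifnot(inherits(model, "sens_bagged"))
  X <- bagged_matrix(model, features)
  d <- xgboost::xgb.DMatrix(X)
  vapply(model$learners,
         function(l) as.numeric(predict(l, d, outputmargin = TRUE)),
         numeric(nrow(X)))
}

#' @export
print.sens_bagged <- function(x, ...) {
  cat("Bagged stage model:", x$k, "tuned gradient-boosted learners on",
      length(x$feature_names), "features\n")
  cat("positive class:", x$levels[2], "| seed:", x$seed, "\n")
  cat("mean CV balanced accuracy:",
      sprintf("%.4f", mean(x$cv_balanced_accuracy)), "\n")
  invisible(x)
}

#' Tidy the tuning outcome of a bagged stage model
#'
#' @param x A `sens_bagged`.
#' @param ... Unused.
#' @return Tibble: one row per base learner with the chosen grid point
#'   and its CV balanced accuracy.
#' @method tidy sens_bagged
#' @export
tidy.sens_bagged <- function(x, ...) {
  out <- x$chosen_params
  out$learner <- as.integer(out$learner)
  out$cv_balanced_accuracy <- x$cv_balanced_accuracy
  tibble::as_tibble(out)
}

#' One-row summary of a bagged stage model
#'
#' @param x A `sens_bagged`.
#' @param ... Unused.
#' @return Tibble with learner count, feature count, training subset
#'   size, mean CV balanced accuracy and seed.
#' @method glance sens_bagged
#' @export
glance.sens_bagged <- function(x, ...) {
  tibble::tibble(
    n_learners = x$k,
    n_features = length(x$feature_names),
    subset_size = length(x$subset_ids[[1]]),
    mean_cv_balanced_accuracy = mean(x$cv_balanced_accuracy),
    positive_class = x$levels[2],
    seed = x$seed
  )
}
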