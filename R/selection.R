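#' Feature importance averaged over the base learners
#'
#' Gain (loss-reduction) importance of every feature in every base
#' learner, arithmetically averaged across the five learners. A feature
#' never used for a split by a learner contributes 0 for that learner.
#' Ranks are assigned with ties sharing a rank.
#'
#' @param model A `sens_bagged`.
#' @return Tibble of class `sens_importance`: `feature`, per-learner
#'   columns `gain_1`..`gain_k`, `mean_gain`, `rank`; ordered by
#'   decreasing mean gain (ties by feature name).
#' @export
average_importance <- function(model) {
  stopifnot(inherits(model, "sens_bagged"))
  feats <- model$feature_names
  per <- vapply(model$learners, function(l) {
    imp <- xgboost::xgb.importance(model = l)
    out <- setNames(rep(0, length(feats)), feats)
    out[imp$Feature] <- imp$Gain
    out
  }, numeric(length(feats)))
  per <- matrix(per, nrow = length(feats),
                dimnames = list(feats, paste0("gain_", seq_along(model$learners))))
  tab <- tibble::as_tibble(per, rownames = "feature")
  tab$mean_gain <- unname(rowMeans(per))
  tab <- tab[order(-tab$mean_gain, tab$feature), , drop = FALSE]
  tab$rank <- dplyr::min_rank(dplyr::desc(tab$mean_gain))
  structure(tab, class = c("sens_importance", class(tab)))
}

#' Top-k features with tie inclusion
#'
#' Returns the `k` highest-importance features; when the k-th value is
#' tied, every tied feature is included, so the list may exceed `k`
#' (e.g. a tie at ranks 15-16 turns a top-15 request into 16 features).
#'
#' @param importance A `sens_importance` table (or any tibble with
#'   `feature` and `mean_gain`).
#' @param k Number of features requested; must be in 1..n.
#' @return Character vector of feature names, by decreasing importance.
#' @export
top_k_features <- function(importance, k) {
  if (k <= 0) abort("k must be positive", class = "skinsens_domain_error")
  if (k > nrow(importance)) {
    abort("k exceeds the number of features", class = "skinsens_domain_error")
  }
  tab <- importance[order(-importance$mean_gain, importance$feature), ]
  kth <- tab$mean_gain[k]
  tab$feature[tab$mean_gain >= kth]
}

#' Substitute the least important assay with the best excluded feature
#'
#' To streamline the in vitro testing burden, the lowest-importance
#' assay feature inside a selected feature list is swapped for the
#' highest-importance feature not yet selected; the list length is
#' preserved.
#'
#' @param selected Character vector of selected feature names.
#' @param importance A `sens_importance` table covering all features.
#' @param assay_features Names counted as in vitro assay features;
#'   default [assay_features()].
#' @return The substituted feature list (same length as `selected`).
#' @export
substitute_assay <- function(selected, importance,
                             assay_features = .assay_features) {
  sel_assays <- intersect(selected, assay_features)
  if (length(sel_assays) == 0) {
    abort("selected list contains no assay feature", class = "skinsens_domain_error")
  }
  pool <- importance[!importance$feature %in% selected, , drop = FALSE]
  if (nrow(pool) == 0) {
    abort("no non-selected feature available as replacement",
          class = "skinsens_domain_error")
  }
  imp_of <- setNames(importance$mean_gain, importance$feature)
  drop_feat <- sel_assays[order(imp_of[sel_assays],
                                sel_assays)][1]
  add_feat <- pool$feature[order(-pool$mean_gain, pool$feature)][1]
  c(setdiff(selected, drop_feat), add_feat)
}

#' Compare candidate feature sets by test balanced accuracy
#'
#' Refits the full bagged stage pipeline once per candidate feature
#' list on identical training rows and seed, and scores each on the
#' same held-out test rows. The chosen candidate has the highest test
#' balanced accuracy; ties prefer fewer features, and among equals a
#' candidate flagged as the assay-substituted variant wins (the swap
#' costs nothing and spares one in vitro test).
#'
#' @param train_features,train_label Training feature tibble (with
#'   `id`) and binary labels.
#' @param test_features,test_label Held-out rows and labels.
#' @param candidates Named list of feature-name vectors.
#' @param grid A [hyper_grid()].
#' @param seed Integer seed shared by all refits.
#' @param substituted Name(s) of candidates that are assay-substituted
#'   variants (used for the final tie-break).
#' @param ... Passed to [fit_bagged()] (`k`, `fraction`, `folds`).
#' @return List: `chosen` (candidate name), `results` (tibble with
#'   candidate, n_features, balanced_accuracy, substituted flag),
#'   `models` (fitted `sens_bagged` per candidate).
#' @export
compare_feature_sets <- function(train_features, train_label,
                                 test_features, test_label,
                                 candidates, grid, seed,
                                 substituted = character(0), ...) {
  if (length(candidates) < 1) {
    abort("need at least one candidate feature set", class = "skinsens_domain_error")
  }
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  models <- list()
  rows <- list()
  for (nm in names(candidates)) {
    feats <- candidates[[nm]]
    m <- fit_bagged(train_features[, c("id", feats), drop = FALSE],
                    train_label, grid, seed = seed, ...)
    pred <- predict_vote(m, test_features[, c("id", feats), drop = FALSE])
    truth01 <- as.integer(factor(test_label, levels = m$levels)) - 1L
    pred01 <- as.integer(pred$.pred) - 1L
    ba <- balanced_accuracy(truth01, pred01)
    models[[nm]] <- m
    rows[[nm]] <- tibble::tibble(
      candidate = nm, n_features = length(feats),
      balanced_accuracy = ba, substituted = nm %in% substituted
    )
  }
  results <- dplyr::bind_rows(rows)
  ord <- order(-results$balanced_accuracy, results$n_features,
               -as.integer(results$substituted))
  list(chosen = results$candidate[ord[1]], results = results, models = models)
}
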