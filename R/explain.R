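#' SHAP attributions averaged over the base learners
#'
#' Exact path-dependent tree attributions on the margin (log-odds)
#' scale for every base learner, computed in double precision, then
#' the unweighted arithmetic mean across the five learners. For each
#' learner and substance the base value plus the attribution sum
#' reproduces that learner's raw margin (additivity), which is exact
#' on the margin scale for tree models.
#'
#' @param model A `sens_bagged`.
#' @param features Feature tibble (with `id`) or matrix covering the
#'   model's features.
#' @return Object of class `sens_shap`: list with `averaged`
#'   (substances x features matrix of mean attributions), `base_values`
#'   (per-learner expected margins), `per_learner` (list of
#'   contribution matrices incl. the base/BIAS column), `margins`
#'   (substances x learners, double precision), `mean_margin`, `ids`,
#'   `feature_names`.
#' @export
shap_attributions <- function(model, features) {
  stopifnot(inherits(model, "sens_bagged"))
  X <- bagged_matrix(model, features)
  ids <- if (!is.matrix(features) && "id" %in% names(features)) {
    as.character(features$id)
  } else rownames(X) %||% as.character(seq_len(nrow(X)))
  rownames(X) <- ids
  res <- lapply(model$learners,
                function(l) tree_shap_contrib(l, X, model$feature_names))
  per <- lapply(res, `[[`, "contrib")
  k <- length(per)
  attr_only <- lapply(per, function(m) m[, model$feature_names, drop = FALSE])
  averaged <- Reduce(`+`, attr_only) / k
  base_values <- vapply(res, `[[`, numeric(1), "base_value")
  margins <- vapply(res, `[[`, numeric(nrow(X)), "margin")
  margins <- matrix(margins, nrow = nrow(X))
  structure(list(
    averaged = averaged,
    base_values = base_values,
    per_learner = per,
    margins = margins,
    mean_margin = rowMeans(margins),
    feature_values = X,
    ids = ids,
    feature_names = model$feature_names
  ), class = "sens_shap")
}

#' @export
print.sens_shap <- function(x, ...) {
  cat("Averaged SHAP attributions:", nrow(x$averaged), "substances x",
      ncol(x$averaged), "features over", length(x$per_learner), "learners\n")
  invisible(x)
}

#' Tidy per-substance averaged attributions
#'
#' @param x A `sens_shap`.
#' @param ... Unused.
#' @return Long tibble: `id`, `feature`, `attribution` (mean over
#'   learners, margin scale).
#' @method tidy sens_shap
#' @export
tidy.sens_shap <- function(x, ...) {
  tibble::as_tibble(x$averaged, rownames = "id") |>
    tidyr::pivot_longer(-dplyr::all_of("id"), names_to = "feature",
                        values_to = "attribution")
}

#' Rank features by mean attribution magnitude
#'
#' Orders features by the mean absolute averaged attribution across
#' substances (the usual summary-plot ordering); ties break
#' alphabetically. Set `type = "mean"` for the signed mean instead.
#'
#' @param attribs A `sens_shap`.
#' @param type `"mean_abs"` (default) or `"mean"`.
#' @return Tibble: `feature`, `score`, in ranking order.
#' @export
shap_summary_ranking <- function(attribs, type = c("mean_abs", "mean")) {
  type <- match.arg(type)
  stopifnot(inherits(attribs, "sens_shap"))
  score <- if (type == "mean_abs") {
    colMeans(abs(attribs$averaged))
  } else {
    colMeans(attribs$averaged)
  }
  out <- tibble::tibble(feature = names(score), score = unname(score))
  out[order(-out$score, out$feature), ]
}

#' Concordance between the majority vote and the averaged attributions
#'
#' The sum of base value and averaged attributions is the mean margin
#' across learners; its sign can disagree with the majority vote when
#' a minority of learners hold extreme margins. Such substances are
#' flagged as discordant - an expected property of vote aggregation,
#' not an error.
#'
#' @param attribs A `sens_shap` for a set of substances.
#' @param predictions The matching [predict_vote()] tibble.
#' @return Tibble: `id`, `vote_label`, `vote_fraction`, `mean_margin`,
#'   `shap_label`, `concordant`.
#' @export
vote_shap_concordance <- function(attribs, predictions) {
  stopifnot(inherits(attribs, "sens_shap"))
  if (nrow(predictions) != length(attribs$ids)) {
    abort("attributions and predictions cover different substances",
          class = "skinsens_validation_error")
  }
  lv <- levels(predictions$.pred)
  mean_margin <- attribs$mean_margin
  shap_label <- factor(lv[(mean_margin > 0) + 1L], levels = lv)
  tibble::tibble(
    id = attribs$ids,
    vote_label = predictions$.pred,
    vote_fraction = predictions$vote_fraction,
    mean_margin = unname(mean_margin),
    shap_label = shap_label,
    concordant = shap_label == predictions$.pred
  )
}
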