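#' Binary confusion counts
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return Object of class `sens_cm2`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("confusion counts must be non-negative integers",
          class = "skinsens_domain_error")
  }
  if (sum(counts) == 0) {
    abort("confusion matrix is empty", class = "skinsens_domain_error")
  }
  structure(as.list(counts), class = "sens_cm2")
}

#' Confusion counts from labeled predictions
#'
#' @param truth,pred Binary vectors (0/1, logical, or a shared
#'   two-level factor with the positive class second).
#' @return A `sens_cm2`.
#' @export
confusion_from_predictions <- function(truth, pred) {
  as01 <- function(x) {
    if (is.factor(x)) as.integer(x) - 1L else as.integer(x)
  }
  t01 <- as01(truth)
  p01 <- as01(pred)
  stopifnot(length(t01) == length(p01))
  confusion_counts(
    tp = sum(t01 == 1 & p01 == 1), fn = sum(t01 == 1 & p01 == 0),
    fp = sum(t01 == 0 & p01 == 1), tn = sum(t01 == 0 & p01 == 0)
  )
}

#' Classification metrics from confusion counts
#'
#' Exact rational evaluation of the standard formulas:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), balanced accuracy =
#' (sensitivity+specificity)/2, and F1 = 2TP/(2TP+FP+FN). A metric
#' whose denominator is zero is reported as `NA` (undefined), never 0.
#'
#' @param cm A `sens_cm2` from [confusion_counts()].
#' @return Tibble with one row: `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `f1`.
#' @export
#' @examples
#' metrics_from_confusion(confusion_counts(tp = 13, fn = 4, fp = 1, tn = 7))
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "sens_cm2"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(cm$tp, cm$tp + cm$fn)
  spec <- safe_div(cm$tn, cm$tn + cm$fp)
  tibble::tibble(
    accuracy = safe_div(cm$tp + cm$tn, cm$tp + cm$tn + cm$fp + cm$fn),
    sensitivity = sens,
    specificity = spec,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    f1 = safe_div(2 * cm$tp, 2 * cm$tp + cm$fp + cm$fn)
  )
}

# Mann-Whitney ROC area: P(score_pos > score_neg) + 0.5 P(tie)
mann_whitney_auc <- function(truth01, scores) {
  pos <- scores[truth01 == 1]
  neg <- scores[truth01 == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' AUC variants for a majority-vote classifier
#'
#' A bagged majority vote yields both a hard label and a graded score
#' (the vote fraction), and "AUC-ROC" is ambiguous between the two.
#' `auc_hard` treats the hard label (vote fraction >= 0.6) as the
#' score; its two-point ROC has area equal to the balanced accuracy -
#' this is the variant that matches the reported numbers. `auc_score`
#' is the Mann-Whitney area over the vote fractions with ties counted
#' one half.
#'
#' @param truth Binary truth vector (0/1, logical, or two-level factor
#'   with the positive class second).
#' @param vote_fraction Numeric scores in `[0, 1]`.
#' @return Tibble with `auc_hard` and `auc_score`; both `NA` when only
#'   one class is present.
#' @export
auc_variants <- function(truth, vote_fraction) {
  t01 <- if (is.factor(truth)) as.integer(truth) - 1L else as.integer(truth)
  stopifnot(length(t01) == length(vote_fraction))
  hard <- as.numeric(vote_fraction >= 0.6)
  tibble::tibble(
    auc_hard = mann_whitney_auc(t01, hard),
    auc_score = mann_whitney_auc(t01, vote_fraction)
  )
}

#' Stage metrics for labeled test predictions
#'
#' Convenience wrapper: confusion counts, the five formula metrics and
#' both AUC variants in one row.
#'
#' @param truth Binary truth vector.
#' @param pred Hard predictions (same coding as `truth`).
#' @param vote_fraction Optional vote fractions; when supplied the AUC
#'   variants are computed from them (hard labels = fraction >= 0.6).
#' @return One-row tibble of metrics, with counts attached as the
#'   `confusion` attribute.
#' @export
stage_metrics <- function(truth, pred, vote_fraction = NULL) {
  cm <- confusion_from_predictions(truth, pred)
  out <- metrics_from_confusion(cm)
  if (!is.null(vote_fraction)) {
    out <- dplyr::bind_cols(out, auc_variants(truth, vote_fraction))
  }
  attr(out, "confusion") <- cm
  out
}

#' 3-class potency confusion matrix
#'
#' Rows are predicted classes, columns are human classes, in the order
#' NC, 1B, 1A.
#'
#' @param pred,truth Factors (or characters) with levels NC/1B/1A.
#' @return A 3x3 integer matrix of class `sens_cm3`.
#' @export
confusion_matrix3 <- function(pred, truth) {
  lv <- c("NC", "1B", "1A")
  pred <- factor(as.character(pred), levels = lv)
  truth <- factor(as.character(truth), levels = lv)
  if (anyNA(pred) || anyNA(truth)) {
    abort("classes must be NC, 1B or 1A", class = "skinsens_domain_error")
  }
  m <- table(predicted = pred, human = truth)
  structure(matrix(as.integer(m), 3, 3, dimnames = dimnames(m)),
            class = c("sens_cm3", "matrix"))
}

as_cm3 <- function(x) {
  if (inherits(x, "sens_cm3")) return(x)
  m <- as.matrix(x)
  stopifnot(all(dim(m) == c(3, 3)))
  dimnames(m) <- list(predicted = c("NC", "1B", "1A"),
                      human = c("NC", "1B", "1A"))
  structure(m, class = c("sens_cm3", "matrix"))
}

#' Potency categorization report
#'
#' Overall accuracy (trace over total) and, per human class, the
#' percentage correctly classified, underpredicted (predicted strictly
#' below the true class on the NC < 1B < 1A ordering) and overpredicted
#' (strictly above). Internal values are exact fractions; printing
#' rounds to one decimal place.
#'
#' @param cm3 A 3x3 matrix (predicted rows, human columns, order
#'   NC/1B/1A) or `sens_cm3`.
#' @return Object of class `sens_potency`: list with
#'   `overall_accuracy` (fraction), `per_class` tibble (`class`, `n`,
#'   `correct`, `underpredicted`, `overpredicted`, as fractions) and
#'   the counts.
#' @export
#' @examples
#' cm <- matrix(c(7, 1, 0, 4, 7, 1, 0, 1, 4), nrow = 3)
#' potency_table(cm)
potency_table <- function(cm3) {
  m <- as_cm3(cm3)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort("every human class must have at least one substance",
          class = "skinsens_domain_error")
  }
  ordv <- c(NC = 1, `1B` = 2, `1A` = 3)
  per <- lapply(1:3, function(j) {
    under <- sum(m[ordv < j, j])
    over <- sum(m[ordv > j, j])
    tibble::tibble(
      class = names(ordv)[j], n = as.integer(totals[j]),
      correct = unname(m[j, j] / totals[j]),
      underpredicted = unname(under / totals[j]),
      overpredicted = unname(over / totals[j])
    )
  })
  structure(list(
    overall_accuracy = sum(diag(m)) / sum(m),
    per_class = dplyr::bind_rows(per),
    counts = m
  ), class = "sens_potency")
}

#' @export
print.sens_potency <- function(x, ...) {
  cat("Potency categorization (predicted rows x human columns)\n")
  print(unclass(x$counts))
  cat(sprintf("\n%.0f%% correct classification overall\n",
              round(100 * x$overall_accuracy)))
  pc <- x$per_class
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", round(100 * v, 1)))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-3s (N=%2d): correct %s, under %s, over %s\n",
                pc$class[i], pc$n[i], fmt(pc$correct[i]),
                fmt(pc$underpredicted[i]), fmt(pc$overpredicted[i])))
  }
  invisible(x)
}

#' @method tidy sens_potency
#' @export
tidy.sens_potency <- function(x, ...) x$per_class

#' @method glance sens_potency
#' @export
glance.sens_potency <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 n = sum(x$counts))
}

#' Collapse a 3-class potency matrix to binary hazard counts
#'
#' Positive = sensitizer = \{1B, 1A\} for both predictions and truth;
#' NC is the negative class.
#'
#' @param cm3 A 3x3 potency confusion matrix.
#' @return A `sens_cm2`.
#' @export
#' @examples
#' cm <- matrix(c(7, 1, 0, 4, 7, 1, 0, 1, 4), nrow = 3)
#' collapse_to_binary(cm)  # TP 13, FN 4, FP 1, TN 7
collapse_to_binary <- function(cm3) {
  m <- as_cm3(cm3)
  pos <- c("1B", "1A")
  confusion_counts(
    tp = sum(m[pos, pos]), fn = sum(m["NC", pos]),
    fp = sum(m[pos, "NC"]), tn = m["NC", "NC"]
  )
}

#' @export
print.sens_cm2 <- function(x, ...) {
  cat("TP", x$tp, "FN", x$fn, "FP", x$fp, "TN", x$tn, "\n")
  invisible(x)
}

#' Applicability-domain ranges from training features
#'
#' The feature ranges of the training set define the applicability
#' domain: substances outside them are predicted with a higher
#' likelihood of error.
#'
#' @param features Numeric feature tibble of the training rows (no id).
#' @return Tibble of class `sens_domain`: `feature`, `min`, `max`,
#'   `q025`, `q975` (central-95% bounds).
#' @export
fit_domain_ranges <- function(features) {
  X <- as.data.frame(features)
  out <- tibble::tibble(
    feature = names(X),
    min = vapply(X, min, numeric(1), na.rm = TRUE, USE.NAMES = FALSE),
    max = vapply(X, max, numeric(1), na.rm = TRUE, USE.NAMES = FALSE),
    q025 = unname(vapply(X, quantile, numeric(1), probs = 0.025, na.rm = TRUE)),
    q975 = unname(vapply(X, quantile, numeric(1), probs = 0.975, na.rm = TRUE))
  )
  structure(out, class = c("sens_domain", class(out)))
}

#' Flag substances outside the applicability domain
#'
#' Flags every feature value outside its training range, and
#' additionally flags an EC1.5 exactly at the censoring cap (2000):
#' such substances carry an elevated false-negative risk because the
#' true concentration is only known to exceed the cap.
#'
#' @param ranges A `sens_domain` from [fit_domain_ranges()].
#' @param features Feature tibble to screen (with or without `id`).
#' @param ec15_feature Name of the capped EC1.5 feature; default
#'   `"EC1_5"`. Set `NULL` to skip the censoring flag.
#' @param cap Censoring cap; default 2000.
#' @return Long tibble: `id` (if present), `feature`, `value`,
#'   `out_of_range`, `censored`, `note`.
#' @export
domain_flags <- function(ranges, features, ec15_feature = "EC1_5", cap = 2000) {
  stopifnot(inherits(ranges, "sens_domain"))
  ids <- if ("id" %in% names(features)) as.character(features$id) else
    as.character(seq_len(nrow(features)))
  long <- tidyr::pivot_longer(
    dplyr::mutate(features[, intersect(c("id", ranges$feature), names(features))],
                  id = ids),
    -dplyr::all_of("id"), names_to = "feature", values_to = "value"
  )
  long <- dplyr::left_join(long, ranges[, c("feature", "min", "max")],
                           by = "feature")
  long$out_of_range <- !is.na(long$value) &
    (long$value < long$min | long$value > long$max)
  long$censored <- !is.null(ec15_feature) & long$feature %in% ec15_feature &
    !is.na(long$value) & long$value == cap
  long$note <- dplyr::case_when(
    long$censored ~ "EC1.5 at censoring cap: elevated false-negative risk",
    long$out_of_range ~ "outside training range",
    TRUE ~ ""
  )
  long[, c("id", "feature", "value", "out_of_range", "censored", "note")]
}
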