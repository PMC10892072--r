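#' Cap KeratinoSens EC1.5 at 2000
#'
#' EC1.5 values above 2000 are unreliable to measure and are substituted
#' with 2000; values at or below pass through, as do missing values.
#' The operation is monotone non-decreasing and bounded above by 2000.
#'
#' @param value Numeric vector of EC1.5 concentrations (positive or NA).
#' @param cap Upper bound (default 2000).
#' @return Capped numeric vector.
#' @export
#' @examples
#' cap_ec15(c(2500, 1500, NA))
cap_ec15 <- function(value, cap = 2000) {
  if (any(!is.na(value) & value <= 0)) {
    abort("EC1.5 must be positive", class = "skinsens_domain_error")
  }
  pmin(value, cap)
}

#' Encode in vitro assay readouts as model features
#'
#' DPRA cysteine- and lysine-peptide depletions enter as continuous
#' percentages, EC1.5 as a capped continuous value, h-CLAT as 0/1, and
#' SENS-IS as a 0/1 call (positive for any sensitizer class extreme
#' through weak, 0 for negative). Missing readouts propagate as missing.
#'
#' @param data Substance tibble.
#' @return Tibble with columns `id`, `C_peptide`, `K_peptide`, `EC1_5`,
#'   `h_CLAT`, `SENS_IS_cat`.
#' @export
encode_assays <- function(data) {
  sensis <- data$sensis_class %||% rep(NA_character_, nrow(data))
  tibble::tibble(
    id = data$id,
    C_peptide = as.numeric(data$dpra_c_depletion %||% rep(NA_real_, nrow(data))),
    K_peptide = as.numeric(data$dpra_k_depletion %||% rep(NA_real_, nrow(data))),
    EC1_5 = cap_ec15(as.numeric(data$keratinosens_ec15 %||% rep(NA_real_, nrow(data)))),
    h_CLAT = as.numeric(data$hclat_positive %||% rep(NA_real_, nrow(data))),
    SENS_IS_cat = dplyr::case_when(
      is.na(sensis) ~ NA_real_,
      sensis %in% c("extreme", "strong", "moderate", "weak") ~ 1,
      sensis == "negative" ~ 0
    )
  )
}

#' Assemble the full feature matrix for a substance table
#'
#' Binds encoded assay features, the SMILES embedding scalar and all
#' descriptor columns into one tibble keyed by `id`. If the table
#' already carries a `roberta_embedding_mean` column it is used as-is;
#' otherwise the scalar is computed from SMILES with `provider` (see
#' [smiles_scalar_feature()]).
#'
#' @param data Substance tibble.
#' @param provider Embedding provider used only when the embedding
#'   column is absent; default [fallback_provider()].
#' @return Tibble: `id`, assay features, `roberta_embedding_mean`,
#'   descriptors.
#' @export
build_feature_table <- function(data, provider = fallback_provider()) {
  feats <- encode_assays(data)
  if (.embedding_feature %in% names(data)) {
    feats[[.embedding_feature]] <- as.numeric(data[[.embedding_feature]])
  } else {
    feats[[.embedding_feature]] <- vapply(
      data$smiles, smiles_scalar_feature, numeric(1), provider = provider,
      USE.NAMES = FALSE
    )
  }
  desc <- descriptor_names(data)
  for (dc in desc) feats[[dc]] <- as.numeric(data[[dc]])
  feats
}

#' Drop rows with missing required features
#'
#' Substances lacking any of the required feature values are removed
#' (no imputation), preserving row order.
#'
#' @param features Feature tibble (with `id`).
#' @param required_features Character vector of feature columns that
#'   must be present; defaults to all non-id columns.
#' @return Filtered tibble; warns when everything is dropped.
#' @export
drop_incomplete <- function(features,
                            required_features = setdiff(names(features), "id")) {
  stray <- setdiff(required_features, names(features))
  if (length(stray) > 0) {
    abort(paste0("required features absent: ", paste(stray, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  if (length(required_features) == 0) return(features)
  keep <- !Reduce(`|`, lapply(features[required_features], is.na))
  out <- features[keep, , drop = FALSE]
  if (nrow(out) == 0 && nrow(features) > 0) {
    warn("all rows removed: every substance is missing a required feature")
  }
  out
}

#' Prune correlated features
#'
#' Greedy scan in column order: the first feature of every correlated
#' group is kept as its representative; any later feature whose
#' absolute Pearson correlation with an already-kept feature reaches
#' the threshold is dropped. Zero-variance features are dropped with an
#' undefined-correlation note. Deterministic given the column order.
#'
#' @param features Tibble or data frame of numeric feature columns
#'   (no id column).
#' @param threshold Correlation threshold in (0, 1]; default 0.75.
#' @param use_absolute Compare `|r|` (default) or signed `r` against the
#'   threshold.
#' @return List with `kept` (character vector) and `report` (tibble:
#'   `dropped`, `representative`, `r`, `reason`).
#' @export
#' @examples
#' X <- tibble::tibble(a = 1:10, b = (1:10) * 2, c = rnorm(10))
#' prune_correlated(X)$kept
prune_correlated <- function(features, threshold = 0.75, use_absolute = TRUE) {
  if (threshold <= 0 || threshold > 1) {
    abort("threshold must be in (0, 1]", class = "skinsens_domain_error")
  }
  X <- as.data.frame(features)
  if (nrow(X) < 2) abort("need at least 2 rows", class = "skinsens_domain_error")
  nm <- names(X)
  kept <- character(0)
  rep_of <- character(0)
  r_with <- numeric(0)
  reason <- character(0)
  dropped <- character(0)
  for (j in seq_along(nm)) {
    xj <- X[[j]]
    if (isTRUE(all.equal(var(xj, na.rm = TRUE), 0)) ||
        is.na(var(xj, na.rm = TRUE))) {
      dropped <- c(dropped, nm[j])
      rep_of <- c(rep_of, NA_character_)
      r_with <- c(r_with, NA_real_)
      reason <- c(reason, "zero variance (correlation undefined)")
      next
    }
    hit <- NA_character_
    hit_r <- NA_real_
    for (kcol in kept) {
      r <- suppressWarnings(cor(xj, X[[kcol]], use = "complete.obs"))
      cmp <- if (use_absolute) abs(r) else r
      if (!is.na(cmp) && cmp >= threshold) {
        hit <- kcol
        hit_r <- r
        break
      }
    }
    if (is.na(hit)) {
      kept <- c(kept, nm[j])
    } else {
      dropped <- c(dropped, nm[j])
      rep_of <- c(rep_of, hit)
      r_with <- c(r_with, hit_r)
      reason <- c(reason, "correlated with representative")
    }
  }
  list(
    kept = kept,
    report = tibble::tibble(dropped = dropped, representative = rep_of,
                            r = r_with, reason = reason)
  )
}

#' Fit a standardizer on training features
#'
#' Records per-feature mean and population standard deviation
#' (denominator n), so that the transformed training columns have mean
#' 0 and variance exactly 1.
#'
#' @param features Numeric feature tibble (training rows only, no id).
#' @return Object of class `sens_scaler`.
#' @export
fit_standardizer <- function(features) {
  X <- as.data.frame(features)
  mu <- vapply(X, mean, numeric(1))
  sd_pop <- vapply(X, function(x) sqrt(mean((x - mean(x))^2)), numeric(1))
  zero <- names(X)[sd_pop == 0 | is.na(sd_pop)]
  if (length(zero) > 0) {
    abort(paste0("zero-variance training column(s): ",
                 paste(zero, collapse = ", ")),
          class = "skinsens_domain_error")
  }
  structure(list(mean = mu, sd = sd_pop, features = names(X)),
            class = "sens_scaler")
}

#' Apply a fitted standardizer
#'
#' @param state A `sens_scaler` from [fit_standardizer()].
#' @param features Feature tibble containing at least the scaler's
#'   columns; extra columns pass through untouched.
#' @return Tibble with the scaler's columns centered and scaled by the
#'   training statistics.
#' @export
apply_standardizer <- function(state, features) {
  stopifnot(inherits(state, "sens_scaler"))
  missing_cols <- setdiff(state$features, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features absent: ", paste(missing_cols, collapse = ", ")),
          class = "skinsens_schema_error")
  }
  out <- features
  for (f in state$features) {
    out[[f]] <- (out[[f]] - state$mean[[f]]) / state$sd[[f]]
  }
  out
}

#' Serialize / restore a standardizer as plain text
#'
#' Tab-separated `feature / mean / sd` records with full double
#' precision, for exact reload.
#'
#' @param state A `sens_scaler`.
#' @param path Output (or input) file path.
#' @return `write_scaler`: the path, invisibly. `read_scaler`: a
#'   `sens_scaler`.
#' @export
write_scaler <- function(state, path) {
  stopifnot(inherits(state, "sens_scaler"))
  df <- data.frame(feature = state$features,
                   mean = sprintf("%.17g", state$mean),
                   sd = sprintf("%.17g", state$sd))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  df <- readr::read_tsv(path, col_types = "cdd", progress = FALSE)
  structure(list(mean = setNames(df$mean, df$feature),
                 sd = setNames(df$sd, df$feature),
                 features = df$feature),
            class = "sens_scaler")
}

#' Stratified train/test split
#'
#' Splits substances into training and testing sets at the requested
#' fraction while keeping the potency-category proportions equal
#' between the two sets. The total test size is `ceiling(n * fraction)`;
#' per-stratum test counts are allocated by largest remainder.
#' Singleton strata go to training with a warning. Sampling is keyed to
#' sorted substance ids, so the split is invariant to row order.
#'
#' @param data Substance tibble with a `potency_category` column (or
#'   the column named by `stratify_by`).
#' @param test_fraction Fraction of substances held out; default 0.2.
#' @param stratify_by Stratification column; default `potency_category`.
#' @param seed Integer seed.
#' @return Object of class `sens_split`: list with `train_ids`,
#'   `test_ids` and a `stratum_counts` tibble.
#' @export
#' @examples
#' d <- simulate_substances(synthetic_config(n = 122, seed = 1))
#' sp <- stratified_split(d, seed = 7)
#' length(sp$train_ids); length(sp$test_ids)  # 97, 25
stratified_split <- function(data, test_fraction = 0.2,
                             stratify_by = "potency_category", seed) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be in (0, 1)", class = "skinsens_domain_error")
  }
  strata <- data[[stratify_by]]
  if (anyNA(strata)) {
    abort("stratification column has missing values",
          class = "skinsens_validation_error")
  }
  ids <- as.character(data$id)
  levels_order <- sort(unique(strata))
  n_s <- vapply(levels_order, function(s) sum(strata == s), numeric(1))
  n_total <- length(ids)
  n_test <- as.integer(ceiling(n_total * test_fraction))

  exact <- n_s * test_fraction
  quota <- floor(exact)
  singleton <- n_s == 1
  if (any(singleton)) {
    warn(paste0("stratum/strata of size 1 assigned to training: ",
                paste(levels_order[singleton], collapse = ", ")))
    quota[singleton] <- 0
  }
  remainder <- exact - floor(exact)
  remainder[singleton] <- -Inf
  deficit <- n_test - sum(quota)
  if (deficit > 0) {
    order_idx <- order(-remainder, seq_along(remainder))
    gi <- 0L
    while (deficit > 0 && gi < length(order_idx)) {
      gi <- gi + 1L
      s <- order_idx[gi]
      if (!singleton[s] && quota[s] < n_s[s]) {
        quota[s] <- quota[s] + 1
        deficit <- deficit - 1
      }
    }
  }

  set.seed(seed)
  test_ids <- character(0)
  for (k in seq_along(levels_order)) {
    sids <- sort(ids[strata == levels_order[k]])
    if (quota[k] > 0) {
      test_ids <- c(test_ids, sample(sids, quota[k]))
    }
  }
  train_ids <- setdiff(ids, test_ids)
  counts <- tibble::tibble(
    stratum = levels_order,
    n = as.integer(n_s),
    n_train = as.integer(n_s - quota),
    n_test = as.integer(quota)
  )
  structure(list(train_ids = train_ids, test_ids = sort(test_ids),
                 stratum_counts = counts, seed = seed,
                 test_fraction = test_fraction),
            class = "sens_split")
}

#' @export
print.sens_split <- function(x, ...) {
  cat("Stratified split:", length(x$train_ids), "train /",
      length(x$test_ids), "test (seed", x$seed, ")\n")
  print(x$stratum_counts)
  invisible(x)
}
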