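test_that("averaged importance is the per-feature mean of per-learner gains", {
  fx <- fixture_hazard()
  imp <- average_importance(fx$model)
  gain_cols <- paste0("gain_", 1:5)
  expect_equal(imp$mean_gain, rowMeans(as.matrix(imp[, gain_cols])))
  # per-learner gains are normalized, so each column sums to 1
  for (gc in gain_cols) expect_equal(sum(imp[[gc]]), 1, tolerance = 1e-6)
  expect_true(all(imp$mean_gain >= 0))
  expect_setequal(imp$feature, fx$model$feature_names)
  # the total importance mass is invariant to feature column order
  perm_feats <- fx$feats_tr[, c("id", sample(setdiff(names(fx$feats_tr), "id")))]
  m2 <- fit_bagged(perm_feats, fx$lab_tr, tiny_grid(), seed = 99)
  imp2 <- average_importance(m2)
  expect_equal(sum(imp2$mean_gain), sum(imp$mean_gain), tolerance = 1e-9)
  expect_setequal(imp2$feature, imp$feature)
})

test_that("gain importance matches the loss-reduction formula on a stump", {
  set.seed(2)
  x1 <- rnorm(100)
  y <- as.integer(x1 > 0.3)
  X <- cbind(f1 = x1, f2 = rnorm(100))
  m <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1, eta = 1,
                  nthread = 1, seed = 1, lambda = 1, base_score = 0.5),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 1)
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = m))
  expect_equal(tr$Feature[1], "f1")
  # oracle: logistic loss reduction at the root, g = p0 - y, h = p0(1 - p0)
  left <- x1 < tr$Split[1]
  g <- 0.5 - y
  GL <- sum(g[left]); GR <- sum(g[!left])
  HL <- 0.25 * sum(left); HR <- 0.25 * sum(!left)
  oracle_gain <- GL^2 / (HL + 1) + GR^2 / (HR + 1) -
    (GL + GR)^2 / (HL + HR + 1)
  expect_equal(tr$Gain[1], oracle_gain, tolerance = 1e-6)
  # the unused feature carries zero importance
  imp <- xgboost::xgb.importance(model = m)
  expect_false("f2" %in% imp$Feature)
  expect_equal(imp$Gain[imp$Feature == "f1"], 1)
})

test_that("top-k includes every feature tied with the k-th", {
  tab <- tibble::tibble(feature = c("a", "b", "c", "d"),
                        mean_gain = c(5, 4, 3, 3))
  expect_equal(top_k_features(tab, 3), c("a", "b", "c", "d"))
  tab2 <- tibble::tibble(feature = letters[1:4], mean_gain = c(5, 4, 3, 2))
  expect_equal(top_k_features(tab2, 3), c("a", "b", "c"))
  expect_equal(top_k_features(tab2, 4), letters[1:4])
  expect_error(top_k_features(tab2, 0), class = "skinsens_domain_error")
  expect_error(top_k_features(tab2, 9), class = "skinsens_domain_error")
  # superset property: never omits a feature above the k-th value
  set.seed(5)
  for (i in 1:20) {
    gains <- round(runif(10), 1)  # rounded to force occasional ties
    t3 <- tibble::tibble(feature = letters[1:10], mean_gain = gains)
    got <- top_k_features(t3, 4)
    kth <- sort(gains, decreasing = TRUE)[4]
    expect_setequal(got, t3$feature[t3$mean_gain >= kth])
  }
})

test_that("assay substitution swaps the weakest assay for the best outsider", {
  imp <- tibble::tibble(
    feature = c("C_peptide", "K_peptide", "phys1", "phys2"),
    mean_gain = c(0.1, 0.3, 0.5, 0.2)
  )
  out <- substitute_assay(c("C_peptide", "K_peptide", "phys1"), imp)
  expect_setequal(out, c("K_peptide", "phys1", "phys2"))
  expect_length(out, 3)
  # applying twice removes two distinct assay features
  imp6 <- tibble::tibble(
    feature = c("C_peptide", "K_peptide", "h_CLAT", "p1", "p2", "p3"),
    mean_gain = c(0.05, 0.10, 0.02, 0.40, 0.30, 0.20)
  )
  once <- substitute_assay(c("C_peptide", "K_peptide", "h_CLAT", "p1"), imp6)
  expect_false("h_CLAT" %in% once)      # weakest assay removed
  expect_true("p2" %in% once)           # strongest outsider added
  twice <- substitute_assay(once, imp6)
  expect_false(any(c("h_CLAT", "C_peptide") %in% twice))
  expect_true(all(c("p1", "p2", "p3") %in% twice))
  # errors: no assay selected / empty pool
  expect_error(substitute_assay(c("p1", "p2"), imp6),
               class = "skinsens_domain_error")
  expect_error(substitute_assay(imp$feature, imp),
               class = "skinsens_domain_error")
})

test_that("feature-set comparison favors signal, then parsimony, then substitution", {
  fx <- fixture_hazard()
  # single candidate returns trivially
  solo <- compare_feature_sets(
    fx$feats_tr, fx$lab_tr, fx$feats_te, fx$lab_te,
    candidates = list(all = setdiff(names(fx$feats_tr), "id")),
    grid = tiny_grid(), seed = 99)
  expect_equal(solo$chosen, "all")

  # informative features beat pure-noise descriptors in most seeds
  informative <- c("EC1_5", "C_peptide", "K_peptide", "SENS_IS_cat")
  noise <- grep("^phys2", names(fx$feats_tr), value = TRUE)[1:4]  # blocks 2-3
  wins <- 0
  for (s in 1:5) {
    cmp <- compare_feature_sets(
      fx$feats_tr, fx$lab_tr, fx$feats_te, fx$lab_te,
      candidates = list(signal = informative, noise = noise),
      grid = tiny_grid(), seed = s)
    wins <- wins + (cmp$chosen == "signal")
  }
  expect_gte(wins, 3)

  # exact tie (identical candidate refitted under one seed): the
  # substituted variant is preferred
  tie <- compare_feature_sets(
    fx$feats_tr, fx$lab_tr, fx$feats_te, fx$lab_te,
    candidates = list(plain = informative, swapped = informative),
    grid = tiny_grid(), seed = 99, substituted = "swapped")
  expect_equal(tie$results$balanced_accuracy[1], tie$results$balanced_accuracy[2])
  expect_equal(tie$chosen, "swapped")
})
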