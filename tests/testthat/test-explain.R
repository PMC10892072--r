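test_that("attributions are additive to each learner's margin", {
  fx <- fixture_hazard()
  sh <- shap_attributions(fx$model, fx$feats_te)
  for (l in seq_along(sh$per_learner)) {
    recon <- rowSums(sh$per_learner[[l]])
    expect_true(all(abs(recon - sh$margins[, l]) < 1e-6))
  }
  # averaging attributions equals attributing the average margin
  avg_recon <- mean(sh$base_values) + rowSums(sh$averaged)
  expect_equal(unname(avg_recon), unname(sh$mean_margin), tolerance = 1e-6)
})

test_that("tree-path attributions match a brute-force 2-player Shapley", {
  set.seed(9)
  n <- 150
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- as.integer(x1 + 0.5 * x2 + 0.3 * x1 * x2 > 0)
  X <- cbind(f1 = x1, f2 = x2)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 2, eta = 0.5,
                  nthread = 1, seed = 1, base_score = 0.5),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 3)
  res <- skinsens:::tree_shap_contrib(booster, X[1:5, , drop = FALSE],
                                      c("f1", "f2"))
  for (i in 1:5) {
    oracle <- oracle_shapley2(booster, as.list(as.data.frame(t(X[i, ]))),
                              c("f1", "f2"))
    expect_equal(unname(res$contrib[i, "BIAS"]), unname(oracle["base"]),
                 tolerance = 1e-6)
    expect_equal(unname(res$contrib[i, "f1"]), unname(oracle["phi1"]),
                 tolerance = 1e-6)
    expect_equal(unname(res$contrib[i, "f2"]), unname(oracle["phi2"]),
                 tolerance = 1e-6)
  }
})

test_that("double-precision attributions agree with the tree library's own", {
  fx <- fixture_hazard()
  X <- as.matrix(fx$feats_te[, fx$model$feature_names])
  d <- xgboost::xgb.DMatrix(X)
  for (l in seq_len(2)) {
    booster <- fx$model$learners[[l]]
    lib <- predict(booster, d, predcontrib = TRUE)
    lib <- matrix(lib, nrow = nrow(X))
    mine <- skinsens:::tree_shap_contrib(booster, X, fx$model$feature_names)
    expect_equal(unname(mine$contrib), unname(lib), tolerance = 1e-4)
  }
})

test_that("a stump learner attributes only through its split feature", {
  set.seed(4)
  x1 <- rnorm(120)
  X <- cbind(f1 = x1, f2 = rnorm(120))
  y <- as.integer(x1 > 0)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 1, eta = 1,
                  nthread = 1, seed = 1, base_score = 0.5),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = 1)
  res <- skinsens:::tree_shap_contrib(booster, X, c("f1", "f2"))
  expect_true(all(res$contrib[, "f2"] == 0, na.rm = FALSE))
  expect_true(any(res$contrib[, "f1"] != 0))
  # closed form for a stump: attribution = leaf value minus the
  # cover-weighted expectation, only through the split feature
  tr <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  expected <- (tr$Cover[2] * tr$Gain[2] + tr$Cover[3] * tr$Gain[3]) /
    (tr$Cover[2] + tr$Cover[3])
  leaf_of <- ifelse(skinsens:::float32(x1) < skinsens:::float32(tr$Split[1]),
                    tr$Gain[2], tr$Gain[3])
  expect_equal(unname(res$contrib[, "f1"]), leaf_of - expected,
               tolerance = 1e-9)
})

test_that("summary ranking orders by mean |attribution| with alphabetical ties", {
  fx <- fixture_hazard()
  sh <- shap_attributions(fx$model, fx$feats_te)
  rk <- shap_summary_ranking(sh)
  expect_equal(rk$score, sort(colMeans(abs(sh$averaged)), decreasing = TRUE),
               ignore_attr = TRUE)
  # all-zero attributions fall back to alphabetical order
  fake <- structure(list(averaged = matrix(0, 2, 3,
                                           dimnames = list(NULL, c("c", "a", "b")))),
                    class = "sens_shap")
  expect_equal(shap_summary_ranking(fake)$feature, c("a", "b", "c"))
  # signed variant can differ from the magnitude variant
  rk2 <- shap_summary_ranking(sh, type = "mean")
  expect_true(all(rk2$score == sort(colMeans(sh$averaged), decreasing = TRUE)))
})

test_that("a dominant feature ranks first across seeds", {
  firsts <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 150
    strong <- rnorm(n)
    feats <- tibble::tibble(
      id = sprintf("r%03d", 1:n),
      dominant = strong,
      weak1 = rnorm(n), weak2 = rnorm(n), weak3 = rnorm(n)
    )
    lab <- factor(ifelse(strong + rnorm(n, 0, 0.3) > 0, "pos", "neg"),
                  levels = c("neg", "pos"))
    m <- fit_bagged(feats, lab, tiny_grid(), seed = s)
    rk <- shap_summary_ranking(shap_attributions(m, feats[1:50, ]))
    firsts <- firsts + (rk$feature[1] == "dominant")
  }
  expect_gte(firsts, 8)
})

test_that("vote/SHAP discordance is flagged, unanimity is always concordant", {
  fx <- fixture_hazard()
  sh <- shap_attributions(fx$model, fx$feats_te)
  conc <- vote_shap_concordance(sh, fx$pred)
  unan <- conc$vote_fraction %in% c(0, 1)
  expect_true(all(conc$concordant[unan]))
  # hand-built 3-vs-2 vote with extreme minority margins is discordant
  fake_sh <- structure(list(
    averaged = matrix(c(0.5, 0.5), 1, 2, dimnames = list("z1", c("a", "b"))),
    mean_margin = c(z1 = -2),   # minority learners dominate the mean margin
    ids = "z1"
  ), class = "sens_shap")
  fake_pred <- tibble::tibble(
    id = "z1",
    .pred = factor("positive", levels = c("negative", "positive")),
    vote_fraction = 0.6,
    votes = list(c(1L, 1L, 1L, 0L, 0L))
  )
  flag <- vote_shap_concordance(fake_sh, fake_pred)
  expect_false(flag$concordant)
  expect_error(vote_shap_concordance(sh, fake_pred),
               class = "skinsens_validation_error")
})
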