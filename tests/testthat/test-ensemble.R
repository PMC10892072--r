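test_that("the default tuning grids enumerate the documented search space", {
  g <- hyper_grid("hazard")
  expect_equal(nrow(g), 3 * 5 * 4 * 3 * 2)
  expect_setequal(unique(g$scale_pos_weight), c(0.5, 1.0))
  expect_setequal(unique(hyper_grid("potency")$scale_pos_weight), c(1.0, 2.0))
  # lexicographic enumeration in field order
  expect_equal(g$learning_rate[1], 0.01)
  expect_true(all(diff(order(g$learning_rate, g$n_estimators, g$max_depth,
                             g$subsample, g$scale_pos_weight)) == 1))
  expect_error(hyper_grid("hazard", learning_rate = -1),
               class = "skinsens_domain_error")
})

test_that("bootstrap subsets have the rounded size and contain duplicates", {
  ids100 <- sprintf("s%03d", 1:100)
  subs <- make_subsets(ids100, k = 5, fraction = 0.8, seed = 1)
  expect_length(subs, 5)
  expect_true(all(lengths(subs) == 80))
  ids97 <- sprintf("s%03d", 1:97)
  expect_true(all(lengths(make_subsets(ids97, seed = 1)) == 78))  # round(77.6)
  expect_error(make_subsets(ids100, fraction = 0), class = "skinsens_domain_error")
  expect_error(make_subsets(character(0), seed = 1), class = "skinsens_domain_error")
  # with replacement, a duplicate is near-certain (birthday effect)
  ids50 <- sprintf("s%02d", 1:50)
  dup_seen <- vapply(1:100, function(s) {
    any(vapply(make_subsets(ids50, seed = s), anyDuplicated, integer(1)) > 0)
  }, logical(1))
  expect_true(all(dup_seen))
  expect_identical(make_subsets(ids100, seed = 7), make_subsets(ids100, seed = 7))
})

test_that("grid search maximizes CV balanced accuracy and is decisive on blobs", {
  set.seed(11)
  n <- 200
  X <- rbind(matrix(rnorm(n / 2 * 5, 0), ncol = 5),
             matrix(rnorm(n / 2 * 5, 6), ncol = 5))  # 6-sd separation
  colnames(X) <- paste0("f", 1:5)
  y <- rep(c(0L, 1L), each = n / 2)
  single <- tiny_grid()
  tuned <- tune_base_learner(X, y, single, seed = 5)
  expect_equal(as.data.frame(tuned$params), as.data.frame(single[1, ]))
  expect_gte(tuned$cv_balanced_accuracy, 0.95)
})

test_that("shuffled labels give chance-level CV balanced accuracy", {
  set.seed(21)
  X <- matrix(rnorm(150 * 4), ncol = 4)
  colnames(X) <- paste0("f", 1:4)
  scores <- vapply(1:8, function(s) {
    set.seed(s)
    y <- sample(rep(c(0L, 1L), length.out = 150))
    tune_base_learner(X, y, tiny_grid(), seed = s)$cv_balanced_accuracy
  }, numeric(1))
  expect_gte(mean(scores), 0.4)
  expect_lte(mean(scores), 0.6)
})

test_that("fold count shrinks with a warning when the minority class is tiny", {
  set.seed(3)
  X <- matrix(rnorm(40 * 3), ncol = 3)
  colnames(X) <- paste0("f", 1:3)
  y <- c(rep(0L, 37), rep(1L, 3))
  expect_warning(tuned <- tune_base_learner(X, y, tiny_grid(), folds = 5, seed = 2),
                 "reducing CV folds")
  expect_s3_class(tuned$params, "tbl_df")
  expect_error(tune_base_learner(X, rep(0L, 40), tiny_grid(), seed = 1),
               class = "skinsens_domain_error")
})

test_that("bagging yields five learners, deterministic under the seed", {
  fx <- fixture_hazard()
  m <- fx$model
  expect_length(m$learners, 5)
  expect_equal(nrow(tidy(m)), 5)
  m2 <- fit_bagged(fx$feats_tr, fx$lab_tr, tiny_grid(), seed = 99)
  expect_equal(tidy(m2), tidy(m))
  expect_identical(predict_vote(m2, fx$feats_te), fx$pred)
  m3 <- fit_bagged(fx$feats_tr, fx$lab_tr, tiny_grid(), seed = 100)
  expect_false(identical(m3$subset_ids, m$subset_ids))
})

test_that("fitting is invariant to the row order of the training table", {
  fx <- fixture_hazard()
  set.seed(1)
  perm <- sample(nrow(fx$feats_tr))
  m_shuffled <- fit_bagged(fx$feats_tr[perm, ], fx$lab_tr[perm],
                           tiny_grid(), seed = 99)
  expect_identical(m_shuffled$subset_ids, fx$model$subset_ids)
  expect_identical(predict_vote(m_shuffled, fx$feats_te), fx$pred)
})

test_that("majority voting with five learners is always decisive", {
  fx <- fixture_hazard()
  p <- fx$pred
  expect_true(all(p$vote_fraction %in% c(0, 0.2, 0.4, 0.6, 0.8, 1)))
  expect_equal(p$.pred == "sensitizer", p$vote_fraction >= 0.6)
  expect_equal(vapply(p$votes, mean, numeric(1)), p$vote_fraction)
  # never a tie: fraction 0.5 is unreachable with 5 voters
  expect_false(any(p$vote_fraction == 0.5))
})

test_that("prediction demands every training feature by name", {
  fx <- fixture_hazard()
  crippled <- fx$feats_te[, setdiff(names(fx$feats_te), "EC1_5")]
  expect_error(predict_vote(fx$model, crippled), "EC1_5",
               class = "skinsens_schema_error")
})

test_that("held-out balanced accuracy is high under strong synthetic signal", {
  fx <- fixture_hazard()
  ba <- balanced_accuracy(as.integer(fx$lab_te) - 1L,
                          as.integer(fx$pred$.pred) - 1L)
  expect_gte(ba, 0.85)
})
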