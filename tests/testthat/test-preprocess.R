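test_that("EC1.5 capping is exact at and around the bound and monotone", {
  expect_equal(cap_ec15(2500), 2000)
  expect_equal(cap_ec15(1500), 1500)
  expect_equal(cap_ec15(2000), 2000)
  expect_true(is.na(cap_ec15(NA_real_)))
  expect_error(cap_ec15(-1), class = "skinsens_domain_error")
  set.seed(1)
  x <- sort(exp(rnorm(100, 7, 1.5)))
  capped <- cap_ec15(x)
  expect_true(all(diff(capped) >= 0))
  expect_true(all(capped <= 2000))
})

test_that("assay encoding binarizes SENS-IS and propagates missingness", {
  d <- tibble::tibble(
    id = letters[1:5], smiles = rep("CCO", 5),
    dpra_c_depletion = c(10, 20, NA, 40, 50),
    dpra_k_depletion = 1:5,
    keratinosens_ec15 = c(2500, 100, 300, NA, 50),
    hclat_positive = c(1, 0, NA, 1, 0),
    sensis_class = c("weak", "negative", "extreme", NA, "moderate")
  )
  enc <- encode_assays(d)
  expect_equal(enc$SENS_IS_cat, c(1, 0, 1, NA, 1))
  expect_equal(enc$EC1_5, c(2000, 100, 300, NA, 50))
  expect_true(is.na(enc$h_CLAT[3]))
  expect_true(is.na(enc$C_peptide[3]))
})

test_that("incomplete-row removal counts and preserves order", {
  f <- tibble::tibble(id = letters[1:5], a = c(1, NA, 3, 4, 5), b = 1:5)
  expect_equal(drop_incomplete(f, "a")$id, c("a", "c", "d", "e"))
  expect_equal(drop_incomplete(f, character(0)), f)
  f2 <- tibble::tibble(id = "x", a = NA_real_)
  expect_warning(out <- drop_incomplete(f2, "a"), "all rows removed")
  expect_equal(nrow(out), 0)
  expect_error(drop_incomplete(f, "zz"), class = "skinsens_schema_error")
})

test_that("pruning keeps the first of identical columns and leaves independent ones", {
  X <- tibble::tibble(A = as.numeric(1:10), B = as.numeric(1:10) * 2 + 3,
                      C = c(2, 5, 1, 9, 3, 7, 4, 8, 6, 10))
  res <- prune_correlated(X)
  expect_equal(res$kept, c("A", "C"))
  expect_equal(res$report$dropped, "B")
  expect_equal(res$report$representative, "A")
  expect_equal(res$report$r, 1)

  set.seed(42)
  Y <- tibble::tibble(u = rnorm(200), v = rnorm(200))
  expect_lt(abs(cor(Y$u, Y$v)), 0.75)  # independent draws stay uncorrelated
  expect_equal(prune_correlated(Y)$kept, c("u", "v"))
})

test_that("greedy pruning on a correlation chain satisfies its postconditions", {
  set.seed(7)
  A <- rnorm(300)
  B <- 0.95 * A + sqrt(1 - 0.95^2) * rnorm(300)   # r(A,B) ~ 0.95
  C <- 0.6 * A + sqrt(1 - 0.6^2) * rnorm(300)     # r(A,C) ~ 0.6 < 0.75
  X <- tibble::tibble(A = A, B = B, C = C)
  res <- prune_correlated(X, threshold = 0.75)
  expect_equal(res$kept, c("A", "C"))
  # brute-force oracle over all pairs
  for (i in seq_along(res$kept)) {
    for (j in seq_len(i - 1)) {
      expect_lt(abs(cor(X[[res$kept[i]]], X[[res$kept[j]]])), 0.75)
    }
  }
  for (r in seq_len(nrow(res$report))) {
    expect_gte(abs(cor(X[[res$report$dropped[r]]],
                       X[[res$report$representative[r]]])), 0.75)
  }
})

test_that("pruning drops zero-variance features with a reason", {
  X <- tibble::tibble(a = rnorm(10), flat = rep(3, 10))
  res <- prune_correlated(X)
  expect_equal(res$kept, "a")
  expect_match(res$report$reason[res$report$dropped == "flat"], "zero variance")
})

test_that("standardizer gives mean 0 / population variance 1 and reloads exactly", {
  X <- tibble::tibble(x = c(1, 2, 3))
  st <- fit_standardizer(X)
  z <- apply_standardizer(st, X)$x
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(mean(z^2), 1, tolerance = 1e-12)  # population variance
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2))
  # a test value at the training mean maps to 0
  expect_equal(apply_standardizer(st, tibble::tibble(x = 2))$x, 0)
  # re-standardizing already-scaled data with the same state is not identity
  expect_false(isTRUE(all.equal(apply_standardizer(st, z_tbl <- tibble::tibble(x = z))$x, z)))

  expect_error(fit_standardizer(tibble::tibble(ok = 1:3, flat = rep(2, 3))),
               "flat", class = "skinsens_domain_error")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_scaler(st, path)
  st2 <- read_scaler(path)
  expect_identical(st2$mean, st$mean)
  expect_identical(st2$sd, st$sd)
})

test_that("stratified split reproduces the 97/25 partition from n = 122", {
  d <- simulate_substances(synthetic_config(n = 122, seed = 4))
  sp <- stratified_split(d, test_fraction = 0.2, seed = 9)
  expect_length(sp$train_ids, 97)
  expect_length(sp$test_ids, 25)
  expect_setequal(c(sp$train_ids, sp$test_ids), d$id)
})

test_that("split rounding follows largest remainder within strata", {
  d <- tibble::tibble(id = sprintf("x%02d", 1:10), smiles = "CCO",
                      potency_category = rep(1L, 10))
  sp <- stratified_split(d, 0.2, seed = 1)
  expect_length(sp$test_ids, 2)

  d2 <- tibble::tibble(id = sprintf("y%03d", 1:100), smiles = "CCO",
                       potency_category = rep(c(1L, 5L), each = 50))
  sp2 <- stratified_split(d2, 0.2, seed = 1)
  expect_equal(sp2$stratum_counts$n_test, c(10L, 10L))
})

test_that("split invariants hold over many seeds", {
  d <- simulate_substances(synthetic_config(n = 122, seed = 8))
  n_s <- table(d$potency_category)
  for (s in 1:100) {
    sp <- stratified_split(d, 0.2, seed = s)
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    expect_setequal(c(sp$train_ids, sp$test_ids), d$id)
    # per-stratum proportion within 1/stratum-size of the target
    for (k in seq_len(nrow(sp$stratum_counts))) {
      row <- sp$stratum_counts[k, ]
      expect_lt(abs(row$n_test / row$n - 0.2), 1 / row$n + 1e-12)
    }
  }
  expect_identical(stratified_split(d, 0.2, seed = 3)$test_ids,
                   stratified_split(d, 0.2, seed = 3)$test_ids)
})

test_that("singleton strata go to training with a warning", {
  d <- tibble::tibble(id = c(sprintf("a%02d", 1:12), "lone"), smiles = "CCO",
                      potency_category = c(rep(3L, 12), 6L))
  expect_warning(sp <- stratified_split(d, 0.2, seed = 2), "size 1")
  expect_true("lone" %in% sp$train_ids)
})
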