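# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small tuning grid: a single point, so tests exercise the bagging and
# voting machinery without paying for a search.
tiny_grid <- function(stage = "hazard", spw = 1) {
  hyper_grid(stage, learning_rate = 0.1, n_estimators = 50, max_depth = 3,
             subsample = 0.8, scale_pos_weight = spw)
}

# A trained hazard-stage bagged model on strong-signal synthetic data,
# with its train/test tables, labels and predictions.
fixture_hazard <- function() {
  if (!is.null(.fixture_env$hazard)) return(.fixture_env$hazard)
  d <- simulate_substances(synthetic_config(n = 150, effect = 2, seed = 202))
  sp <- stratified_split(d, seed = 202)
  tr <- d[d$id %in% sp$train_ids, ]
  te <- d[d$id %in% sp$test_ids, ]
  feats_tr <- build_feature_table(tr)
  feats_te <- build_feature_table(te)
  lab_tr <- derive_labels(tr$potency_category)$hazard
  lab_te <- derive_labels(te$potency_category)$hazard
  model <- fit_bagged(feats_tr, lab_tr, tiny_grid(), seed = 99)
  .fixture_env$hazard <- list(
    data = d, train = tr, test = te,
    feats_tr = feats_tr, feats_te = feats_te,
    lab_tr = lab_tr, lab_te = lab_te,
    model = model,
    pred = predict_vote(model, feats_te)
  )
  .fixture_env$hazard
}

# A trained two-stage cascade on the same kind of data.
fixture_cascade <- function() {
  if (!is.null(.fixture_env$cascade)) return(.fixture_env$cascade)
  d <- simulate_substances(synthetic_config(n = 160, effect = 2, seed = 303))
  sp <- stratified_split(d, seed = 303)
  tr <- d[d$id %in% sp$train_ids, ]
  te <- d[d$id %in% sp$test_ids, ]
  cfg <- cascade_config(grid_hazard = tiny_grid("hazard"),
                        grid_potency = tiny_grid("potency"))
  model <- sens_train(tr, cfg, seed = 77)
  .fixture_env$cascade <- list(data = d, train = tr, test = te,
                               config = cfg, model = model)
  .fixture_env$cascade
}

# The 3x3 potency counts printed for the emulated study's test set
# (predicted rows x human columns, order NC/1B/1A).
reference_cm3 <- function() {
  matrix(c(7, 1, 0,
           4, 7, 1,
           0, 1, 4), nrow = 3,
         dimnames = list(predicted = c("NC", "1B", "1A"),
                         human = c("NC", "1B", "1A")))
}

# Path-dependent expected margin of one booster when only the features
# in `known` are observed: unknown-feature nodes average their children
# weighted by training cover. Independent oracle for TreeSHAP.
oracle_expected_margin <- function(booster, x, known) {
  tr <- xgboost::xgb.model.dt.tree(model = booster)
  tr <- as.data.frame(tr)
  total <- 0
  for (tree_id in unique(tr$Tree)) {
    nodes <- tr[tr$Tree == tree_id, ]
    rownames(nodes) <- nodes$ID
    walk <- function(id) {
      node <- nodes[id, ]
      if (node$Feature == "Leaf") return(node$Gain)  # leaf value
      if (node$Feature %in% known) {
        # route at the model's storage precision (single)
        go_yes <- skinsens:::float32(x[[node$Feature]]) <
          skinsens:::float32(node$Split)
        return(walk(if (go_yes) node$Yes else node$No))
      }
      cy <- nodes[node$Yes, "Cover"]
      cn <- nodes[node$No, "Cover"]
      (cy * walk(node$Yes) + cn * walk(node$No)) / (cy + cn)
    }
    total <- total + walk(nodes$ID[nodes$Node == 0])
  }
  total
}

# Exact 2-player Shapley values of the path-dependent value function.
oracle_shapley2 <- function(booster, x, features) {
  stopifnot(length(features) == 2)
  v0 <- oracle_expected_margin(booster, x, character(0))
  v1 <- oracle_expected_margin(booster, x, features[1])
  v2 <- oracle_expected_margin(booster, x, features[2])
  v12 <- oracle_expected_margin(booster, x, features)
  phi1 <- 0.5 * ((v1 - v0) + (v12 - v2))
  phi2 <- 0.5 * ((v2 - v0) + (v12 - v1))
  c(base = v0, phi1 = phi1, phi2 = phi2)
}
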