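# Exact path-dependent TreeSHAP in double precision.
#
# Attributions are computed tree by tree with the polynomial-weight
# path algorithm; unknown features are marginalized by training cover,
# and everything is accumulated in doubles, so base + sum(attributions)
# reproduces the margin to full double precision (the tree leaves
# themselves are the model's stored single-precision values).

float32 <- function(x) {
  readBin(writeBin(x, raw(), size = 4L), "numeric", size = 4L, n = length(x))
}

parse_booster_trees <- function(booster, feature_names) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  lapply(split(dt, dt$Tree), function(nodes) {
    nodes <- nodes[order(nodes$Node), , drop = FALSE]
    id2node <- setNames(seq_len(nrow(nodes)), nodes$ID)
    leaf <- nodes$Feature == "Leaf"
    list(
      feature = ifelse(leaf, NA_integer_,
                       match(nodes$Feature, feature_names)),
      # split conditions are stored single-precision; the dump prints
      # extra digits that must not influence routing
      split = float32(nodes$Split),
      yes = ifelse(leaf, NA_integer_, unname(id2node[nodes$Yes])),
      no = ifelse(leaf, NA_integer_, unname(id2node[nodes$No])),
      cover = nodes$Cover,
      value = ifelse(leaf, nodes$Gain, NA_real_)  # Gain column holds leaf values
    )
  })
}

# Cover-weighted expected leaf value (the tree's contribution to the
# model's expected margin).
tree_expected_value <- function(tree, j = 1L) {
  if (is.na(tree$feature[j])) return(tree$value[j])
  y <- tree$yes[j]
  n <- tree$no[j]
  (tree$cover[y] * tree_expected_value(tree, y) +
      tree$cover[n] * tree_expected_value(tree, n)) / (tree$cover[y] + tree$cover[n])
}

# Margin contribution of one tree for one fully observed row.
tree_leaf_value <- function(tree, x) {
  j <- 1L
  while (!is.na(tree$feature[j])) {
    j <- if (x[tree$feature[j]] < tree$split[j]) tree$yes[j] else tree$no[j]
  }
  tree$value[j]
}

# One tree, one row: returns the per-feature attribution vector.
# Ports the canonical extend/unwind path recursion (0-based indices
# kept 1-based here; path element 1 is the sentinel).
tree_shap_row <- function(tree, x, n_features) {
  phis <- numeric(n_features)

  extend_path <- function(m, ud, pz, po, pi) {
    # ud = unique depth before extension; element ud+1 is written
    m$d[ud + 1L] <- pi
    m$z[ud + 1L] <- pz
    m$o[ud + 1L] <- po
    m$w[ud + 1L] <- if (ud == 0L) 1 else 0
    i <- ud
    while (i >= 1L) {
      m$w[i + 1L] <- m$w[i + 1L] + po * m$w[i] * i / (ud + 1)
      m$w[i] <- pz * m$w[i] * (ud + 1 - i) / (ud + 1)
      i <- i - 1L
    }
    m
  }

  unwind_path <- function(m, ud, k) {
    one <- m$o[k]
    zero <- m$z[k]
    nxt <- m$w[ud + 1L]
    i <- ud
    while (i >= 1L) {
      if (one != 0) {
        tmp <- m$w[i]
        m$w[i] <- nxt * (ud + 1) / (i * one)
        nxt <- tmp - m$w[i] * zero * (ud + 1 - i) / (ud + 1)
      } else {
        m$w[i] <- m$w[i] * (ud + 1) / (zero * (ud + 1 - i))
      }
      i <- i - 1L
    }
    if (k <= ud) {
      for (i in k:ud) {
        m$d[i] <- m$d[i + 1L]
        m$z[i] <- m$z[i + 1L]
        m$o[i] <- m$o[i + 1L]
      }
    }
    m
  }

  unwound_sum <- function(m, ud, k) {
    one <- m$o[k]
    zero <- m$z[k]
    nxt <- m$w[ud + 1L]
    total <- 0
    i <- ud
    while (i >= 1L) {
      if (one != 0) {
        tmp <- nxt * (ud + 1) / (i * one)
        total <- total + tmp
        nxt <- m$w[i] - tmp * zero * (ud + 1 - i) / (ud + 1)
      } else {
        total <- total + m$w[i] * (ud + 1) / (zero * (ud + 1 - i))
      }
      i <- i - 1L
    }
    total
  }

  recurse <- function(j, m, ud, pz, po, pi) {
    m <- extend_path(m, ud, pz, po, pi)
    ud <- ud + 1L
    if (is.na(tree$feature[j])) {
      if (ud >= 2L) {
        for (i in 2:ud) {
          w <- unwound_sum(m, ud - 1L, i)
          phis[m$d[i]] <<- phis[m$d[i]] +
            w * (m$o[i] - m$z[i]) * tree$value[j]
        }
      }
      return(invisible(NULL))
    }
    f <- tree$feature[j]
    hot <- if (x[f] < tree$split[j]) tree$yes[j] else tree$no[j]
    cold <- if (hot == tree$yes[j]) tree$no[j] else tree$yes[j]
    iz <- 1
    io <- 1
    k <- if (ud >= 2L) {
      hits <- which(m$d[2:ud] == f)
      if (length(hits) > 0) hits[1] + 1L else 0L
    } else 0L
    if (k > 0L) {
      iz <- m$z[k]
      io <- m$o[k]
      m <- unwind_path(m, ud - 1L, k)
      ud <- ud - 1L
    }
    recurse(hot, m, ud, iz * tree$cover[hot] / tree$cover[j], io, f)
    recurse(cold, m, ud, iz * tree$cover[cold] / tree$cover[j], 0, f)
    invisible(NULL)
  }

  depth_bound <- sum(!is.na(tree$feature)) + 2L
  m0 <- list(d = integer(depth_bound), z = numeric(depth_bound),
             o = numeric(depth_bound), w = numeric(depth_bound))
  recurse(1L, m0, 0L, 1, 1, 0L)
  phis
}

# Full double-precision contributions for a booster: n x (p + 1) matrix
# (last column BIAS) plus the double-precision margins.
tree_shap_contrib <- function(booster, X, feature_names) {
  trees <- parse_booster_trees(booster, feature_names)
  # route with the storage precision the library uses: features are
  # held in single precision, so comparisons against splits must see
  # the float32-rounded values
  X_routed <- matrix(float32(as.numeric(X)), nrow(X), ncol(X),
                     dimnames = dimnames(X))
  n <- nrow(X)
  p <- length(feature_names)
  contrib <- matrix(0, n, p)
  margin_trees <- numeric(n)
  expected <- 0
  for (tree in trees) {
    expected <- expected + tree_expected_value(tree)
    if (all(is.na(tree$feature))) {  # single-leaf tree: pure bias
      margin_trees <- margin_trees + tree$value[1]
      next
    }
    for (i in seq_len(n)) {
      xi <- X_routed[i, ]
      contrib[i, ] <- contrib[i, ] + tree_shap_row(tree, xi, p)
      margin_trees[i] <- margin_trees[i] + tree_leaf_value(tree, xi)
    }
  }
  # global bias on the margin scale, recovered once from the booster
  # (single-precision in the probe; a constant offset shared by margin
  # and BIAS, so additivity is unaffected)
  probe <- predict(booster, xgboost::xgb.DMatrix(X[1, , drop = FALSE]),
                   outputmargin = TRUE)
  base_margin <- probe - margin_trees[1]
  dimnames(contrib) <- list(rownames(X), feature_names)
  list(
    contrib = cbind(contrib, BIAS = base_margin + expected),
    margin = base_margin + margin_trees,
    base_value = base_margin + expected
  )
}
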