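# Independent oracles used by the unit and acceptance tests.  These are
# deliberately separate implementations: plain R, no calls into the
# package's split-search or growth code.

# ---- reference deterministic CART (greedy weighted-Gini) -------------------
# Grows a tree on hard labels y (integers 1..K) with per-class weights w,
# one feature subset consumed per split attempt from `subsets`.  Nodes are
# stored in preorder (parent, left subtree, right subtree).
ref_cart_grow <- function(X, y, K, w, idx, subsets,
                          min_split = 2, min_leaf = 1, max_depth = Inf) {
  env <- new.env()
  env$nodes <- list()
  env$consumed <- 0L

  node_dist <- function(ii) {
    cnt <- vapply(seq_len(K), function(c) sum(y[ii] == c), 0)
    q <- w * cnt
    q / sum(q)
  }
  gini <- function(p) 1 - sum(p^2)

  best_split <- function(ii, sub) {
    best <- NULL
    n <- length(ii)
    for (f in sort(sub)) {
      xs <- X[ii, f]
      o <- order(xs)
      xs <- xs[o]
      ys <- y[ii][o]
      cum <- sapply(seq_len(K), function(c) cumsum(ys == c))
      tot <- cum[n, ]
      for (i in seq_len(n - 1)) {
        if (xs[i] == xs[i + 1]) next
        t <- (xs[i] + xs[i + 1]) / 2
        nL <- i; nR <- n - i
        if (nL < min_leaf || nR < min_leaf) next
        qL <- w * cum[i, ]; qR <- w * (tot - cum[i, ])
        gL <- gini(qL / sum(qL)); gR <- gini(qR / sum(qR))
        cost <- (nL * gL + nR * gR) / n
        if (is.null(best) || cost < best$cost)
          best <- list(f = f, t = t, cost = cost)
      }
    }
    best
  }

  grow <- function(ii, depth) {
    id <- length(env$nodes) + 1L
    env$nodes[[id]] <- list(feature = NA_integer_, threshold = NA_real_,
                            left = NA_integer_, right = NA_integer_,
                            dist = node_dist(ii), n = length(ii))
    g <- gini(env$nodes[[id]]$dist)
    if (length(ii) >= min_split && depth < max_depth && g > 1e-12) {
      env$consumed <- env$consumed + 1L
      if (env$consumed > length(subsets)) stop("ref subset stream exhausted")
      b <- best_split(ii, subsets[[env$consumed]])
      if (!is.null(b) && b$cost < g - 1e-12) {
        L <- ii[X[ii, b$f] <= b$t]
        R <- ii[X[ii, b$f] > b$t]
        env$nodes[[id]]$feature <- b$f
        env$nodes[[id]]$threshold <- b$t
        env$nodes[[id]]$left <- grow(L, depth + 1)
        env$nodes[[id]]$right <- grow(R, depth + 1)
      }
    }
    id
  }
  grow(idx, 0)
  env$nodes
}

ref_cart_predict <- function(nodes, x) {
  i <- 1L
  while (!is.na(nodes[[i]]$feature)) {
    f <- nodes[[i]]$feature
    i <- if (x[f] > nodes[[i]]$threshold) nodes[[i]]$right else
      nodes[[i]]$left
  }
  nodes[[i]]$dist
}

# ---- exhaustive best-split enumeration over candidate thresholds -----------
# Uses the package's scalar split_cost primitive candidate by candidate; the
# search logic (candidate set, validity, tie-breaks) is re-derived here.
enumerate_best_split <- function(X, DX, pmf, arrival, subset, w,
                                 min_leaf, keep_prob) {
  best <- NULL
  for (f in sort(subset)) {
    vals <- sort(unique(X[arrival >= keep_prob, f]))
    if (length(vals) < 2) next
    for (j in seq_len(length(vals) - 1)) {
      t <- (vals[j] + vals[j + 1]) / 2
      pR <- prforest::gaussian_right_probability(X[, f], DX[, f], t)
      mR <- sum(arrival * pR)
      mL <- sum(arrival) - mR
      if (mL < min_leaf || mR < min_leaf || mL <= 0 || mR <= 0) next
      cost <- prforest::split_cost(X, DX, pmf, arrival, f, t, w)
      if (is.null(best) || cost < best$cost)
        best <- list(feature = f, threshold = t, cost = cost)
    }
  }
  best
}

# ---- Mann-Whitney concordance AUC ------------------------------------------
concordance_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# ---- misc fixtures ----------------------------------------------------------
# a small separable two-class dataset with exact labels
toy_dataset <- function(n_per_class = 6, d = 2, gap = 3, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_class * d), ncol = d)
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] - gap
  label <- rep(c("A", "B"), each = n_per_class)
  uncertain_dataset(X, label, rep("confirmed", 2 * n_per_class),
                    class_names = c("A", "B"))
}

# random feature subsets, enough for any tree on n samples
make_subset_streams <- function(n_trees, n, d, mtry, seed) {
  set.seed(seed)
  lapply(seq_len(n_trees), function(b)
    lapply(seq_len(2 * n + 10), function(i) sort(sample.int(d, mtry))))
}

strip_policy <- function(report) report[setdiff(names(report), "policy")]
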