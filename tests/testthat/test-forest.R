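test_that("grow_tree handles trivial separable and pure nodes", {
  # 2 samples, opposite labels, separable: depth-1 tree with pure leaves
  ds <- uncertain_dataset(matrix(c(0, 10), ncol = 1), c("A", "B"),
                          rep("confirmed", 2), class_names = c("A", "B"))
  tr <- prf_grow_tree(ds, c(1, 2), prf_control(max_features = "all",
                                               keep_probability = 0))
  expect_length(tr$feature, 3)
  expect_equal(tr$feature[1], 1L)
  expect_equal(unname(tr$dist[2, ]), c(1, 0))
  expect_equal(unname(tr$dist[3, ]), c(0, 1))

  # all samples share one label: terminal root, one-hot distribution
  ds1 <- uncertain_dataset(matrix(rnorm(5), ncol = 1), rep("A", 5),
                           rep("confirmed", 5), class_names = c("A", "B"))
  tr1 <- prf_grow_tree(ds1, 1:5, prf_control(),
                       class_weights = c(1, 1))
  expect_length(tr1$feature, 1)
  expect_true(is.na(tr1$feature[1]))
  expect_equal(unname(tr1$dist[1, ]), c(1, 0))
  expect_error(prf_grow_tree(ds1, integer(0), prf_control()), "empty")
})

test_that("fits are deterministic given the seed", {
  ds <- toy_dataset(n_per_class = 10, d = 3, gap = 1)
  m1 <- prf_fit(ds, prf_control(n_trees = 5, seed = 77))
  m2 <- prf_fit(ds, prf_control(n_trees = 5, seed = 77))
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$bootstrap_ids, m2$bootstrap_ids)
  Xnew <- matrix(rnorm(30), ncol = 3)
  expect_identical(predict(m1, Xnew), predict(m2, Xnew))
  m3 <- prf_fit(ds, prf_control(n_trees = 5, seed = 78))
  expect_false(identical(m1$trees, m3$trees))
})

test_that("leaf distributions match deterministically recomputed memberships", {
  # dx = 0, one-hot labels: route each bootstrap sample down its single
  # path and recompute the weighted leaf frequencies independently
  ds <- toy_dataset(n_per_class = 12, d = 3, gap = 1, seed = 5)
  m <- prf_fit(ds, prf_control(n_trees = 3, keep_probability = 0,
                               seed = 42))
  y <- match(ds$label, ds$class_names)
  for (b in seq_along(m$trees)) {
    tr <- m$trees[[b]]
    boot <- match(m$bootstrap_ids[[b]], ds$sample_id)
    members <- vector("list", length(tr$feature))
    for (i in boot) {
      nd <- 1L
      repeat {
        members[[nd]] <- c(members[[nd]], i)
        if (is.na(tr$feature[nd])) break
        nd <- if (ds$X[i, tr$feature[nd]] > tr$threshold[nd])
          tr$right[nd] else tr$left[nd]
      }
    }
    for (nd in which(is.na(tr$feature))) {
      cnt <- tabulate(y[members[[nd]]], nbins = 2)
      q <- m$class_weights * cnt
      expect_equal(unname(tr$dist[nd, ]), unname(q / sum(q)),
                   tolerance = 1e-12)
      expect_equal(tr$mass[nd], length(members[[nd]]))
    }
  }
})

test_that("tree prediction follows arrival-mass-weighted leaf averaging", {
  ds <- uncertain_dataset(matrix(c(0, 10), ncol = 1), c("A", "B"),
                          rep("confirmed", 2), class_names = c("A", "B"))
  tr <- prf_grow_tree(ds, c(1, 2), prf_control(max_features = "all",
                                               keep_probability = 0))
  # dx = 0: deterministic routing to a single leaf
  expect_equal(unname(predict_proba_tree(tr, matrix(0, 1, 1))[1, ]),
               c(1, 0))
  # depth-1 closed form with feature uncertainty
  x <- 4; dx <- 2; t <- tr$threshold[1]
  pi_r <- gaussian_right_probability(x, dx, t)
  expect_equal(unname(predict_proba_tree(tr, matrix(x, 1, 1),
                                         matrix(dx, 1, 1))[1, ]),
               pi_r * tr$dist[3, ] + (1 - pi_r) * tr$dist[2, ],
               tolerance = 1e-12)
  # single-node tree returns the root distribution for any input
  ds1 <- uncertain_dataset(matrix(rnorm(4), ncol = 1), rep("A", 4),
                           rep("confirmed", 4), class_names = c("A", "B"))
  tr1 <- prf_grow_tree(ds1, 1:4, prf_control(), class_weights = c(1, 1))
  expect_equal(unname(predict_proba_tree(tr1, matrix(99, 1, 1))[1, ]),
               unname(tr1$dist[1, ]))
})

test_that("forest predictions are averaged and rows sum to one", {
  ds <- toy_dataset(n_per_class = 10, d = 3, gap = 0.5, seed = 8)
  m <- prf_fit(ds, prf_control(n_trees = 7, seed = 4))
  X <- matrix(rnorm(60), ncol = 3)
  p <- predict(m, X)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  acc <- Reduce(`+`, lapply(m$trees, function(tr)
    predict_proba_tree(tr, X))) / length(m$trees)
  expect_equal(unname(p), unname(acc))
  # test-time feature uncertainty shifts probabilities continuously
  pdx <- predict(m, X, DX = matrix(0.5, nrow(X), 3))
  expect_true(all(abs(rowSums(pdx) - 1) < 1e-9))
  expect_error(predict(m, X[, 1:2]), "expects")
})

test_that("feature importances are normalized and identify signal", {
  ds <- uncertain_dataset(matrix(c(0, 10), ncol = 1), c("A", "B"),
                          rep("confirmed", 2), class_names = c("A", "B"))
  tr <- prf_grow_tree(ds, c(1, 2), prf_control(max_features = "all",
                                               keep_probability = 0))
  m1 <- structure(list(trees = list(tr), feature_names = "f1",
                       class_names = c("A", "B")), class = "prf_forest")
  expect_equal(unname(feature_importances(m1)), 1)

  # one separating feature vs pure noise, over 10 seeds
  wins <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 40
    X <- cbind(sep = c(rnorm(n / 2, -3), rnorm(n / 2, 3)),
               noise = rnorm(n))
    dss <- uncertain_dataset(X, rep(c("A", "B"), each = n / 2),
                             rep("confirmed", n),
                             class_names = c("A", "B"))
    m <- prf_fit(dss, prf_control(n_trees = 10, max_features = 1,
                                  seed = s))
    imp <- feature_importances(m)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    imp["sep"] > imp["noise"]
  }, TRUE)
  expect_true(all(wins))
})

test_that("JSON serialization round-trips the model exactly", {
  ds <- toy_dataset(n_per_class = 8, d = 2, gap = 1, seed = 3)
  m <- prf_fit(ds, prf_control(n_trees = 4, seed = 10))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  model_to_json(m, path)
  m2 <- model_from_json(path)
  X <- matrix(rnorm(20), ncol = 2)
  expect_identical(predict(m, X), predict(m2, X))
  expect_equal(m2$class_weights, unname(m$class_weights))
  expect_equal(m2$control$seed, m$control$seed)
})

test_that("leaf distributions vary continuously as pmfs approach one-hot", {
  # hold the arrival pattern fixed; an epsilon-soft pmf must give a node
  # distribution within O(epsilon) of the one-hot limit
  arrival <- c(0.8, 0.6, 0.4)
  base <- rbind(c(1, 0), c(0, 1), c(1, 0))
  lim <- node_class_distribution(arrival, base, c(1.2, 0.9))
  for (eps in 10^seq(-2, -9)) {
    soft <- base * (1 - eps) + eps / 2
    d <- node_class_distribution(arrival, soft, c(1.2, 0.9))
    expect_lt(max(abs(d - lim)), 2 * eps)
  }
})
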