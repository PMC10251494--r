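test_that("gaussian_right_probability matches symmetry, step and tail oracle", {
  expect_equal(gaussian_right_probability(1.3, 1.0, 1.3), 0.5)
  expect_equal(gaussian_right_probability(2.0, 0.0, 1.0), 1.0)
  expect_equal(gaussian_right_probability(0.5, 0.0, 1.0), 0.0)
  # numerical-integration oracle for P(N(0,1) > 1)
  tail_mass <- integrate(dnorm, 1, Inf)$value
  expect_equal(gaussian_right_probability(0.0, 1.0, 1.0), tail_mass,
               tolerance = 1e-8)
  # continuous and non-increasing in t
  ts <- seq(-4, 4, length.out = 200)
  ps <- gaussian_right_probability(0.7, 0.9, ts)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps >= 0 & ps <= 1))
  expect_error(gaussian_right_probability(0, -0.1, 0), "non-negative")
})

test_that("node_class_distribution averages pmfs by arrival mass and weight", {
  expect_equal(node_class_distribution(c(1, 1), rbind(c(1, 0), c(0.5, 0.5))),
               c(0.75, 0.25))
  expect_equal(node_class_distribution(1, rbind(c(0, 1))), c(0, 1))
  expect_equal(node_class_distribution(c(0.5, 0.5),
                                       rbind(c(1, 0), c(1, 0))), c(1, 0))
  # class weights rescale the fractions
  expect_equal(node_class_distribution(c(1, 1), rbind(c(1, 0), c(0, 1)),
                                       class_weights = c(3, 1)),
               c(0.75, 0.25))
  expect_error(node_class_distribution(c(0, 0), rbind(c(1, 0), c(0, 1))),
               "degenerate")
})

test_that("modified_gini is the Gini impurity of the distribution", {
  expect_equal(modified_gini(c(1, 0)), 0)
  expect_equal(modified_gini(c(0.5, 0.5)), 0.5)
  expect_equal(modified_gini(c(0.74, 0.26)), 0.3848)
  expect_error(modified_gini(c(0.7, 0.7)), "sum to 1")
})

test_that("split_cost handles separating, degenerate and Gaussian cases", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  DX <- matrix(0, 4, 1)
  pmf <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  a <- rep(1, 4)
  expect_equal(split_cost(X, DX, pmf, a, 1, 2.5), 0)
  # all mass to one side: parent impurity sentinel
  expect_equal(split_cost(X, DX, pmf, a, 1, 0.5), 0.5)

  # brute-force scalar oracle with feature uncertainty
  X3 <- matrix(c(0, 1, 2), ncol = 1)
  DX3 <- matrix(1, 3, 1)
  pmf3 <- rbind(c(1, 0), c(1, 0), c(0, 1))
  t <- 1.0
  pR <- pnorm(t, mean = c(0, 1, 2), sd = 1, lower.tail = FALSE)
  mR <- pR; mL <- 1 - pR
  gini2 <- function(q) 1 - sum((q / sum(q))^2)
  qL <- c(mL[1] + mL[2], mL[3]); qR <- c(mR[1] + mR[2], mR[3])
  oracle <- (sum(mL) * gini2(qL) + sum(mR) * gini2(qR)) / 3
  expect_equal(split_cost(X3, DX3, pmf3, rep(1, 3), 1, t), oracle,
               tolerance = 1e-12)
})

test_that("find_best_split finds separating gaps and declines flat nodes", {
  X <- matrix(c(1, 2, 3, 4), ncol = 1)
  DX <- matrix(0, 4, 1)
  pmf <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  s <- find_best_split(X, DX, pmf, rep(1, 4), 1)
  expect_equal(s$feature_index, 1L)
  expect_gt(s$threshold, 2)
  expect_lt(s$threshold, 3)
  expect_equal(s$cost, 0)
  # all-identical feature values: no candidates
  Xc <- matrix(5, 4, 1)
  expect_null(find_best_split(Xc, DX, pmf, rep(1, 4), 1))
  expect_error(find_best_split(X, DX, pmf, rep(1, 4), integer(0)),
               "non-empty")
})

test_that("find_best_split equals exhaustive enumeration on random nodes", {
  set.seed(31)
  for (r in 1:40) {
    n <- sample(4:12, 1); d <- sample(1:3, 1)
    X <- matrix(round(rnorm(n * d), 2), n, d)
    DX <- matrix(ifelse(runif(n * d) < 0.5, 0, runif(n * d, 0.1, 1)), n, d)
    a <- runif(n)
    p1 <- runif(n); pmf <- cbind(p1, 1 - p1)
    w <- runif(2, 0.5, 2)
    sub <- sort(sample.int(d, sample.int(d, 1)))
    fb <- find_best_split(X, DX, pmf, a, sub, w, min_samples_leaf = 0.1,
                          keep_probability = 0.05)
    or <- enumerate_best_split(X, DX, pmf, a, sub, w, 0.1, 0.05)
    parent <- modified_gini(node_class_distribution(a, pmf, w))
    if (is.null(fb)) {
      expect_true(is.null(or) || or$cost >= parent - 1e-12)
    } else {
      expect_equal(fb$cost, or$cost, tolerance = 1e-12)
      expect_identical(fb$feature_index, or$feature)
      expect_identical(fb$threshold, or$threshold)
    }
  }
})

test_that("compute_class_weights implements balanced effective counts", {
  pmf <- rbind(matrix(rep(c(0, 1), 81), ncol = 2, byrow = TRUE),
               matrix(rep(c(1, 0), 29), ncol = 2, byrow = TRUE),
               matrix(0.5, 32, 2))
  w <- compute_class_weights(pmf)
  expect_equal(unname(w), c(142 / (2 * 45), 142 / (2 * 97)))
  expect_equal(unname(w), c(1.5778, 0.7320), tolerance = 1e-4)
  # balanced one-hot labels and symmetric soft labels give unit weights
  expect_equal(unname(compute_class_weights(rbind(c(1, 0), c(0, 1)))),
               c(1, 1))
  expect_equal(unname(compute_class_weights(matrix(0.5, 4, 2))), c(1, 1))
  expect_error(compute_class_weights(rbind(c(1, 0), c(1, 0))),
               "zero effective count")
})
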