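test_that("stratified_kfold partitions with balanced class counts", {
  labels <- c(rep("pos", 81), rep("stable", 61))
  f <- stratified_kfold(labels, 7, seed = 1)
  expect_setequal(unique(f), 1:7)
  sizes <- table(f)
  expect_true(all(sizes %in% c(20, 21)))
  for (cl in unique(labels)) {
    per <- table(f[labels == cl])
    expect_lte(max(per) - min(per), 1)
  }
  expect_identical(f, stratified_kfold(labels, 7, seed = 1))
  expect_false(identical(f, stratified_kfold(labels, 7, seed = 2)))

  # n = 14 balanced binary, k = 7: exactly one of each class per fold
  lab2 <- rep(c("a", "b"), 7)
  f2 <- stratified_kfold(lab2, 7, seed = 3)
  expect_true(all(table(f2, lab2) == 1))
  expect_error(stratified_kfold(c("a", "a", "b"), 2, 1), "smaller than k")
})

test_that("fold_plan builds a nested partition reconstructible from seed", {
  labels <- c(rep("pos", 81), rep("stable", 61))
  plan <- fold_plan(labels, k = 7, seed = 11)
  test_sets <- lapply(plan$outer, `[[`, "test")
  expect_setequal(unlist(test_sets), seq_along(labels))
  expect_equal(sum(lengths(test_sets)), length(labels))
  expect_true(all(lengths(lapply(plan$outer, `[[`, "train")) %in%
                    c(121, 122)))
  for (i in 1:7) {
    out <- plan$outer[[i]]
    expect_length(intersect(out$train, out$test), 0)
    vals <- lapply(plan$inner[[i]], `[[`, "validation")
    expect_setequal(unlist(vals), out$train)
    for (fold in plan$inner[[i]]) {
      expect_length(intersect(fold$train, fold$validation), 0)
      expect_setequal(c(fold$train, fold$validation), out$train)
    }
  }
  expect_identical(plan, fold_plan(labels, k = 7, seed = 11))
})

test_that("precision_recall_f1 matches hand arithmetic and flags edge cases", {
  m <- precision_recall_f1(9, 3, 1)
  expect_equal(m$precision, 75)
  expect_equal(m$recall, 90)
  expect_equal(m$f1, 2 * 75 * 90 / 165, tolerance = 1e-12)
  expect_equal(round(m$f1, 2), 81.82)

  perfect <- precision_recall_f1(5, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1),
               c(100, 100, 100))

  zero <- precision_recall_f1(0, 2, 3)
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))
  expect_false(zero$f1_defined)

  undef <- precision_recall_f1(0, 0, 3)
  expect_true(is.na(undef$precision))
  expect_false(undef$precision_defined)
})

test_that("roc_auc sweeps thresholds and equals concordance", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  r2 <- roc_auc(c(0.8, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 0.75)
  r3 <- roc_auc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r3$auc, 0.5)
  expect_true(is.na(roc_auc(c(0.1, 0.9), c(TRUE, TRUE))$auc))

  # trapezoidal AUC equals Mann-Whitney concordance on random inputs
  set.seed(12)
  for (r in 1:25) {
    n <- sample(5:40, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc,
                 concordance_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("evaluate_fold scores confirmed samples only, counts verifiable", {
  co <- generate_cohort(synthetic_config(seed = 21))
  ds <- co$dataset
  tr_ids <- 1:100
  te_ids <- 101:142
  m <- prf_fit(apply_policy(dataset_subset(ds, tr_ids),
                            label_policy("naive")),
               prf_control(n_trees = 20, seed = 2))
  te <- dataset_subset(ds, te_ids)
  ev <- evaluate_fold(m, te)
  expect_equal(ev$n_confirmed, sum(te$status == "confirmed"))
  # independent recount
  conf <- dataset_subset(te, which(te$status == "confirmed"))
  sc <- predict(m, conf$X)[, 2]
  truth <- conf$label == ds$class_names[2]
  pred <- sc > 0.5
  expect_equal(ev$TP, sum(pred & truth))
  expect_equal(ev$FP, sum(pred & !truth))
  expect_equal(ev$FN, sum(!pred & truth))
  expect_equal(ev$TN, sum(!pred & !truth))
  expect_equal(ev$TP + ev$FP + ev$FN + ev$TN, nrow(conf$X))

  # a fold with no confirmed samples is skipped with a warning
  post_only <- dataset_subset(ds, which(ds$status == "posthoc"))
  expect_warning(res <- evaluate_fold(m, post_only), "skipped")
  expect_null(res)
})

test_that("select_hyperparameters picks the better candidate deterministically", {
  co <- generate_cohort(synthetic_config(seed = 4))
  ds <- co$dataset
  plan <- fold_plan(ds$label, k = 7, seed = 4)
  policy <- label_policy("naive")

  single <- hyper_grid(n_trees = 25, max_features = "sqrt",
                       min_samples_split = 2, min_samples_leaf = 1)
  best <- select_hyperparameters(ds, plan$inner[[1]], single, policy,
                                 seed = 4)
  expect_equal(best$n_trees, 25)

  # the winner of a two-candidate grid is the candidate with the higher
  # mean validation F1, recomputed via single-candidate runs
  grid <- hyper_grid(n_trees = c(1, 25), max_features = "sqrt",
                     min_samples_split = 2, min_samples_leaf = 1)
  best2 <- select_hyperparameters(ds, plan$inner[[1]], grid, policy,
                                  seed = 4)
  # fits are seeded by candidate identity, so single-candidate runs
  # reproduce the scores seen inside the two-candidate search exactly
  solo <- vapply(1:2, function(g)
    select_hyperparameters(ds, plan$inner[[1]], grid[g, ], policy,
                           seed = 4)$mean_metric, 0)
  expect_equal(best2$mean_metric, max(solo))
  expect_equal(best2$n_trees, grid$n_trees[which.max(solo)])

  # selection invariant to grid ordering (no exact ties here)
  rev_grid <- grid[2:1, ]
  best3 <- select_hyperparameters(ds, plan$inner[[1]], rev_grid, policy,
                                  seed = 4)
  expect_equal(best3$n_trees, best2$n_trees)
})

test_that("average_roc interpolates fold curves onto a common grid", {
  curves <- list(
    data.frame(threshold = c(Inf, 1, 0, -Inf), fpr = c(0, 0, 1, 1),
               tpr = c(0, 1, 1, 1)),
    data.frame(threshold = c(Inf, 1, 0, -Inf), fpr = c(0, 0.5, 1, 1),
               tpr = c(0, 0.5, 1, 1)))
  rep <- list(roc = curves)
  avg <- average_roc(rep)
  expect_equal(nrow(avg), 101)
  expect_equal(avg$tpr[avg$fpr == 1], 1)
  expect_true(all(diff(avg$tpr) >= -1e-12))
})
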