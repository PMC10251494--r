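#' Stratified k-fold assignment
#'
#' Within each class the sample indices are shuffled with a seeded RNG and
#' dealt round-robin to the k folds, so per-class fold sizes differ by at
#' most one from perfectly proportional allocation.
#'
#' @param labels vector of (nominal) class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold numbers in `1:k`, one per sample.
#' @export
stratified_kfold <- function(labels, k, seed) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stopf("class(es) smaller than k = %d: %s", k,
          paste(names(tab)[tab < k], collapse = ", "))
  fold <- integer(length(labels))
  offset <- 0L
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      ids <- which(labels == cl)
      ids <- ids[sample.int(length(ids))]
      # rotate the dealing start across classes so total fold sizes also
      # differ by at most one
      fold[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
      offset <- (offset + length(ids)) %% k
    }
  })
  fold
}

#' Nested stratified cross-validation plan
#'
#' Builds the outer k-fold partition and, for every outer fold, an inner
#' k-fold partition of that fold's training set (both stratified on the
#' nominal labels). The whole plan is reconstructible from `seed` alone
#' and is shared across label policies so that policy comparisons are
#' paired.
#'
#' @param labels nominal class labels of the full dataset.
#' @param k folds (study default 7), used for both loops.
#' @param seed integer seed.
#' @return A list of class `fold_plan` with `outer` (list of
#'   `list(train, test)` index vectors) and `inner` (per outer fold, a list
#'   of `list(train, validation)` indices into the full dataset).
#' @export
fold_plan <- function(labels, k = 7, seed = 1L) {
  outer_fold <- stratified_kfold(labels, k, seed)
  outer <- lapply(seq_len(k), function(i)
    list(train = which(outer_fold != i), test = which(outer_fold == i)))
  inner <- lapply(seq_len(k), function(i) {
    tr <- outer[[i]]$train
    f <- stratified_kfold(labels[tr], k, derive_seed(seed, i))
    lapply(seq_len(k), function(j)
      list(train = tr[f != j], validation = tr[f == j]))
  })
  structure(list(outer = outer, inner = inner, k = as.integer(k),
                 seed = as.integer(seed), n = length(labels)),
            class = "fold_plan")
}

#' Precision, recall and F1 from confusion counts
#'
#' Returned as percentages. Undefined denominators give `NA` with the
#' corresponding `*_defined` flag set to `FALSE`; the conventional
#' boundary case TP = 0 with FP > 0 and FN > 0 yields precision 0,
#' recall 0 and F1 reported as 0 but flagged undefined.
#'
#' @param TP,FP,FN confusion counts (true positive, false positive, false
#'   negative).
#' @return List with `precision`, `recall`, `f1` (percent) and logical
#'   flags `precision_defined`, `recall_defined`, `f1_defined`.
#' @export
precision_recall_f1 <- function(TP, FP, FN) {
  precision_defined <- (TP + FP) > 0
  recall_defined <- (TP + FN) > 0
  precision <- if (precision_defined) 100 * TP / (TP + FP) else NA_real_
  recall <- if (recall_defined) 100 * TP / (TP + FN) else NA_real_
  if (!precision_defined || !recall_defined) {
    f1 <- NA_real_; f1_defined <- FALSE
  } else if (precision + recall == 0) {
    f1 <- 0; f1_defined <- FALSE
  } else {
    f1 <- 2 * precision * recall / (precision + recall); f1_defined <- TRUE
  }
  list(precision = precision, recall = recall, f1 = f1,
       precision_defined = precision_defined,
       recall_defined = recall_defined, f1_defined = f1_defined)
}

#' ROC curve and AUC
#'
#' Sweeps the distinct scores as thresholds (predict positive when score >
#' threshold) and integrates the curve by the trapezoidal rule, which
#' equals the Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param scores numeric vector of positive-class scores.
#' @param labels logical (or 0/1) vector, `TRUE` for the positive class.
#' @return List with `curve` (data.frame `threshold`, `fpr`, `tpr`) and
#'   `auc`; both are `NA` when only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels)
  N <- sum(!labels)
  if (P == 0 || N == 0)
    return(list(curve = NULL, auc = NA_real_))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[labels] > t) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores[!labels] > t) / N, 0)
  # close the curve at (1, 1)
  thr <- c(thr, -Inf); tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a fitted model on one test fold
#'
#' Metrics are computed on test samples with confirmed labels only; the
#' positive class is the second entry of the model's `class_names`. Hard
#' predictions call a sample positive when its predicted positive-class
#' probability exceeds `threshold`.
#'
#' @param model a fitted `prf_forest`.
#' @param test_dataset an [uncertain_dataset()] of test samples (post-hoc
#'   samples are dropped internally).
#' @param threshold classification threshold on the positive-class
#'   probability (default 0.5).
#' @return List with confusion counts `TP`, `FP`, `FN`, `TN`, the metric
#'   list of [precision_recall_f1()], `auc`, the ROC `curve`, the score
#'   vector and `n_confirmed`; or `NULL` (with a warning) when the fold
#'   has no confirmed samples.
#' @export
evaluate_fold <- function(model, test_dataset, threshold = 0.5) {
  conf <- test_dataset$status == "confirmed"
  if (!any(conf)) {
    warning("fold has no confirmed test samples; skipped")
    return(NULL)
  }
  ds <- dataset_subset(test_dataset, which(conf))
  pos_class <- model$class_names[2]
  probs <- predict(model, ds$X)
  scores <- probs[, pos_class]
  truth <- ds$label == pos_class
  pred <- scores > threshold
  TP <- sum(pred & truth); FP <- sum(pred & !truth)
  FN <- sum(!pred & truth); TN <- sum(!pred & !truth)
  roc <- roc_auc(scores, truth)
  c(list(TP = TP, FP = FP, FN = FN, TN = TN),
    precision_recall_f1(TP, FP, FN),
    list(auc = roc$auc, curve = roc$curve, scores = scores,
         truth = truth, n_confirmed = sum(conf)))
}

#' Hyperparameter grid
#'
#' Cartesian product of the candidate values. `min_samples_split` and
#' `min_samples_leaf` apply to deterministic (zero-uncertainty) baselines;
#' for the probabilistic policy they are fixed at their defaults (2, 1)
#' because propagation mass and `keep_probability` govern node occupancy
#' there.
#'
#' @param n_trees,max_features,min_samples_split,min_samples_leaf candidate
#'   vectors.
#' @return A data.frame of class `hyper_grid`, one row per combination.
#' @export
hyper_grid <- function(n_trees = c(50, 100, 250),
                       max_features = c("sqrt", "log2", "all"),
                       min_samples_split = c(2, 5, 10),
                       min_samples_leaf = c(1, 3, 5)) {
  g <- expand.grid(n_trees = n_trees, max_features = max_features,
                   min_samples_split = min_samples_split,
                   min_samples_leaf = min_samples_leaf,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  class(g) <- c("hyper_grid", "data.frame")
  g
}

grid_for_policy <- function(grid, policy) {
  if (policy$name == "probabilistic") {
    grid$min_samples_split <- 2
    grid$min_samples_leaf <- 1
    grid <- grid[!duplicated(grid), , drop = FALSE]
    rownames(grid) <- NULL
  }
  grid
}

fit_seed <- function(seed, outer, inner, cand)
  derive_seed(seed, 7919 * outer, 104729 * inner, cand)

# stable identifier of a grid row: fits are seeded by the candidate's
# values (not its grid position), so selection is invariant to grid order
cand_key <- function(hp)
  derive_seed(0L, hp$n_trees,
              sum(utf8ToInt(as.character(hp$max_features))),
              round(1000 * hp$min_samples_split),
              round(1000 * hp$min_samples_leaf))

fit_policy_model <- function(dataset, train_ids, policy, hp, seed,
                             keep_probability) {
  train <- apply_policy(dataset_subset(dataset, train_ids), policy)
  control <- prf_control(n_trees = hp$n_trees,
                         max_features = hp$max_features,
                         min_samples_split = hp$min_samples_split,
                         min_samples_leaf = hp$min_samples_leaf,
                         keep_probability = keep_probability,
                         seed = seed)
  prf_fit(train, control)
}

#' Inner-loop hyperparameter selection
#'
#' Full grid search: every candidate is trained on each inner training set
#' (after applying the label policy) and scored on the confirmed samples
#' of the corresponding validation set; the candidate with the best mean
#' selection metric over the inner folds wins. Ties are broken by higher
#' mean AUC, then smaller `n_trees`, then grid order.
#'
#' @param dataset the full [uncertain_dataset()].
#' @param inner_folds list of `list(train, validation)` index pairs (see
#'   [fold_plan()]).
#' @param grid a [hyper_grid()].
#' @param policy a [label_policy()].
#' @param seed integer seed for the candidate fits.
#' @param outer_index index of the enclosing outer fold (seed derivation).
#' @param selection_metric `"f1"` (default) or `"auc"`.
#' @param threshold classification threshold for the inner metrics.
#' @param keep_probability forwarded to the fits.
#' @return The winning grid row (one-row data.frame) with columns
#'   `mean_metric` and `mean_auc` appended.
#' @export
select_hyperparameters <- function(dataset, inner_folds, grid, policy,
                                   seed, outer_index = 1L,
                                   selection_metric = c("f1", "auc"),
                                   threshold = 0.5,
                                   keep_probability = 0.05) {
  selection_metric <- match.arg(selection_metric)
  grid <- grid_for_policy(grid, policy)
  if (nrow(grid) == 0) stopf("empty hyperparameter grid")
  scores <- matrix(NA_real_, nrow(grid), 2,
                   dimnames = list(NULL, c("metric", "auc")))
  for (g in seq_len(nrow(grid))) {
    hp <- grid[g, ]
    ms <- vapply(seq_along(inner_folds), function(j) {
      fold <- inner_folds[[j]]
      model <- fit_policy_model(dataset, fold$train, policy, hp,
                                fit_seed(seed, outer_index, j, cand_key(hp)),
                                keep_probability)
      ev <- withCallingHandlers(
        evaluate_fold(model, dataset_subset(dataset, fold$validation),
                      threshold),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(ev)) return(c(NA_real_, NA_real_))
      m <- if (selection_metric == "f1") ev$f1 else ev$auc
      c(m, ev$auc)
    }, numeric(2))
    scores[g, "metric"] <- mean(ms[1, ], na.rm = TRUE)
    scores[g, "auc"] <- mean(ms[2, ], na.rm = TRUE)
  }
  if (all(is.na(scores[, "metric"])))
    stopf("no hyperparameter candidate could be scored")
  ord <- order(-scores[, "metric"], -scores[, "auc"], grid$n_trees,
               seq_len(nrow(grid)))
  best <- grid[ord[1], , drop = FALSE]
  best$mean_metric <- scores[ord[1], "metric"]
  best$mean_auc <- scores[ord[1], "auc"]
  rownames(best) <- NULL
  best
}

#' Nested cross-validated comparison of label policies
#'
#' Runs the full protocol: one shared nested stratified fold plan; for
#' each policy and each outer fold, inner-loop hyperparameter selection,
#' training on the policy-transformed outer training set, and evaluation
#' on the confirmed test samples; then fold-averaged reporting. The three
#' policies see identical outer test samples in every fold and identical
#' fit seeds, so the comparison is paired.
#'
#' @param dataset an [uncertain_dataset()].
#' @param policies list of [label_policy()] objects (default: all three at
#'   `posthoc_probability = 0.5`).
#' @param grid a [hyper_grid()].
#' @param k folds for both CV loops (default 7).
#' @param seed master seed: fold plan and every fit derive from it.
#' @param selection_metric inner selection metric, `"f1"` or `"auc"`.
#' @param threshold classification threshold.
#' @param keep_probability propagation-mass threshold for the fits.
#' @return A list of class `prf_comparison`: one `prf_report` per policy
#'   (named by policy), plus attributes carrying the plan and manifest.
#' @export
run_comparison <- function(dataset,
                           policies = list(label_policy("exclude"),
                                           label_policy("naive"),
                                           label_policy("probabilistic")),
                           grid = hyper_grid(), k = 7, seed = 1L,
                           selection_metric = "f1", threshold = 0.5,
                           keep_probability = 0.05) {
  plan <- fold_plan(dataset$label, k = k, seed = seed)
  reports <- lapply(policies, function(policy) {
    folds <- vector("list", plan$k)
    selected <- vector("list", plan$k)
    for (i in seq_len(plan$k)) {
      best <- select_hyperparameters(dataset, plan$inner[[i]], grid, policy,
                                     seed, outer_index = i,
                                     selection_metric = selection_metric,
                                     threshold = threshold,
                                     keep_probability = keep_probability)
      model <- fit_policy_model(dataset, plan$outer[[i]]$train, policy,
                                best, fit_seed(seed, i, 0L, 0L),
                                keep_probability)
      folds[[i]] <- evaluate_fold(
        model, dataset_subset(dataset, plan$outer[[i]]$test), threshold)
      selected[[i]] <- best
    }
    build_report(policy, folds, selected, seed, plan$k)
  })
  names(reports) <- vapply(policies, function(p) p$name, "")
  structure(reports, class = "prf_comparison", plan = plan, seed = seed,
            grid = grid,
            manifest = list(package_version =
                              as.character(utils::packageVersion("prforest")),
                            k = k, seed = seed,
                            selection_metric = selection_metric,
                            threshold = threshold,
                            keep_probability = keep_probability))
}

build_report <- function(policy, folds, selected, seed, k) {
  used <- which(!vapply(folds, is.null, TRUE))
  per_fold <- do.call(rbind, lapply(used, function(i) {
    f <- folds[[i]]
    data.frame(fold = i, TP = f$TP, FP = f$FP, FN = f$FN, TN = f$TN,
               precision = f$precision, recall = f$recall, f1 = f$f1,
               auc = f$auc, f1_defined = f$f1_defined,
               n_confirmed = f$n_confirmed)
  }))
  metrics <- c("auc", "recall", "precision", "f1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_fold[[m]], na.rm = TRUE), 0),
    sd = vapply(metrics, function(m) stats::sd(per_fold[[m]],
                                               na.rm = TRUE), 0),
    row.names = NULL)
  structure(list(policy = policy, folds = per_fold, summary = summary,
                 selected = selected,
                 roc = lapply(folds[used], function(f) f$curve),
                 skipped_folds = setdiff(seq_len(k), used),
                 seed = seed, k = k),
            class = "prf_report")
}

#' @export
print.prf_report <- function(x, ...) {
  cat(sprintf("prf_report: policy = %s (seed %d, %d-fold)\n",
              x$policy$name, x$seed, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %6.2f (%.2f)\n", s$metric[i], s$mean[i], s$sd[i]))
  if (length(x$skipped_folds))
    cat("  skipped folds:", paste(x$skipped_folds, collapse = ", "), "\n")
  invisible(x)
}

#' Summary table of a policy comparison
#'
#' One row per policy with mean (SD) AUC, recall, precision and F1 over
#' the outer test folds, AUC to two decimals and percentages to two
#' decimals.
#'
#' @param object a `prf_comparison` from [run_comparison()].
#' @param ... unused.
#' @return A data.frame.
#' @export
summary.prf_comparison <- function(object, ...) {
  do.call(rbind, lapply(names(object), function(nm) {
    s <- object[[nm]]$summary
    fmt <- function(metric, digits = 2) {
      i <- match(metric, s$metric)
      sprintf("%.*f (%.*f)", digits, s$mean[i], digits, s$sd[i])
    }
    data.frame(policy = nm, AUC = fmt("auc"), Recall = fmt("recall"),
               Precision = fmt("precision"), F1 = fmt("f1"))
  }))
}

#' Vertically averaged ROC curve
#'
#' Interpolates each fold's ROC onto a fixed grid of 101 false-positive
#' rates and averages the true-positive rates (for plotting; the reported
#' AUC remains the mean of per-fold AUCs).
#'
#' @param report a `prf_report`.
#' @return data.frame with `fpr` and mean `tpr`.
#' @export
average_roc <- function(report) {
  grid <- seq(0, 1, length.out = 101)
  tprs <- vapply(report$roc, function(curve) {
    stats::approx(curve$fpr, curve$tpr, xout = grid, ties = max,
                  yleft = 0, yright = 1)$y
  }, numeric(101))
  data.frame(fpr = grid, tpr = rowMeans(tprs))
}
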