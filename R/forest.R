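#' Hyperparameters for a probabilistic random forest
#'
#' @param n_trees number of trees in the ensemble.
#' @param max_features per-node feature-subset strategy: `"sqrt"` (floor of
#'   the square root of d), `"log2"`, `"all"`, or an explicit integer.
#' @param min_samples_split minimum effective mass at a node to attempt a
#'   split. Effective mass generalizes the sample count: it is the sum of
#'   the arrival probabilities of the training samples at the node, and
#'   reduces to a count at zero feature uncertainty.
#' @param min_samples_leaf minimum effective mass per child.
#' @param keep_probability arrival-mass threshold below which a sample's
#'   path into a child is dropped during training (default 0.05).
#' @param max_depth maximum number of splits on any root-to-leaf path;
#'   `NULL` means unlimited.
#' @param seed integer seed; all randomness (bootstraps, per-node feature
#'   subsets) flows from it.
#' @return A list of class `prf_control`.
#' @export
prf_control <- function(n_trees = 100, max_features = "sqrt",
                        min_samples_split = 2, min_samples_leaf = 1,
                        keep_probability = 0.05, max_depth = NULL,
                        seed = 1L) {
  if (n_trees < 1) stopf("n_trees must be >= 1")
  if (min_samples_leaf > min_samples_split)
    stopf("min_samples_leaf must be <= min_samples_split")
  if (keep_probability < 0 || keep_probability > 1)
    stopf("keep_probability must be in [0, 1]")
  structure(list(n_trees = as.integer(n_trees), max_features = max_features,
                 min_samples_split = min_samples_split,
                 min_samples_leaf = min_samples_leaf,
                 keep_probability = keep_probability,
                 max_depth = max_depth, seed = as.integer(seed)),
            class = "prf_control")
}

resolve_mtry <- function(max_features, d) {
  if (is.numeric(max_features)) {
    m <- as.integer(max_features)
  } else {
    m <- switch(as.character(max_features),
                sqrt = floor(sqrt(d)),
                log2 = floor(log2(d)),
                all = d,
                stopf("unknown max_features strategy '%s'", max_features))
  }
  max(1L, min(as.integer(m), d))
}

#' Grow a single probabilistic tree
#'
#' Recursively applies the exhaustive best-split search; each sample is
#' propagated to both children carrying its arrival mass times the Gaussian
#' crossing probability, and a path into a child is dropped when its mass
#' there falls below `keep_probability`. Recursion stops when the node's
#' effective mass is below `min_samples_split`, the maximum depth is
#' reached, the node is pure, or no candidate strictly reduces impurity.
#'
#' @param dataset an [uncertain_dataset()].
#' @param bootstrap_ids integer row indices (with replacement) of the
#'   training samples used by this tree.
#' @param control a [prf_control()].
#' @param class_weights numeric vector of K positive weights (default:
#'   [compute_class_weights()] on the bootstrap pmfs).
#' @param subset_stream optional list of integer feature subsets consumed
#'   in depth-first split-attempt order instead of drawing subsets from the
#'   RNG (used for paired comparisons against reference implementations).
#' @return A list of class `prf_tree` with parallel per-node vectors
#'   `feature`, `threshold`, `left`, `right`, `mass`, `decrease`, a node x K
#'   matrix `dist`, and the consumed feature `subsets`.
#' @export
prf_grow_tree <- function(dataset, bootstrap_ids, control = prf_control(),
                          class_weights = NULL, subset_stream = NULL) {
  if (length(bootstrap_ids) == 0) stopf("empty bootstrap")
  class_weights <- class_weights %||%
    compute_class_weights(dataset$pmf[bootstrap_ids, , drop = FALSE])
  mtry <- resolve_mtry(control$max_features, ncol(dataset$X))
  max_depth <- if (is.null(control$max_depth)) .Machine$integer.max else
    as.integer(control$max_depth)
  tree <- prf_grow_tree_cpp(dataset$X, dataset$DX, dataset$pmf,
                            as.double(class_weights),
                            as.integer(bootstrap_ids), mtry,
                            as.double(control$min_samples_split),
                            as.double(control$min_samples_leaf),
                            as.double(control$keep_probability),
                            max_depth, subset_stream)
  class(tree) <- "prf_tree"
  tree
}

#' Fit a probabilistic random forest
#'
#' Draws `n_trees` bootstrap samples (with replacement, size n) from a
#' seeded RNG stream and grows one probabilistic tree per bootstrap, with a
#' fresh feature subset drawn at every node. Class weights default to the
#' balanced inverse effective-frequency scheme computed on the training
#' pmfs and enter both the split impurities and the stored node
#' distributions. The fit is deterministic given `control$seed`.
#'
#' @param dataset an [uncertain_dataset()] (K >= 2 classes).
#' @param control a [prf_control()].
#' @param class_weights optional fixed class weights.
#' @param bootstraps optional list of per-tree bootstrap index vectors
#'   (overrides the seeded draws; for paired comparisons).
#' @param subset_streams optional list (one per tree) of feature-subset
#'   streams, see [prf_grow_tree()].
#' @return An object of class `prf_forest`.
#' @export
prf_fit <- function(dataset, control = prf_control(), class_weights = NULL,
                    bootstraps = NULL, subset_streams = NULL) {
  stopifnot(inherits(dataset, "uncertain_dataset"))
  n <- n_samples(dataset)
  if (n < 1) stopf("dataset is empty")
  class_weights <- class_weights %||% compute_class_weights(dataset$pmf)
  trees <- vector("list", control$n_trees)
  boots <- vector("list", control$n_trees)
  with_seed(control$seed, {
    for (b in seq_len(control$n_trees)) {
      boot <- if (!is.null(bootstraps)) as.integer(bootstraps[[b]]) else
        sample.int(n, n, replace = TRUE)
      stream <- if (!is.null(subset_streams)) subset_streams[[b]] else NULL
      boots[[b]] <- boot
      trees[[b]] <- prf_grow_tree(dataset, boot, control,
                                  class_weights = class_weights,
                                  subset_stream = stream)
    }
  })
  structure(list(trees = trees, control = control,
                 feature_names = dataset$feature_names,
                 class_names = dataset$class_names,
                 class_weights = class_weights,
                 bootstrap_ids = lapply(boots, function(b)
                   dataset$sample_id[b]),
                 n_train = n),
            class = "prf_forest")
}

#' @export
print.prf_forest <- function(x, ...) {
  cat(sprintf("prf_forest: %d trees, %d features, classes: %s\n",
              length(x$trees), length(x$feature_names),
              paste(x$class_names, collapse = ", ")))
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%.4f", x$class_weights), collapse = ", ")))
  invisible(x)
}

#' Class probabilities from a single probabilistic tree
#'
#' A test point is propagated down the tree; at every split it continues to
#' both children with the Gaussian crossing probabilities, so it reaches
#' each leaf with some arrival mass. The returned distribution is the
#' arrival-mass-weighted mean of the leaf class distributions. With
#' `prune = FALSE` (the default) no path is dropped and the leaf arrival
#' masses sum to 1.
#'
#' @param tree a `prf_tree`.
#' @param X numeric matrix (or vector for one sample) of feature values.
#' @param DX optional matrix of feature uncertainties (default all zero:
#'   deterministic routing).
#' @param prune drop paths whose mass falls below `keep_probability`
#'   (training-style pruning; the output is then renormalized).
#' @param keep_probability mass threshold used when `prune = TRUE`.
#' @return Numeric n x K matrix of class probabilities.
#' @export
predict_proba_tree <- function(tree, X, DX = NULL, prune = FALSE,
                               keep_probability = 0.05) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (is.null(DX)) DX <- matrix(0, nrow(X), ncol(X))
  DX <- as.matrix(DX)
  if (!identical(dim(DX), dim(X))) stopf("DX must have the same shape as X")
  prf_predict_tree_cpp(tree, X, DX, prune, keep_probability)
}

#' Predict class probabilities with a probabilistic random forest
#'
#' The forest prediction is the unweighted mean over trees of the per-tree
#' probabilities; every row sums to 1.
#'
#' @param object a fitted `prf_forest`.
#' @param X numeric matrix of feature values (d columns) or an
#'   [uncertain_dataset()].
#' @param DX optional matrix of test-time feature uncertainties; defaults
#'   to zero (label uncertainty is never used at test time).
#' @param type `"prob"` for the n x K probability matrix, `"class"` for
#'   hard labels (argmax; ties go to the lower class index).
#' @param prune,keep_probability see [predict_proba_tree()].
#' @param ... unused.
#' @return Probability matrix or character vector of class names.
#' @export
predict.prf_forest <- function(object, X, DX = NULL,
                               type = c("prob", "class"), prune = FALSE,
                               keep_probability = NULL, ...) {
  type <- match.arg(type)
  if (inherits(X, "uncertain_dataset")) {
    if (is.null(DX)) DX <- matrix(0, nrow(X$X), ncol(X$X))
    X <- X$X
  }
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != length(object$feature_names))
    stopf("X has %d columns; model expects %d", ncol(X),
          length(object$feature_names))
  keep_probability <- keep_probability %||% object$control$keep_probability
  acc <- matrix(0, nrow(X), length(object$class_names))
  for (tree in object$trees)
    acc <- acc + predict_proba_tree(tree, X, DX, prune, keep_probability)
  probs <- acc / length(object$trees)
  colnames(probs) <- object$class_names
  if (type == "prob") return(probs)
  object$class_names[max.col(probs, ties.method = "first")]
}

#' Impurity-decrease feature importances
#'
#' For each tree, every split contributes its effective-mass-weighted
#' impurity decrease to the split feature; per-tree vectors are normalized
#' and averaged over trees, then renormalized to sum to 1.
#'
#' @param model a fitted `prf_forest`.
#' @return Named numeric vector of d non-negative importances summing to 1.
#' @export
feature_importances <- function(model) {
  d <- length(model$feature_names)
  acc <- numeric(d)
  n_used <- 0L
  for (tree in model$trees) {
    internal <- !is.na(tree$feature)
    if (!any(internal)) next
    v <- numeric(d)
    dec <- tapply(tree$decrease[internal], tree$feature[internal], sum)
    v[as.integer(names(dec))] <- dec
    if (sum(v) > 0) {
      acc <- acc + v / sum(v)
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) return(stats::setNames(rep(0, d), model$feature_names))
  out <- acc / n_used
  stats::setNames(out / sum(out), model$feature_names)
}

#' Serialize a fitted forest to JSON
#'
#' Writes the complete tree structure (split features and thresholds, child
#' indices, node class distributions and effective masses), the
#' hyperparameters, class weights and seed to a plain-text JSON file from
#' which the model can be reconstructed exactly.
#'
#' @param model a fitted `prf_forest`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
model_to_json <- function(model, path) {
  obj <- list(
    format = "prforest-model",
    version = 1L,
    control = unclass(model$control),
    feature_names = model$feature_names,
    class_names = model$class_names,
    class_weights = model$class_weights,
    n_train = model$n_train,
    bootstrap_ids = model$bootstrap_ids,
    trees = lapply(model$trees, function(tr) {
      list(feature = tr$feature, threshold = tr$threshold, left = tr$left,
           right = tr$right, mass = tr$mass, decrease = tr$decrease,
           dist = apply(tr$dist, 1L, function(r) r, simplify = FALSE))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = FALSE)
  invisible(path)
}

#' Load a forest serialized with [model_to_json()]
#' @param path JSON file path.
#' @return A `prf_forest`.
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "prforest-model"))
    stopf("%s is not a prforest model file", path)
  ctrl <- obj$control
  if (length(ctrl$max_depth) == 0) ctrl$max_depth <- NULL
  control <- prf_control(n_trees = ctrl$n_trees,
                         max_features = ctrl$max_features,
                         min_samples_split = ctrl$min_samples_split,
                         min_samples_leaf = ctrl$min_samples_leaf,
                         keep_probability = ctrl$keep_probability,
                         max_depth = ctrl$max_depth, seed = ctrl$seed)
  trees <- lapply(obj$trees, function(tr) {
    structure(list(feature = as.integer(tr$feature),
                   threshold = as.double(tr$threshold),
                   left = as.integer(tr$left),
                   right = as.integer(tr$right),
                   dist = do.call(rbind, lapply(tr$dist, as.double)),
                   mass = as.double(tr$mass),
                   decrease = as.double(tr$decrease)),
              class = "prf_tree")
  })
  structure(list(trees = trees, control = control,
                 feature_names = obj$feature_names,
                 class_names = obj$class_names,
                 class_weights = as.double(obj$class_weights),
                 bootstrap_ids = obj$bootstrap_ids,
                 n_train = obj$n_train),
            class = "prf_forest")
}

#' Leaf arrival masses of a test point in one tree
#'
#' Exposes the per-leaf arrival probabilities used by the prediction rule;
#' with `prune = FALSE` they sum to 1 exactly (conservation of propagated
#' mass).
#'
#' @param tree a `prf_tree`.
#' @param x numeric feature vector.
#' @param dx numeric uncertainty vector (default zero).
#' @param prune,keep_probability see [predict_proba_tree()].
#' @return Numeric vector over tree nodes; non-zero only at leaves.
#' @export
leaf_arrivals <- function(tree, x, dx = NULL, prune = FALSE,
                          keep_probability = 0.05) {
  dx <- dx %||% rep(0, length(x))
  prf_leaf_arrivals_cpp(tree, as.double(x), as.double(dx), prune,
                        keep_probability)
}
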