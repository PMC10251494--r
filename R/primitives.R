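#' Probability that an uncertain feature value crosses a threshold
#'
#' An uncertain measurement is modeled as a Gaussian with mean `x` (the
#' recorded value) and standard deviation `dx` (the uncertainty); the
#' probability of falling on the right side of a split threshold `t` is the
#' upper-tail mass P(N(x, dx^2) > t). With `dx = 0` the Gaussian degenerates
#' to a point mass and the function becomes the step `x > t`.
#'
#' @param x numeric vector of feature values.
#' @param dx numeric vector of non-negative uncertainties (recycled).
#' @param t numeric vector of thresholds (recycled).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' gaussian_right_probability(0, 1, 1)  # 1 - pnorm(1)
#' gaussian_right_probability(2, 0, 1)  # step function: 1
#' @export
gaussian_right_probability <- function(x, dx, t) {
  if (any(dx < 0)) stopf("dx must be non-negative")
  n <- max(length(x), length(dx), length(t))
  x <- rep_len(x, n); dx <- rep_len(dx, n); t <- rep_len(t, n)
  out <- numeric(n)
  zero <- dx == 0
  out[zero] <- as.numeric(x[zero] > t[zero])
  if (any(!zero))
    out[!zero] <- stats::pnorm(t[!zero], mean = x[!zero], sd = dx[!zero],
                               lower.tail = FALSE)
  out
}

#' Probability-weighted class distribution of a tree node
#'
#' Combines the arrival masses of the samples sitting at a node with their
#' label pmfs and the global class weights into the node's class
#' distribution: p_c = w_c * sum_i m_i pmf_ic, normalized over classes.
#'
#' @param arrival_probs numeric vector of non-negative arrival masses.
#' @param label_pmfs numeric n x K matrix of label pmfs.
#' @param class_weights numeric vector of K positive class weights
#'   (default: all 1).
#' @return Numeric vector of K class probabilities summing to 1.
#' @export
node_class_distribution <- function(arrival_probs, label_pmfs,
                                    class_weights = NULL) {
  label_pmfs <- as.matrix(label_pmfs)
  if (length(arrival_probs) != nrow(label_pmfs))
    stopf("arrival_probs and label_pmfs disagree on n")
  if (any(arrival_probs < 0)) stopf("arrival masses must be non-negative")
  K <- ncol(label_pmfs)
  class_weights <- class_weights %||% rep(1, K)
  s <- colSums(arrival_probs * label_pmfs)
  q <- class_weights * s
  z <- sum(q)
  if (z <= 0) stopf("degenerate node: zero total class mass")
  unname(q / z)
}

#' Gini impurity of a class distribution
#'
#' `1 - sum(p^2)`: zero for a pure (one-hot) node, maximal (`1 - 1/K`) at
#' the uniform distribution. Applied to probability-weighted class
#' fractions this is the modified Gini impurity used for probabilistic
#' split scoring.
#'
#' @param class_distribution numeric vector summing to 1.
#' @return Impurity in \[0, 1 - 1/K\].
#' @export
modified_gini <- function(class_distribution) {
  if (abs(sum(class_distribution) - 1) > 1e-6)
    stopf("class distribution must sum to 1")
  1 - sum(class_distribution^2)
}

#' Cost of a candidate split
#'
#' Propagates every sample at a node to both children with its Gaussian
#' crossing probability, forms the children's probability-weighted class
#' distributions, and returns the child-mass-weighted mean of the two
#' children's Gini impurities. A candidate that sends all mass to one side
#' returns the parent impurity (a no-gain sentinel).
#'
#' @param X,DX numeric matrices (samples at the node; uncertainties).
#' @param pmf numeric n x K matrix of label pmfs.
#' @param arrival_probs numeric vector of arrival masses.
#' @param feature_index 1-based feature column.
#' @param threshold split threshold (feature units).
#' @param class_weights numeric vector of K positive class weights.
#' @return The scalar split cost.
#' @export
split_cost <- function(X, DX, pmf, arrival_probs, feature_index, threshold,
                       class_weights = NULL) {
  X <- as.matrix(X); DX <- as.matrix(DX); pmf <- as.matrix(pmf)
  if (sum(arrival_probs) <= 0) stopf("no arrival mass at node")
  pR <- gaussian_right_probability(X[, feature_index], DX[, feature_index],
                                   threshold)
  mR <- arrival_probs * pR
  mL <- arrival_probs - mR
  parent <- modified_gini(node_class_distribution(arrival_probs, pmf,
                                                  class_weights))
  if (sum(mL) <= 0 || sum(mR) <= 0) return(parent)
  gL <- modified_gini(node_class_distribution(mL, pmf, class_weights))
  gR <- modified_gini(node_class_distribution(mR, pmf, class_weights))
  (sum(mL) * gL + sum(mR) * gR) / sum(arrival_probs)
}

#' Exhaustive best-split search at a node
#'
#' Evaluates, for every feature in `feature_subset`, the midpoints between
#' consecutive distinct sorted feature values among samples with arrival
#' mass at least `keep_probability`, and returns the minimal-cost candidate
#' whose children both carry at least `min_samples_leaf` effective mass.
#' Ties are broken by lower feature index, then lower threshold.
#'
#' @param X,DX,pmf,arrival_probs,class_weights as in [split_cost()].
#' @param feature_subset integer vector of 1-based feature indices.
#' @param min_samples_leaf minimum effective mass per child (default 1).
#' @param keep_probability candidate-set mass threshold (default 0.05).
#' @return `NULL` when no candidate strictly reduces the parent impurity,
#'   otherwise a list with `feature_index`, `threshold`, `cost`,
#'   `parent_impurity`.
#' @export
find_best_split <- function(X, DX, pmf, arrival_probs, feature_subset,
                            class_weights = NULL, min_samples_leaf = 1,
                            keep_probability = 0.05) {
  X <- as.matrix(X); DX <- as.matrix(DX); pmf <- as.matrix(pmf)
  if (length(feature_subset) == 0) stopf("feature_subset must be non-empty")
  class_weights <- class_weights %||% rep(1, ncol(pmf))
  res <- prf_best_split_cpp(X, DX, pmf, as.double(class_weights),
                            as.integer(seq_len(nrow(X))),
                            as.double(arrival_probs),
                            as.integer(feature_subset),
                            as.double(min_samples_leaf),
                            as.double(keep_probability))
  if (!isTRUE(res$improving)) return(NULL)
  list(feature_index = res$feature, threshold = res$threshold,
       cost = res$cost, parent_impurity = res$parent_impurity)
}

#' Balanced class weights from soft labels
#'
#' The effective count of class c is the total pmf mass assigned to it,
#' `m_c = sum_i pmf_ic`; the balanced weight is `n / (K * m_c)` so that
#' every class contributes equally to the impurity regardless of
#' prevalence. Reduces to the usual balanced scheme for one-hot labels.
#'
#' @param label_pmfs numeric n x K matrix of label pmfs.
#' @return Numeric vector of K positive weights (named if `label_pmfs`
#'   has column names).
#' @export
compute_class_weights <- function(label_pmfs) {
  label_pmfs <- as.matrix(label_pmfs)
  n <- nrow(label_pmfs)
  K <- ncol(label_pmfs)
  m <- colSums(label_pmfs)
  if (any(m <= 0)) {
    bad <- colnames(label_pmfs)[m <= 0] %||% which(m <= 0)
    stopf("class(es) with zero effective count: %s",
          paste(bad, collapse = ", "))
  }
  n / (K * m)
}
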