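#' Tabular dataset with uncertain class labels
#'
#' Container for per-subject data in which every sample carries, besides its
#' feature vector, a per-feature measurement uncertainty, a probability mass
#' function (pmf) over the class labels, and a label-status flag stating
#' whether the recorded label was confirmed or assigned post hoc.
#'
#' Confirmed samples must have a one-hot pmf; post-hoc samples may put
#' probability mass on several classes. Feature uncertainties are standard
#' deviations in the feature's own units; binary features must have zero
#' uncertainty.
#'
#' @param X numeric matrix, n samples x d features (column names are the
#'   feature names).
#' @param label character or factor of length n: the nominal class of each
#'   sample (for post-hoc samples, the label recorded after the fact).
#' @param status character of length n, each `"confirmed"` or `"posthoc"`.
#' @param class_names character of length K >= 2; the second entry is
#'   treated as the positive class by the evaluation layer. Defaults to the
#'   distinct labels in order of appearance.
#' @param DX numeric matrix of feature uncertainties (same shape as `X`);
#'   defaults to all zeros (exactly known features).
#' @param pmf numeric n x K matrix of per-sample label pmfs; defaults to the
#'   one-hot encoding of `label`.
#' @param sample_id character of length n, unique; defaults to `"S1".."Sn"`.
#'
#' @return An object of class `uncertain_dataset`: a list with elements
#'   `X`, `DX`, `pmf`, `label`, `status`, `sample_id`, `feature_names`,
#'   `class_names`.
#' @export
uncertain_dataset <- function(X, label, status,
                              class_names = NULL, DX = NULL, pmf = NULL,
                              sample_id = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  d <- ncol(X)
  if (n < 1L || d < 1L) stopf("X must have at least one row and column")
  feature_names <- colnames(X) %||% paste0("f", seq_len(d))
  colnames(X) <- feature_names

  label <- as.character(label)
  if (length(label) != n) stopf("label must have length nrow(X)")
  class_names <- class_names %||% unique(label)
  if (length(class_names) < 2L) stopf("need at least two class names")
  if (!all(label %in% class_names))
    stopf("unknown label(s): %s",
          paste(setdiff(label, class_names), collapse = ", "))
  K <- length(class_names)

  status <- as.character(status)
  if (length(status) != n || !all(status %in% c("confirmed", "posthoc")))
    stopf("status must be 'confirmed' or 'posthoc' for every sample")

  if (is.null(DX)) DX <- matrix(0, n, d)
  DX <- as.matrix(DX)
  storage.mode(DX) <- "double"
  if (!identical(dim(DX), dim(X))) stopf("DX must have the same shape as X")
  if (any(DX < 0)) stopf("feature uncertainties must be non-negative")
  colnames(DX) <- feature_names

  if (is.null(pmf)) pmf <- one_hot(label, class_names)
  pmf <- as.matrix(pmf)
  storage.mode(pmf) <- "double"
  if (nrow(pmf) != n || ncol(pmf) != K)
    stopf("pmf must be an n x K matrix")
  colnames(pmf) <- class_names

  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stopf("sample_id values must be unique")

  ds <- structure(list(X = X, DX = DX, pmf = pmf, label = label,
                       status = status, sample_id = sample_id,
                       feature_names = feature_names,
                       class_names = class_names),
                  class = "uncertain_dataset")
  validate_dataset(ds)
  ds
}

one_hot <- function(label, class_names) {
  m <- matrix(0, length(label), length(class_names),
              dimnames = list(NULL, class_names))
  m[cbind(seq_along(label), match(label, class_names))] <- 1
  m
}

validate_dataset <- function(ds, tol = 1e-9) {
  rs <- rowSums(ds$pmf)
  if (any(ds$pmf < -tol) || any(abs(rs - 1) > tol))
    stopf("label pmfs must be non-negative and sum to 1 (tolerance %g)", tol)
  conf <- ds$status == "confirmed"
  if (any(conf)) {
    oh <- apply(ds$pmf[conf, , drop = FALSE], 1L,
                function(p) any(abs(p - 1) <= tol))
    if (!all(oh)) stopf("confirmed samples must have one-hot label pmfs")
  }
  # binary features (values only in {0,1}) must be exactly known
  for (j in seq_len(ncol(ds$X))) {
    if (all(ds$X[, j] %in% c(0, 1)) && any(ds$DX[, j] > 0))
      stopf("binary feature '%s' must have zero uncertainty",
            ds$feature_names[j])
  }
  invisible(ds)
}

#' Subset an uncertain dataset by sample
#'
#' @param ds an [uncertain_dataset()].
#' @param ids integer indices or character sample ids.
#' @return The subsetted `uncertain_dataset` (sample order follows `ids`).
#' @export
dataset_subset <- function(ds, ids) {
  if (is.character(ids)) ids <- match(ids, ds$sample_id)
  if (anyNA(ids) || any(ids < 1L) || any(ids > length(ds$sample_id)))
    stopf("invalid sample ids")
  uncertain_dataset(ds$X[ids, , drop = FALSE], ds$label[ids],
                    ds$status[ids], class_names = ds$class_names,
                    DX = ds$DX[ids, , drop = FALSE],
                    pmf = ds$pmf[ids, , drop = FALSE],
                    sample_id = ds$sample_id[ids])
}

#' @export
print.uncertain_dataset <- function(x, ...) {
  cat(sprintf("uncertain_dataset: %d samples x %d features, %d classes\n",
              nrow(x$X), ncol(x$X), length(x$class_names)))
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  confirmed: %d, post hoc: %d\n",
              sum(x$status == "confirmed"), sum(x$status == "posthoc")))
  invisible(x)
}

#' Number of samples in an uncertain dataset
#' @param ds an [uncertain_dataset()].
#' @return Integer sample count.
#' @export
n_samples <- function(ds) nrow(ds$X)
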