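#' Configuration of the synthetic cohort generator
#'
#' Describes a simulated early-MS-style cohort: a fixed number of
#' confirmed outcome-positive and confirmed stable subjects plus a block
#' of post-hoc "stable" labels whose latent truth is Bernoulli. Volumetric
#' features (deep-gray-matter volumes and T2w lesion volume, mm^3) are
#' log-normal with class-conditional location shifts expressed as
#' standardized effects on the log scale; the treatment arm is an
#' independent Bernoulli flag.
#'
#' The default feature table gives the stable class a lesion-volume median
#' matching the cohort-level median of the emulated trial (1675.15 mm^3)
#' and a log-scale spread derived from its quartiles; positive-class
#' shifts are negative for DGM volumes (strongest for the thalami) and
#' positive for lesion volume.
#'
#' @param n_confirmed_positive,n_confirmed_stable,n_posthoc stratum sizes
#'   (defaults 81, 29, 32).
#' @param latent_positive_rate_posthoc probability that a post-hoc
#'   "stable" subject truly belongs to the positive class (default 0.5).
#' @param features data.frame with columns `name`, `family` ("lognormal"
#'   or "bernoulli"), `meanlog`, `sdlog`, `effect` (positive-class shift
#'   in units of `sdlog`), `rate` (bernoulli only).
#' @param treatment_assignment_rate Bernoulli rate of the treatment flag.
#' @param class_names the two class names (stable first).
#' @param seed integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_confirmed_positive = 81,
                             n_confirmed_stable = 29,
                             n_posthoc = 32,
                             latent_positive_rate_posthoc = 0.5,
                             features = default_feature_table(),
                             treatment_assignment_rate = 0.5,
                             class_names = c("stable",
                                             "new_disease_activity"),
                             seed = 1L) {
  bad <- character()
  if (n_confirmed_positive < 0) bad <- c(bad, "n_confirmed_positive")
  if (n_confirmed_stable < 0) bad <- c(bad, "n_confirmed_stable")
  if (n_posthoc < 0) bad <- c(bad, "n_posthoc")
  if (latent_positive_rate_posthoc < 0 || latent_positive_rate_posthoc > 1)
    bad <- c(bad, "latent_positive_rate_posthoc")
  if (treatment_assignment_rate < 0 || treatment_assignment_rate > 1)
    bad <- c(bad, "treatment_assignment_rate")
  req <- c("name", "family", "meanlog", "sdlog", "effect", "rate")
  if (!all(req %in% names(features)) ||
      !all(features$family %in% c("lognormal", "bernoulli")) ||
      any(features$sdlog[features$family == "lognormal"] <= 0) ||
      any(!is.finite(features$effect)))
    bad <- c(bad, "features")
  if (length(class_names) != 2) bad <- c(bad, "class_names")
  if (length(bad))
    stopf("invalid synthetic_config field(s): %s", paste(bad, collapse = ", "))
  structure(list(n_confirmed_positive = as.integer(n_confirmed_positive),
                 n_confirmed_stable = as.integer(n_confirmed_stable),
                 n_posthoc = as.integer(n_posthoc),
                 latent_positive_rate_posthoc = latent_positive_rate_posthoc,
                 features = features,
                 treatment_assignment_rate = treatment_assignment_rate,
                 class_names = class_names, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic feature table
#'
#' Eight DGM volumes, T2w lesion volume (BOD) and the binary treatment
#' arm. Stable-class medians are plausible adult values in mm^3; the BOD
#' log-scale sd (1.213) is derived from the emulated cohort's quartiles
#' (log(3796.8 / 550.475) / (2 * 0.6745)); DGM spreads reflect ~10%
#' inter-subject variability.
#'
#' @return data.frame suitable for [synthetic_config()].
#' @export
default_feature_table <- function() {
  vol <- function(name, median, sdlog, effect)
    data.frame(name = name, family = "lognormal", meanlog = log(median),
               sdlog = sdlog, effect = effect, rate = NA_real_)
  rbind(
    vol("L_thalamus", 7500, 0.10, -0.80),
    vol("R_thalamus", 7400, 0.10, -0.80),
    vol("L_putamen", 5000, 0.11, -0.25),
    vol("R_putamen", 4900, 0.11, -0.25),
    vol("L_caudate", 3800, 0.12, -0.20),
    vol("R_caudate", 3700, 0.12, -0.20),
    vol("L_pallidum", 1700, 0.12, -0.20),
    vol("R_pallidum", 1650, 0.12, -0.20),
    vol("BOD", 1675.15, 1.213, 0.90),
    data.frame(name = "treatment", family = "bernoulli", meanlog = NA_real_,
               sdlog = NA_real_, effect = 0, rate = 0.5))
}

#' Generate a synthetic cohort
#'
#' Latent truth: confirmed strata are fixed by construction; each
#' post-hoc subject is truly positive with probability
#' `latent_positive_rate_posthoc`. Confirmed subjects' nominal labels
#' equal their latent truth; every post-hoc subject carries the nominal
#' label "stable" regardless of truth. Features are drawn from the
#' class-conditional families of the config. Deterministic given
#' `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_cohort`: `dataset` (an
#'   [uncertain_dataset()] with one-hot pmfs at the nominal labels) and
#'   `latent_truth` (character vector, hidden from learners).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cls <- config$class_names
  n <- config$n_confirmed_positive + config$n_confirmed_stable +
    config$n_posthoc
  status <- c(rep("confirmed", config$n_confirmed_positive +
                    config$n_confirmed_stable),
              rep("posthoc", config$n_posthoc))
  with_seed(config$seed, {
    truth <- c(rep(cls[2], config$n_confirmed_positive),
               rep(cls[1], config$n_confirmed_stable),
               ifelse(stats::rbinom(config$n_posthoc, 1,
                                    config$latent_positive_rate_posthoc) == 1,
                      cls[2], cls[1]))
    X <- draw_features(config$features, truth, cls,
                       config$treatment_assignment_rate)
  })
  label <- ifelse(status == "posthoc", cls[1], truth)
  ds <- uncertain_dataset(X, label, status, class_names = cls,
                          sample_id = sprintf("S%03d", seq_len(n)))
  structure(list(dataset = ds, latent_truth = truth, config = config),
            class = "synthetic_cohort")
}

draw_features <- function(features, truth, cls, treatment_rate) {
  n <- length(truth)
  pos <- truth == cls[2]
  X <- matrix(0, n, nrow(features),
              dimnames = list(NULL, features$name))
  for (j in seq_len(nrow(features))) {
    f <- features[j, ]
    if (f$family == "lognormal") {
      mu <- ifelse(pos, f$meanlog + f$effect * f$sdlog, f$meanlog)
      X[, j] <- stats::rlnorm(n, meanlog = mu, sdlog = f$sdlog)
    } else {
      rate <- if (f$name == "treatment") treatment_rate else f$rate
      X[, j] <- stats::rbinom(n, 1, rate)
    }
  }
  X
}

#' Write a cohort to CSV (plus a latent-truth sidecar)
#'
#' The modeling table holds `sample_id`, one column per feature, `label`,
#' `label_status` and `p_stable` (the pmf mass on the first class);
#' floats are serialized at full precision so the round trip through
#' [csv_to_dataset()] is lossless. The latent truth goes to a separate
#' sidecar file (`<path base>_truth.csv`) and never into the modeling
#' table.
#'
#' @param cohort a `synthetic_cohort` (or an [uncertain_dataset()], in
#'   which case no sidecar is written).
#' @param path output CSV path.
#' @return Named character vector of the file(s) written, invisibly.
#' @export
cohort_to_csv <- function(cohort, path) {
  ds <- if (inherits(cohort, "synthetic_cohort")) cohort$dataset else cohort
  num <- function(x) sprintf("%.17g", x)
  tab <- data.frame(sample_id = ds$sample_id,
                    apply(ds$X, 2L, num),
                    label = ds$label, label_status = ds$status,
                    p_stable = num(ds$pmf[, 1]),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  out <- c(cohort = path)
  if (inherits(cohort, "synthetic_cohort")) {
    tpath <- sub("\\.csv$", "", path)
    tpath <- paste0(tpath, "_truth.csv")
    utils::write.csv(data.frame(sample_id = ds$sample_id,
                                latent_class = cohort$latent_truth),
                     tpath, row.names = FALSE, quote = FALSE)
    out <- c(out, truth = tpath)
  }
  invisible(out)
}

#' Read a cohort CSV written by [cohort_to_csv()]
#'
#' @param path CSV path.
#' @param class_names class names (stable class first); defaults to the
#'   distinct labels in file order.
#' @return An [uncertain_dataset()]. Missing required columns raise a
#'   parse error naming the column; unknown columns raise a warning and
#'   are ignored. If the `p_stable` column is absent, pmfs are synthesized
#'   as one-hot at the nominal labels.
#' @export
csv_to_dataset <- function(path, class_names = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  required <- c("sample_id", "label", "label_status")
  for (col in required)
    if (!col %in% names(tab))
      stopf("%s: missing required column '%s'", path, col)
  known <- c(required, "p_stable")
  feat_cols <- setdiff(names(tab), known)
  numeric_ok <- vapply(tab[feat_cols], is.numeric, TRUE)
  if (any(!numeric_ok)) {
    warning(sprintf("ignoring unknown non-numeric column(s): %s",
                    paste(feat_cols[!numeric_ok], collapse = ", ")))
    feat_cols <- feat_cols[numeric_ok]
  }
  if (length(feat_cols) == 0) stopf("%s: no feature columns found", path)
  X <- as.matrix(tab[feat_cols])
  if (is.null(class_names)) {
    class_names <- unique(tab$label)
    # the stable/negative class is the reference: keep it first so the
    # evaluation layer's positive class (second entry) is well defined
    # regardless of row order in the file
    if ("stable" %in% class_names)
      class_names <- c("stable", setdiff(class_names, "stable"))
  }
  if (length(class_names) < 2)
    class_names <- unique(c(class_names, "new_disease_activity"))
  pmf <- if ("p_stable" %in% names(tab)) {
    cbind(tab$p_stable, 1 - tab$p_stable)
  } else NULL
  uncertain_dataset(X, tab$label, tab$label_status,
                    class_names = class_names, pmf = pmf,
                    sample_id = tab$sample_id)
}
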