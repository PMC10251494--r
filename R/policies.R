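#' Label-handling policy for uncertain (post-hoc) labels
#'
#' Three approaches for training on a cohort that mixes confirmed outcome
#' labels with post-hoc labels of unknown truth:
#' \describe{
#'   \item{exclude}{drop the post-hoc samples and train on confirmed labels
#'     only.}
#'   \item{naive}{keep all samples and treat every post-hoc label as if it
#'     were confirmed (one-hot at the nominal label).}
#'   \item{probabilistic}{keep all samples; each post-hoc sample's label
#'     pmf puts `posthoc_probability` on its nominal label and the
#'     remainder on the other class(es).}
#' }
#'
#' @param name one of `"exclude"`, `"naive"`, `"probabilistic"`.
#' @param posthoc_probability probability assigned to the nominal label of
#'   a post-hoc sample under the probabilistic policy; in (0, 1], default
#'   0.5 (no prior information on either side).
#' @return A list of class `label_policy`.
#' @export
label_policy <- function(name = c("exclude", "naive", "probabilistic"),
                         posthoc_probability = 0.5) {
  name <- match.arg(name)
  if (posthoc_probability <= 0 || posthoc_probability > 1)
    stopf("posthoc_probability must be in (0, 1]")
  structure(list(name = name, posthoc_probability = posthoc_probability),
            class = "label_policy")
}

#' Apply a label policy to a dataset
#'
#' Confirmed samples are never altered (their pmfs stay one-hot). The
#' probabilistic policy with `posthoc_probability = 1` is identical to the
#' naive policy.
#'
#' @param dataset an [uncertain_dataset()].
#' @param policy a [label_policy()].
#' @return The transformed `uncertain_dataset`.
#' @export
apply_policy <- function(dataset, policy) {
  stopifnot(inherits(dataset, "uncertain_dataset"),
            inherits(policy, "label_policy"))
  post <- dataset$status == "posthoc"
  if (policy$name == "exclude") {
    keep <- which(!post)
    out <- dataset_subset(dataset, keep)
    counts <- colSums(out$pmf)
    if (any(counts <= 0))
      stopf("excluding post-hoc samples empties class(es): %s",
            paste(dataset$class_names[counts <= 0], collapse = ", "))
    return(out)
  }
  pmf <- one_hot(dataset$label, dataset$class_names)
  if (policy$name == "probabilistic" && any(post)) {
    p <- policy$posthoc_probability
    K <- length(dataset$class_names)
    for (i in which(post)) {
      nominal <- match(dataset$label[i], dataset$class_names)
      row <- rep((1 - p) / (K - 1), K)
      row[nominal] <- p
      pmf[i, ] <- row
    }
  }
  uncertain_dataset(dataset$X, dataset$label, dataset$status,
                    class_names = dataset$class_names, DX = dataset$DX,
                    pmf = pmf, sample_id = dataset$sample_id)
}
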