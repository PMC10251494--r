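---
title: "Probabilistic random forests for cohorts with uncertain outcome labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic random forests for cohorts with uncertain outcome labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical prediction cohorts routinely contain subjects whose outcome is not
known with certainty: participants drop out before the follow-up window
closes, or are recruited too late to be observed for the full window. The
common practice of assigning such subjects a *post hoc* label after expert
deliberation leaves a block of labels whose truth is unknown. With small
cohorts — the regime in which most imaging studies operate — neither of the
two easy options is attractive: excluding the uncertain subjects shrinks an
already small training set, while accepting the post hoc labels at face
value injects label noise at a rate that materially biases the classifier.

`prforest` implements the third option: a **probabilistic random forest
(PRF)**, a random-forest variant in which class labels (and optionally
input features) are probability functions rather than point values, along
with the complete evaluation protocol needed to compare the three
label-handling policies fairly on one dataset.

## The model

A training sample is a tuple $(x_i, \Delta x_i, p_i)$: a feature vector,
per-feature measurement uncertainties, and a probability mass function
$p_i(c)$ over the $K$ classes. A confirmed outcome is a one-hot pmf; an
uncertain outcome spreads its mass (by default $0.5/0.5$ in the two-class
setting).

**Propagation.** An uncertain feature is modeled as Gaussian with mean
$x_{ij}$ and standard deviation $\Delta x_{ij}$. At a split on feature $j$
with threshold $t$, sample $i$ continues *to both children*: to the right
with probability $\pi_R = P(\mathcal N(x_{ij}, \Delta x_{ij}^2) > t)$ and
to the left with $1 - \pi_R$. With $\Delta x = 0$ this is the usual step
function and routing is deterministic. A sample's *arrival mass* at a node
is the product of the propagation probabilities along the path; the
node's *effective mass* is the sum of arrival masses and generalizes the
sample count.

**Split scoring.** A node's class distribution is the probability-weighted
class fraction

$$\hat p_c \;=\; \frac{w_c \sum_i m_i\, p_i(c)}{\sum_{c'} w_{c'} \sum_i m_i\, p_i(c')},$$

where $m_i$ are arrival masses and $w_c$ are class weights. The modified
Gini impurity is $G = 1 - \sum_c \hat p_c^2$, and a candidate split costs
the effective-mass-weighted mean of its children's impurities. Candidate
thresholds are the midpoints between consecutive distinct feature values
at the node — standard CART practice, exhaustive and deterministic. Ties
are broken toward the lower feature index, then the lower threshold. A
split is accepted only if it reduces impurity by more than $10^{-12}$
(guarding against floating-point "improvements" between numerically
identical children).

**Degeneration to a random forest.** With all $\Delta x = 0$, one-hot
pmfs and `keep_probability = 0`, every sample follows a single path with
mass 1 and the modified Gini reduces to the ordinary weighted Gini. The
test suite verifies that in this regime the grown trees are *identical* —
split for split, threshold for threshold — to an independently implemented
greedy CART ensemble on shared bootstraps and feature subsets.

**Prediction.** A test point is propagated through each tree (with zero
feature uncertainty unless supplied; label uncertainty is never used at
test time) and reaches each leaf with some arrival mass; the tree returns
the mass-weighted average of leaf distributions, and the forest averages
over trees. With pruning disabled the leaf arrival masses sum to exactly
1, a conservation law the tests check to $10^{-9}$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_trees` | 100 | ensemble size |
| `max_features` | `"sqrt"` | per-node feature-subset size (`"sqrt"`, `"log2"`, `"all"`, or an integer) |
| `min_samples_split` | 2 | minimum effective mass to attempt a split |
| `min_samples_leaf` | 1 | minimum effective mass per child |
| `keep_probability` | 0.05 | arrival mass below which a training path is dropped |
| `max_depth` | unlimited | maximum splits per path |
| `posthoc_probability` | 0.5 | pmf mass on the nominal label of a post hoc sample |
| `k` | 7 | folds, both CV loops |

`keep_probability` exists purely for tractability: with feature
uncertainty every sample would otherwise reach every node with some
(vanishing) mass. We drop a sample's path into a child when its arrival
mass there falls below the threshold, and we do **not** renormalize the
surviving mass at training time — this keeps the training-side bookkeeping
simple and the conservation law exact whenever pruning is off. At
prediction time pruning is disabled by default (so that leaf arrivals sum
to 1 exactly); a flag restores training-style pruning for speed.

`min_samples_*` are interpreted as effective mass, so at zero feature
uncertainty they reduce to the familiar sample counts. They are searched
only for deterministic baselines; for the probabilistic policy they stay
at their defaults, since mass decay and `keep_probability` already govern
node occupancy there.

Class weights are balanced inverse effective frequencies over soft
labels, $w_c = n / (K\, m_c)$ with $m_c = \sum_i p_i(c)$. The weights
enter both the impurity and the stored node distributions. The study
composition (81 confirmed positive, 29 confirmed stable, 32 uncertain at
$0.5$) gives $m = (45, 97)$ and $w = (1.578, 0.732)$.

## The three label policies

Given a cohort with confirmed and post hoc labels, `apply_policy()`
produces the three training sets compared throughout:

* **exclude** — confirmed samples only (110 of 142 in the default
  synthetic cohort);
* **naive** — all samples, post hoc labels taken at face value;
* **probabilistic** — all samples, post hoc pmfs set to
  $(p, 1-p)$ with $p$ the mass on the nominal ("stable") label.

Confirmed samples are never altered, and `probabilistic(1.0)` is
bit-for-bit the naive policy — a property the acceptance suite asserts on
a full nested-CV report.

## Evaluation protocol

Performance is estimated with nested stratified 7-fold cross-validation:
the outer loop measures generalization, the inner loop (a second
stratified 7-fold split of each outer training set) selects
hyperparameters by mean validation F1 (ties: higher mean AUC, then fewer
trees, then grid order). Stratification uses the nominal labels — the
labels exist before any policy makes them probabilistic — and the fold
plan is built once per run and shared by all policies, so the comparison
is paired: every policy sees the same test subjects in every fold, and
fits are seeded by fold and candidate identity, never by policy.

Test metrics are computed on **confirmed test samples only**; post hoc
samples never enter a confusion count. Precision, recall and F1 are
reported as percentages; a fold with TP = 0 but errors present reports
F1 = 0 with an explicit undefined flag rather than silently. The ROC is
swept over distinct scores and integrated by the trapezoidal rule, which
equals the Mann–Whitney concordance probability (ties at ½) — the suite
checks the two computations against each other to $10^{-12}$. Reported
AUC is the mean of per-fold AUCs; the vertically averaged curve on a
101-point FPR grid is provided for plotting only. The inner loop also
evaluates on confirmed validation samples only, for consistency with the
outer loop.

## The synthetic cohort generator

The original trial data are access-restricted, so the package ships a
seeded generator emulating their structure: 142 subjects — 81 confirmed
positive ("new disease activity"), 29 confirmed stable, and 32 post hoc
"stable" labels whose latent truth is Bernoulli(0.5). Volumes are
log-normal (strictly positive and right-skewed, like real lesion
volumes): the stable-class lesion-volume median matches the published
cohort median (1675.15 mm³) with a log-sd of 1.213 derived from the
published quartiles, and the eight DGM medians are plausible adult
values with ~10% inter-subject spread. Class-conditional shifts are
standardized effects on the log scale: strongest for the thalami (−0.8)
and lesion volume (+0.9), weaker (−0.15 to −0.25) for the other DGM
nuclei, mirroring the field's consistent finding that thalamic volume
and lesion burden carry most of the prognostic signal. The treatment arm
is an independent Bernoulli(0.5) flag with no effect on outcome.

Only pooled summaries of the real cohort are published, so the effect
sizes are calibration knobs, not estimates. They were set once so that a
random forest trained on the *latent* (oracle) labels achieves a mean
7-fold AUC of ≈ 0.79 over ten seeds — inside the 0.75–0.85 band that
keeps the policy comparison in the difficulty regime of the original
study — and were not revisited afterwards.

What a green test does establish: the implementation's exact reductions,
conservation laws and protocol correctness, and — across ten seeds — the
recall advantage of probabilistic labels over naive ones under a
truthfully specified 50% contamination of the post hoc stratum. What the
tests deliberately record as an open red: at 50% contamination the
*ranking* (AUC) ordering between the probabilistic and naive policies is
at chance on this generator (paired differences within ±0.035), even
though it becomes decisive when the contamination rate rises — naive
training mislabels degrade the decision threshold far more than the
ranking. And no synthetic test establishes the original study's numeric
results, which depend on a private dataset with feature correlations,
site effects and dropout mechanisms the generator does not simulate.

## Numerical and design choices

* Gaussian crossing probabilities use the exact normal tail (`pnorm`),
  not an approximation; `dx = 0` short-circuits to the step function.
* Impurity-improvement and purity checks use an absolute epsilon of
  $10^{-12}$.
* Candidate thresholds come from samples with arrival mass at least
  `keep_probability`; the cost itself is computed over all samples at
  the node, and pruning applies only when children are materialized.
* Hard classification thresholds the positive-class probability at 0.5
  (configurable); an exact tie predicts the lower class index
  ("stable"), the conservative choice for a screening metric.
* Whether the original analysis applied class weights inside the PRF
  impurity or only to the baselines is not stated in the source; this
  implementation applies the same balanced weights to both engines,
  which keeps the paired comparison interpretable.
* The confirmed-subgroup prevalence is derived from counts (81/110 =
  73.6%) rather than hard-coding any published rounding of it.
* All randomness flows from a single user seed through explicit
  derivation; identical seeds give bit-identical models, fold plans and
  reports. Derived seeds stay below $2^{31}$.

## Limitations

Binary features cannot carry feature uncertainty (their `dx` must be 0).
The engine is binary-or-multiclass in its containers but the shipped
policies, generator and evaluation target the two-class setting. There
is no significance testing between policies, no calibration analysis,
and no support for regression targets or non-Gaussian feature error
models. With `keep_probability = 0` and nonzero feature uncertainty,
training cost grows quickly with depth (every sample reaches every
node); bound `max_depth` in that regime.
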