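---
title: "Predicting multi-class chemoradiotherapy response from gene expression"
author: "crtpredict developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting multi-class chemoradiotherapy response from gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtpredict)
```

## The problem

Locally advanced rectal cancer is commonly treated with preoperative
chemoradiotherapy (CRT), but histopathologic response varies widely between
patients. Response is graded on the Dworak tumor-regression scale: grade 1
(minimal regression, MI), grade 2 (moderate, MO), grade 3 (near total, NT),
grade 4 (total regression, TO). A patient predicted to respond completely
(TO) and a patient predicted to barely respond (MI) warrant different
treatment decisions, so the clinically useful question is *multi-class*:
will this patient be a total, intermediate, or minimal responder?

`crtpredict` implements a full analysis pipeline for this question, driven by
a pre-treatment gene-expression matrix (RMA-style log2 intensities, genes ×
samples) and per-sample Dworak grades. The modeled cohort design has 77
samples with grade counts (10 MI, 36 MO, 13 NT, 18 TO). Because no such
patient matrix is publicly deposited, the package ships a synthetic-cohort
generator that emulates this design, and every stage of the pipeline is
validated against it.

## Feature scores

Each of the two one-vs-rest contrasts (TO vs rest, MI vs rest) produces, per
gene $i$, a two-sided Welch $t$-test p-value $p_i$ and an effect size $d_i$,
defined here as the difference of group means on the log2 scale (target minus
rest). Three feature scores rank genes:

$$
FS_i = \begin{cases}
-\log_{10}(p_i) & \text{pval} \\
\operatorname{rank}(-\log_{10} p_i)\times\operatorname{rank}(|d_i|) & \text{rank} \\
\operatorname{norm}(-\log_{10} p_i)\times\operatorname{norm}(|d_i|) & \text{norm}
\end{cases}
\qquad
\operatorname{norm}(x_i) = \frac{x_i - \min(x)}{\max(x) - \min(x)}.
$$

The `pval` score orders genes purely by significance. The product scores
deliberately promote genes whose p-value is modest but whose effect size is
large — on a volcano plot, the selected set spreads outward along the
effect-size axis instead of clustering at the significance apex:

```{r fs-example}
tab <- compute_feature_table(
  generate_cohort(synthetic_spec(seed = 1, n_genes = 500,
                                 delta_to = 2, delta_mi = 2))$cohort,
  binary_contrast("TO"))
head(tab[order(-tab$fs_norm), ], 3)
```

Numerical choices worth knowing:

* **Effect-size sign.** The score products use $|d_i|$ so that strong
  down-regulation is rewarded symmetrically with up-regulation; the signed
  $d_i$ is kept in the table for volcano-style output.
* **Ranks** are ascending with average ties, so the jointly most extreme
  gene has the largest rank product.
* **p-value clamping** at $10^{-300}$ before the log avoids infinities.
* **Degenerate inputs**: an all-equal vector min-max-normalizes to all zeros
  (rather than erroring, so a degenerate column cannot abort a grid run),
  and a zero-variance/equal-means Welch comparison returns $t = 0, p = 1$ —
  an uninformative gene ranks last instead of crashing.
* **Top-k ties** are broken by smaller p-value, then lexicographic gene ID,
  making selections deterministic.

## Classifier bank and model selection

Seven binary classifiers compete in a grid over feature-score type × feature
count × algorithm: linear SVM, random forest, elastic-net logistic
regression, LDA, and kNN with $k = 1, 3, 5$. None of their hyperparameters
is dictated by the underlying study design, so the package fixes
conventional defaults (all config-exposed):

| algorithm | default | rationale |
|---|---|---|
| `svm` | linear kernel, $C = 1$, exact dual QP | standard and stable when $d \gg n$ |
| `rf` | 500 trees, $\text{mtry}=\lfloor\sqrt d\rfloor$, gini, grown to purity | classic classification forest |
| `en` | $\alpha = 0.5$, $\lambda$ by internal stratified 5-fold CV | penalized logistic regression |
| `lda` | pooled covariance, pseudo-inverse, empirical priors | degrades (rather than fails) under collinearity |
| `knn*` | Euclidean, majority vote | odd $k$ avoids vote ties |

The LDA pseudo-inverse choice is deliberate: with many correlated features
the pooled covariance becomes singular and LDA accuracy collapses — a known
qualitative behaviour of this design that the package preserves as a
diagnostic instead of masking with regularization.

Model selection uses stratified 5-fold cross-validation (fold sizes within
1 overall and within every class — essential when one class has only 10
members) with **pooled** accuracy (total correct held-out predictions /
cohort size), which is unambiguous with unequal fold sizes. Two scoring
modes are exposed:

* `paper` (default): feature scores are computed once on the whole cohort
  before cross-validation. This is the small-sample variant the modeled
  study used, and it is *optimistically biased* — features have seen the
  test folds.
* `nested`: features are re-scored inside every training split; the honest
  estimate.

Both modes ship because the bias itself is part of the method's story; the
acceptance suite checks that `paper` ≥ `nested` on average over null
cohorts. `select_best()` takes the accuracy argmax with deterministic
tie-breaks: smaller feature count first (parsimony), then algorithm priority
`svm > en > rf > lda > knn1 > knn3 > knn5`, then feature-score priority
`pval > norm > rank` (this last tie-break is unspecified upstream and is a
package decision).

## Sequential three-class prediction

The two best binary models compose into a three-class rule: apply the TO
model first; a positive call is labeled TO. Otherwise apply the MI model:
positive ⇒ MI, negative ⇒ MO. NT is absorbed into MO throughout (both
binary contrasts place NT in "rest", and evaluation counts NT as MO) — the
pipeline never attempts a true four-class distinction. The mirror order
(MI first) is available, and `order_agreement()` reports the fraction of
samples labeled identically by both orders; the two orders can differ only
on samples positive under *both* submodels, where TO-first precedence wins
by convention. Agreement is reported as a diagnostic, never asserted — it
is an empirical observation, not a guarantee.

## Cross-platform harmonization

Applying the model to an external dataset from a different array platform
faces two gaps: fewer overlapping genes, and a different intensity scale.
The package mirrors the validation recipe:

1. `match_symbols()` — intersect gene symbols (uppercased, trimmed),
   reference order.
2. `build_quantile_profile()` — $q_r$ = mean over reference samples of each
   sample's $r$-th order statistic on the common genes.
3. `quantile_map()` — per external sample independently, the rank-$r$ gene
   receives $q_r$; ties broken by reference gene order. After mapping,
   every sample carries exactly the multiset $\{q_1,\dots,q_m\}$ and
   within-sample rank order is preserved.
4. `rebuild_on_common()` — each submodel is retrained on the intersection
   of its selected genes with the common set; the default rebuild algorithm
   is the linear SVM for both submodels, reflecting that SVM is the more
   accurate choice at reduced feature counts.

Per-sample (rather than pooled) normalization is a package decision — the
upstream description does not say — chosen because it makes single-patient
prediction well-defined.

## The synthetic world

`generate_cohort()` emulates exactly the stated cohort design: 77 samples
(10/36/13/18), per-gene baselines $\mu_g \sim U(4, 12)$ on the log2 scale,
Gaussian within-gene noise with unit standard deviation, and disjoint planted
gene sets (100 TO-specific, 100 MI-specific) receiving a class-specific mean
shift. Gaussian noise on the log2 scale matches the variance model implicit
in running t-tests on RMA values; the planted effects are mean shifts (not
variance effects) because that is the simplest structure making both
contrasts learnable. The default shift of 1.0 log2 unit is a conventional
"twofold change"; property tests that need a clearly learnable signal use
2.0 (twice the noise sd), stated per test.

A reused `truth` object pins down the planted sets, shifts, *and* per-gene
baselines, so an "independent test cohort" shares gene-level properties with
the training cohort while all noise is redrawn — the synthetic analogue of
profiling a new patient group on the same platform.

`distort_platform()` derives a second-platform dataset: a seeded random
subset of genes (default 60%) and an affine intensity map $y = 0.8x + 1.5$
plus Gaussian noise (sd 0.2). It deliberately does **not** emulate
probe-level artifacts, batch effects, or non-monotone distortions; a green
harmonization test establishes that the pipeline inverts affine-plus-noise
scale differences on a reduced gene set, nothing stronger. Likewise, green
grid tests establish that the machinery finds planted mean-shift signal —
they say nothing about how much signal real rectal-cancer cohorts contain.

## Evaluation

`confusion_matrix3()` tallies predicted × true counts over {MI, MO, TO}
(NT counted as MO). Headline metrics are per-class sensitivity
($100 \cdot \mathrm{diag}_c / \mathrm{coltotal}_c$) and overall accuracy
($100 \cdot \mathrm{trace} / \mathrm{total}$), reported to one decimal with
half-up rounding; specificity and precision are included in the extended
report. Where a published presentation's own rounding is internally
inconsistent with its printed matrix (e.g. 13/15 printed as 86.6), the
package reports the value computed from the matrix — it does not
reverse-engineer anyone's rounding.

## Known limitations

* Probe-to-gene summarization and RMA preprocessing are upstream: the
  pipeline consumes gene-level matrices only.
* The classifier hyperparameters are conventions, not tuned values.
* The synthetic generator's distributional defaults are conventions; the
  modeled study published no distributional description of its data, so no
  synthetic result can be read as a reproduction of its numeric accuracies.
* Multiple-testing correction is intentionally absent: the scores drive
  ranking, not significance claims.
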