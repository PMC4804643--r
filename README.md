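# crtpredict

Multi-class prediction of tumor response to preoperative chemoradiotherapy
(CRT) from pre-treatment gene-expression profiles.

## What problem this solves

Rectal-cancer patients receiving preoperative CRT respond very differently:
on the Dworak tumor-regression scale some show total regression (TO, grade
4), some minimal regression (MI, grade 1), most something in between (MO
grade 2 / NT grade 3). Knowing the likely response *before* treatment would
let clinicians send predicted non-responders straight to surgery and spare
them ineffective therapy. `crtpredict` is for computational biologists who
want to build and evaluate such a predictor from a genes × samples matrix of
RMA-style log2 expression intensities plus per-sample Dworak grades.

## The method

1. **Feature scores.** For each one-vs-rest contrast (TO-vs-rest,
   MI-vs-rest) every gene gets a Welch t-test p-value `p_i` and a log2
   mean-difference effect size `d_i`, combined three ways:

   ```
   FS_i =  -log10(p_i)                                   ("pval")
           rank(-log10 p_i) * rank(|d_i|)                ("rank")
           norm(-log10 p_i) * norm(|d_i|)                ("norm")
   norm(x_i) = (x_i - min x) / (max x - min x)
   ```

   The product scores promote genes with modest p-values but large effect
   sizes over genes that are merely significant.

2. **Classifier grid.** Seven algorithms (linear SVM, random forest,
   elastic net, LDA, kNN with k = 1/3/5) are trained on the top-k genes for
   every combination of score type and feature count, and scored by
   stratified 5-fold cross-validation (pooled accuracy). The default
   `"paper"` scoring mode computes feature scores once on the whole cohort
   (the optimistic small-sample variant); `"nested"` re-scores within each
   training fold.

3. **Sequential three-class rule.** The best TO model is applied first: a
   positive call is TO. Otherwise the best MI model decides MI vs MO (with
   NT absorbed into MO).

4. **Cross-platform validation.** For an external dataset on another
   platform: match HGNC symbols, quantile-normalize the common genes onto
   the reference profile (each rank-r value replaced by the reference's
   mean r-th order statistic), and retrain the submodels on the
   platform-common subset of their signatures.

5. **Evaluation.** 3×3 confusion matrix (predicted × true over
   {MI, MO, TO}), per-class sensitivity, and overall accuracy.

Because no patient matrix of this design is publicly deposited, the package
includes a seeded synthetic-cohort generator (77 samples; 10 MI / 36 MO /
13 NT / 18 TO; planted class-specific expression shifts; a derived
"second platform" with fewer genes and an affine intensity distortion) that
makes every stage testable end to end.

## Worked example

```r
library(crtpredict)

# a training cohort with clearly learnable planted signal (delta = 2 x sd)
sim <- generate_cohort(synthetic_spec(seed = 7, n_genes = 500,
                                      n_planted_to = 50, n_planted_mi = 50,
                                      delta_to = 2, delta_mi = 2))
sim$cohort
#> <crt_cohort> 500 genes x 77 samples
#> MI MO NT TO
#> 10 36 13 18

tab <- compute_feature_table(sim$cohort, binary_contrast("TO"))
head(tab[order(-tab$fs_norm), c("gene","p","d","fs_pval","fs_rank","fs_norm")], 3)
#>         gene        p    d fs_pval fs_rank fs_norm
#> 454 SYNG0454 5.98e-14 2.53    13.2  249001   0.873
#> 456 SYNG0456 5.75e-15 2.28    14.2  247000   0.849
#> 476 SYNG0476 9.68e-13 2.69    12.0  249000   0.844

# cross-validated model selection (reduced grid for the example)
spec <- grid_spec(fs_types = "norm", feature_counts = c(10L, 20L, 30L),
                  algorithms = c("svm", "en", "knn3"), seed = 7)
res_to <- run_grid(sim$cohort, binary_contrast("TO"), spec)
res_to
#> <crt_grid_result> 9 cells; best: norm k=10 svm (acc 1.000)
res_mi <- run_grid(sim$cohort, binary_contrast("MI"), spec)

# sequential three-class model from the two best submodels
model <- sequential_model(
  train_binary(sim$cohort, binary_contrast("TO"),
               select_top_k(tab, res_to$best$fs_type, res_to$best$k),
               res_to$best$algorithm, seed = 7),
  train_binary(sim$cohort, binary_contrast("MI"),
               select_top_k(compute_feature_table(sim$cohort,
                                                  binary_contrast("MI")),
                            res_mi$best$fs_type, res_mi$best$k),
               res_mi$best$algorithm, seed = 7))

# an independent test cohort sharing the planted truth (same "platform")
test <- generate_cohort(synthetic_spec(seed = 8, n_genes = 500,
                                       n_planted_to = 50, n_planted_mi = 50,
                                       delta_to = 2, delta_mi = 2),
                        truth = sim$truth)
cm <- confusion_matrix3(predict_sequential(model, test$cohort$expression),
                        test$cohort$labels)
cm
#> Confusion matrix (rows = predicted, cols = true; NT counted as MO)
#>          true
#> predicted MI MO TO
#>        MI 10  0  0
#>        MO  0 49  0
#>        TO  0  0 18
overall_accuracy(cm)
#> [1] 100
order_agreement(model, test$cohort$expression)$agreement
#> [1] 1
```

The 49 in the true-MO column is 36 MO plus 13 NT: the package never
predicts NT; it evaluates the three clinically actionable classes. On this
strong-signal synthetic cohort the pipeline is perfect; real cohorts carry
far weaker signal — see the vignette (`vignettes/crt-response-prediction.Rmd`)
for what the synthetic world does and does not establish.

## Command line

An installed `exec/crtpredict` script exposes the pipeline as subcommands
(`simulate`, `score`, `train`, `predict`, `select`, `predict-multiclass`,
`harmonize`, `rebuild`, `evaluate`), e.g.

```sh
crtpredict simulate --seed 1 --expr expr.tsv --labels labels.tsv --truth truth.tsv
crtpredict score --expr expr.tsv --labels labels.tsv --target TO --out scores.tsv
```

All file formats are plain TSV; trained models are versioned JSON.

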