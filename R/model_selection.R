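#' Specification of the model-selection grid
#'
#' The grid spans feature-score type x feature count x algorithm for one
#' binary contrast, evaluated by stratified k-fold cross-validation.
#'
#' @param fs_types subset of `c("pval", "rank", "norm")`.
#' @param feature_counts ordered positive integers (default 2:100, which
#'   covers the best counts reported for this design, 65 and 98).
#' @param algorithms subset of [ALGORITHMS].
#' @param n_folds folds (default 5).
#' @param seed integer; fixes the fold assignment and all stochastic fits.
#' @param scoring_mode `"paper"` scores features once on the whole cohort
#'   before cross-validation (the optimistic variant used when samples are
#'   scarce); `"nested"` recomputes feature scores inside each training split.
#' @return a `crt_grid_spec` list.
#' @export
grid_spec <- function(fs_types = FS_TYPES, feature_counts = 2:100,
                      algorithms = ALGORITHMS, n_folds = 5L, seed = 1L,
                      scoring_mode = c("paper", "nested")) {
  scoring_mode <- match.arg(scoring_mode)
  fs_types <- match.arg(fs_types, FS_TYPES, several.ok = TRUE)
  if (!all(algorithms %in% ALGORITHMS))
    abort_algorithm("unknown algorithm in grid spec")
  if (n_folds < 2L) abort_spec("n_folds must be >= 2")
  if (any(feature_counts < 1L)) abort_spec("feature_counts must be positive")
  structure(list(fs_types = fs_types,
                 feature_counts = as.integer(feature_counts),
                 algorithms = algorithms, n_folds = as.integer(n_folds),
                 seed = as.integer(seed), scoring_mode = scoring_mode),
            class = "crt_grid_spec")
}

#' Stratified fold assignment
#'
#' Deterministic given the seed. Fold sizes differ by at most 1 overall and by
#' at most 1 within every class.
#'
#' @param labels factor (binary in the grid, but any factor works).
#' @param n_folds number of folds.
#' @param seed integer seed.
#' @return integer vector of fold IDs (1..n_folds) per sample.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  counts <- table(labels)
  if (any(counts < n_folds))
    abort_fold(sprintf("class '%s' has %d members, fewer than %d folds",
                       names(counts)[which.min(counts)], min(counts), n_folds))
  fold <- integer(length(labels))
  totals <- integer(n_folds)
  withr::with_seed(seed, {
    # process classes largest-first; each class gives every fold its base
    # share and the remainder goes to the currently smallest folds (ties by
    # fold index), which keeps overall fold sizes within 1 of each other
    for (cls in names(sort(counts, decreasing = TRUE))) {
      members <- sample(which(labels == cls))
      nc <- length(members)
      per <- rep(nc %/% n_folds, n_folds)
      extra <- nc %% n_folds
      if (extra > 0L) {
        take <- order(totals, seq_len(n_folds))[seq_len(extra)]
        per[take] <- per[take] + 1L
      }
      fold[members] <- rep(seq_len(n_folds), times = per)
      totals <- totals + per
    }
  })
  fold
}

#' Cross-validated accuracy of one grid cell
#'
#' In `"paper"` mode the feature table is computed once on the full cohort and
#' the same top-k gene list is used inside every fold; in `"nested"` mode the
#' table and selection are recomputed on each training split. Accuracy is
#' pooled: total correct held-out predictions / cohort size, so every sample
#' is predicted exactly once.
#'
#' @param cohort a `crt_cohort`.
#' @param contrast a [binary_contrast()].
#' @param fs_type,k,algorithm the grid cell.
#' @param n_folds,seed CV controls.
#' @param scoring_mode `"paper"` or `"nested"`.
#' @param folds optional precomputed fold assignment (shared across cells in
#'   [run_grid()]).
#' @return accuracy in \[0, 1\].
#' @export
cv_accuracy <- function(cohort, contrast, fs_type, k, algorithm,
                        n_folds = 5L, seed = 1L,
                        scoring_mode = c("paper", "nested"), folds = NULL) {
  scoring_mode <- match.arg(scoring_mode)
  y <- ifelse(cohort$labels == contrast$target_class,
              contrast$target_class, "other")
  if (is.null(folds))
    folds <- stratified_folds(factor(y), n_folds = n_folds, seed = seed)
  feats_full <- if (scoring_mode == "paper")
    select_top_k(compute_feature_table(cohort, contrast), fs_type, k)
  correct <- 0L
  for (f in sort(unique(folds))) {
    train <- subset_cohort(cohort, which(folds != f))
    test_idx <- which(folds == f)
    feats <- if (scoring_mode == "paper") feats_full
             else select_top_k(compute_feature_table(train, contrast), fs_type, k)
    model <- train_binary(train, contrast, feats, algorithm, seed = seed,
                          fs_type = fs_type)
    pred <- predict_binary(model, cohort$expression[, test_idx, drop = FALSE])
    correct <- correct + sum(pred == y[test_idx])
  }
  correct / length(y)
}

#' Run the cross-validated model-selection grid
#'
#' One fold assignment per (contrast, seed) is shared by every cell. Returns
#' per-cell accuracies, the per-(fs_type, algorithm) mean accuracy across
#' feature counts (the "average accuracy" summary), and the selected best
#' cell.
#'
#' @param cohort a `crt_cohort`.
#' @param contrast a [binary_contrast()].
#' @param spec a [grid_spec()].
#' @param verbose print progress per fs_type/algorithm block.
#' @return a `crt_grid_result`: list with `cells` (data.frame contrast,
#'   fs_type, k, algorithm, accuracy), `mean_accuracy` (data.frame), `best`.
#' @export
run_grid <- function(cohort, contrast, spec, verbose = FALSE) {
  stopifnot(inherits(spec, "crt_grid_spec"))
  if (max(spec$feature_counts) > nrow(cohort$expression))
    abort_spec("feature_counts exceed the number of genes")
  y <- ifelse(cohort$labels == contrast$target_class,
              contrast$target_class, "other")
  folds <- stratified_folds(factor(y), n_folds = spec$n_folds, seed = spec$seed)

  cells <- expand.grid(fs_type = spec$fs_types, k = spec$feature_counts,
                       algorithm = spec$algorithms,
                       stringsAsFactors = FALSE)
  cells$contrast <- contrast$contrast_name
  cells <- cells[, c("contrast", "fs_type", "k", "algorithm")]
  cells$accuracy <- NA_real_
  for (fs in spec$fs_types) {
    for (alg in spec$algorithms) {
      rows <- which(cells$fs_type == fs & cells$algorithm == alg)
      for (r in rows) {
        cells$accuracy[r] <- cv_accuracy(
          cohort, contrast, fs, cells$k[r], alg,
          n_folds = spec$n_folds, seed = spec$seed,
          scoring_mode = spec$scoring_mode, folds = folds)
      }
      if (verbose)
        message(sprintf("%s | %s | %s: mean acc %.3f",
                        contrast$contrast_name, fs, alg,
                        mean(cells$accuracy[rows])))
    }
  }
  mean_acc <- aggregate(accuracy ~ fs_type + algorithm, data = cells, FUN = mean)
  names(mean_acc)[names(mean_acc) == "accuracy"] <- "mean_accuracy"
  res <- structure(list(cells = cells, mean_accuracy = mean_acc, best = NULL),
                   class = "crt_grid_result")
  res$best <- select_best(res)
  res
}

#' Select the best grid cell
#'
#' Argmax of cross-validated accuracy; ties are broken by smaller feature
#' count, then by algorithm priority
#' `svm > en > rf > lda > knn1 > knn3 > knn5`, then by feature-score type
#' (`pval > norm > rank`).
#'
#' @param result a `crt_grid_result` (or its `cells` data.frame).
#' @return list with `fs_type`, `k`, `algorithm`, `accuracy`.
#' @export
select_best <- function(result) {
  cells <- if (inherits(result, "crt_grid_result")) result$cells else result
  if (is.null(cells) || nrow(cells) == 0L)
    abort_selection("empty grid result")
  alg_priority <- c("svm", "en", "rf", "lda", "knn1", "knn3", "knn5")
  fs_priority <- c("pval", "norm", "rank")
  ord <- order(-cells$accuracy, cells$k,
               match(cells$algorithm, alg_priority),
               match(cells$fs_type, fs_priority))
  top <- cells[ord[1L], ]
  list(fs_type = top$fs_type, k = as.integer(top$k),
       algorithm = top$algorithm, accuracy = top$accuracy)
}

#' @export
print.crt_grid_result <- function(x, ...) {
  cat(sprintf("<crt_grid_result> %d cells; best: %s k=%d %s (acc %.3f)\n",
              nrow(x$cells), x$best$fs_type, x$best$k, x$best$algorithm,
              x$best$accuracy))
  invisible(x)
}
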