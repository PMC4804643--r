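test_that("stratified folds balance sizes overall and per class", {
  y <- factor(rep(c("TO", "other"), c(18, 59)))
  f <- stratified_folds(y, n_folds = 5, seed = 1)
  expect_equal(sort(as.vector(table(f))), c(15L, 15L, 15L, 16L, 16L))
  per_fold_to <- table(f[y == "TO"])
  expect_true(all(per_fold_to %in% 3:4))

  # exact divisibility: 10 positives over 5 folds -> exactly 2 each
  y2 <- factor(rep(c("MI", "other"), c(10, 40)))
  f2 <- stratified_folds(y2, n_folds = 5, seed = 2)
  expect_true(all(table(f2[y2 == "MI"]) == 2L))

  expect_error(stratified_folds(factor(rep(c("a", "b"), c(4, 40))), 5),
               class = "crt_fold_error")
  expect_identical(stratified_folds(y, 5, seed = 7),
                   stratified_folds(y, 5, seed = 7))
})

test_that("a perfectly informative feature yields CV accuracy 1", {
  withr::with_seed(21, {
    labels <- dworak_labels(sprintf("S%02d", 1:40),
                            rep(c("TO", "MO"), each = 20))
    oracle <- ifelse(labels == "TO", 1, 0) + rnorm(40, sd = 0.01)
    noise <- matrix(rnorm(40 * 9), nrow = 9)
    expr <- expression_matrix(rbind(oracle, noise),
                              gene_ids = paste0("G", 1:10),
                              sample_ids = names(labels))
    cohort <- bind_cohort(expr, labels)
  })
  for (alg in c("svm", "knn3")) {
    acc <- cv_accuracy(cohort, binary_contrast("TO"), "pval", 1, alg,
                       n_folds = 5, seed = 1)
    expect_equal(acc, 1, label = alg)
  }
})

test_that("pure-noise cohorts hover near the majority-class baseline", {
  accs <- vapply(1:3, function(s) {
    sim <- generate_cohort(synthetic_spec(seed = s, n_genes = 300,
                                          delta_to = 0, delta_mi = 0))
    cv_accuracy(sim$cohort, binary_contrast("TO"), "pval", 10, "svm",
                seed = s)
  }, numeric(1))
  # majority rate is 59/77 = 0.766; allow generous Monte-Carlo slack
  expect_gt(mean(accs), 0.55)
  expect_lt(mean(accs), 0.95)
})

test_that("run_grid enumerates cells, averages, and is reproducible", {
  sim <- strong_cohort(6, n_genes = 120)
  spec <- grid_spec(fs_types = "norm", feature_counts = c(5, 10),
                    algorithms = c("svm", "knn3"), seed = 2)
  res <- run_grid(sim$cohort, binary_contrast("TO"), spec)
  expect_equal(nrow(res$cells), 4L)
  expect_true(all(res$cells$accuracy >= 0 & res$cells$accuracy <= 1))

  # mean_accuracy is the arithmetic mean over feature counts
  svm_cells <- res$cells$accuracy[res$cells$algorithm == "svm"]
  expect_equal(
    res$mean_accuracy$mean_accuracy[res$mean_accuracy$algorithm == "svm"],
    mean(svm_cells))

  res2 <- run_grid(sim$cohort, binary_contrast("TO"), spec)
  expect_identical(res$cells, res2$cells)
})

test_that("select_best applies argmax with parsimony and priority tie-breaks", {
  cells <- data.frame(
    contrast = "TO-vs-rest",
    fs_type = c("pval", "norm"),
    k = c(10L, 5L),
    algorithm = c("svm", "rf"),
    accuracy = c(0.90, 0.95))
  expect_equal(select_best(cells)[c("fs_type", "k", "algorithm")],
               list(fs_type = "norm", k = 5L, algorithm = "rf"))

  tie_k <- data.frame(contrast = "x", fs_type = "pval", k = c(50L, 5L),
                      algorithm = "svm", accuracy = 0.95)
  expect_equal(select_best(tie_k)$k, 5L)

  tie_alg <- data.frame(contrast = "x", fs_type = "pval", k = 5L,
                        algorithm = c("rf", "svm"), accuracy = 0.95)
  expect_equal(select_best(tie_alg)$algorithm, "svm")

  expect_error(select_best(cells[0, ]), class = "crt_selection_error")
})

test_that("every sample is predicted exactly once per cv_accuracy call", {
  # pooled accuracy over a cohort of n samples is a multiple of 1/n
  sim <- strong_cohort(8, n_genes = 100)
  acc <- cv_accuracy(sim$cohort, binary_contrast("MI"), "pval", 5, "knn1",
                     seed = 3)
  expect_equal(acc * 77, round(acc * 77), tolerance = 1e-9)
})

test_that("accuracy is non-decreasing in the planted effect size", {
  mean_acc <- function(delta) {
    mean(vapply(1:3, function(s) {
      sim <- generate_cohort(synthetic_spec(seed = s, n_genes = 300,
                                            delta_to = delta, delta_mi = delta))
      cv_accuracy(sim$cohort, binary_contrast("TO"), "norm", 10, "svm",
                  seed = s)
    }, numeric(1)))
  }
  a0 <- mean_acc(0); a1 <- mean_acc(1); a2 <- mean_acc(2)
  expect_lte(a0, a1 + 0.05)  # small slack: stochastic at 3 seeds
  expect_lte(a1, a2 + 0.05)
  expect_gt(a2, a0)
})
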