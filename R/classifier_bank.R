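#' The seven-algorithm classifier bank
#'
#' Closed set of algorithm identifiers usable in the model-selection grid:
#' linear SVM, random forest, elastic-net logistic regression, pooled-covariance
#' LDA, and k-nearest neighbors with k = 1, 3, 5.
#' @export
ALGORITHMS <- c("svm", "rf", "en", "lda", "knn1", "knn3", "knn5")

# Deterministic hyperparameters (the source study states none):
#   svm  - linear kernel, soft margin C = 1, exact dual QP
#   rf   - 500 trees, mtry = floor(sqrt(d)), gini, grown to purity
#   en   - penalized logistic regression, alpha = 0.5, lambda by internal
#          stratified 5-fold CV on the training split
#   lda  - pooled full covariance, pseudo-inverse (collinearity degrades
#          gracefully instead of erroring), empirical priors
#   knn  - Euclidean distance, majority vote (odd k avoids vote ties)
RF_NTREE <- 500L
SVM_COST <- 1
EN_ALPHA <- 0.5

#' Train a one-vs-rest binary classifier
#'
#' @param cohort a `crt_cohort`.
#' @param contrast a [binary_contrast()]; samples of the target class are the
#'   positive group, all others (including NT) the negative group.
#' @param features character vector of feature genes, all present in cohort.
#' @param algorithm one of [ALGORITHMS].
#' @param seed integer; makes rf bootstraps and the elastic-net internal CV
#'   reproducible.
#' @param fs_type optional record of the feature-score type that produced
#'   `features` (metadata only).
#' @return a `crt_binary_model`.
#' @export
train_binary <- function(cohort, contrast, features, algorithm, seed = 1L,
                         fs_type = NA_character_) {
  if (!(algorithm %in% ALGORITHMS))
    abort_algorithm(sprintf("unknown algorithm '%s' (choose from %s)",
                            algorithm, paste(ALGORITHMS, collapse = ", ")))
  stopifnot(inherits(contrast, "crt_contrast"))
  features <- as.character(features)
  if (length(features) == 0L || anyDuplicated(features))
    abort_feature("features must be a non-empty list of unique genes")
  missing <- setdiff(features, rownames(cohort$expression))
  if (length(missing))
    abort_feature(sprintf("feature gene(s) absent from cohort: %s",
                          paste(missing, collapse = ", ")))
  y <- as.integer(cohort$labels == contrast$target_class)
  if (length(unique(y)) < 2L)
    abort_train("training set contains a single class")
  X <- t(cohort$expression[features, , drop = FALSE])

  state <- withr::with_seed(seed, switch(algorithm,
    svm = fit_svm_linear(X, y),
    rf = fit_rf(X, y, seed),
    en = fit_en(X, y, seed),
    lda = fit_lda(X, y),
    knn1 = fit_knn(X, y, 1L),
    knn3 = fit_knn(X, y, 3L),
    knn5 = fit_knn(X, y, 5L)))

  structure(list(format = "crt_binary_model/1", algorithm = algorithm,
                 feature_genes = features, fs_type = fs_type,
                 contrast = contrast, fitted_state = state,
                 training_seed = as.integer(seed)),
            class = "crt_binary_model")
}

#' Predict target-vs-other labels from a trained binary model
#'
#' @param model a `crt_binary_model`.
#' @param expr expression matrix containing every feature gene of the model.
#' @return character vector per sample, `target_class` or `"other"`, named by
#'   sample ID.
#' @export
predict_binary <- function(model, expr) {
  stopifnot(inherits(model, "crt_binary_model"))
  expr <- expression_matrix(expr)
  missing <- setdiff(model$feature_genes, rownames(expr))
  if (length(missing))
    abort_feature(sprintf("matrix lacks feature gene(s): %s",
                          paste(missing, collapse = ", ")))
  X <- t(expr[model$feature_genes, , drop = FALSE])
  pos <- switch(model$algorithm,
    svm = predict_svm_linear(model$fitted_state, X),
    rf = .rf_predict_cpp(model$fitted_state$forest, X) >= 0.5,
    en = predict_en(model$fitted_state, X),
    lda = predict_lda(model$fitted_state, X),
    knn1 = , knn3 = , knn5 = predict_knn(model$fitted_state, X))
  out <- ifelse(pos, model$contrast$target_class, "other")
  names(out) <- rownames(X)
  out
}

#' @export
print.crt_binary_model <- function(x, ...) {
  cat(sprintf("<crt_binary_model> %s, %s, %d features (fs = %s)\n",
              x$contrast$contrast_name, x$algorithm,
              length(x$feature_genes), x$fs_type))
  invisible(x)
}

## --- individual fitters ----------------------------------------------------

# Exact soft-margin linear SVM via the dual QP:
#   max  1'a - a' (yy' * K) a / 2   s.t.  y'a = 0,  0 <= a <= C
fit_svm_linear <- function(X, y) {
  ys <- ifelse(y == 1L, 1, -1)
  n <- nrow(X)
  K <- tcrossprod(X)
  D <- (ys %o% ys) * K + diag(1e-8, n)  # ridge keeps D positive definite
  A <- cbind(ys, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-SVM_COST, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  a <- pmin(pmax(sol$solution, 0), SVM_COST)
  w <- drop(crossprod(X, a * ys))
  tol <- 1e-6 * SVM_COST
  free <- which(a > tol & a < SVM_COST - tol)
  sv <- if (length(free)) free else which(a > tol)
  b <- mean(ys[sv] - X[sv, , drop = FALSE] %*% w)
  list(type = "svm", w = w, b = b)
}

predict_svm_linear <- function(state, X) {
  drop(X %*% state$w) + state$b > 0
}

fit_rf <- function(X, y, seed) {
  mtry <- max(1L, floor(sqrt(ncol(X))))
  list(type = "rf",
       forest = .rf_fit_cpp(X, as.integer(y), RF_NTREE, mtry, seed))
}

# Elastic-net-penalized logistic regression; lambda by internal stratified CV
# when the training split is large enough, else the midpoint of the path.
fit_en <- function(X, y, seed) {
  Xg <- X
  if (ncol(Xg) < 2L)  # glmnet requires >= 2 columns
    Xg <- cbind(Xg, `.pad` = 0)
  nf <- min(5L, min(table(y)))
  if (nf >= 2L) {
    foldid <- stratified_folds(factor(y), n_folds = nf, seed = seed)
    # small training splits trip glmnet's internal sample-size warnings;
    # they are expected in this regime and not actionable
    cv <- suppressWarnings(
      glmnet::cv.glmnet(Xg, y, family = "binomial", alpha = EN_ALPHA,
                        foldid = foldid))
    lam <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    fit <- glmnet::glmnet(Xg, y, family = "binomial", alpha = EN_ALPHA)
    lam <- fit$lambda[ceiling(length(fit$lambda) / 2)]
  }
  beta <- coef(fit, s = lam)
  list(type = "en", intercept = beta[1L],
       beta = as.numeric(beta[-1L])[seq_len(ncol(X))], lambda = lam)
}

predict_en <- function(state, X) {
  drop(X %*% state$beta) + state$intercept > 0
}

# Pooled-covariance linear discriminant with empirical priors; the
# pseudo-inverse lets collinear feature sets degrade rather than fail.
fit_lda <- function(X, y) {
  X1 <- X[y == 1L, , drop = FALSE]
  X0 <- X[y == 0L, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  m1 <- colMeans(X1); m0 <- colMeans(X0)
  S <- (crossprod(sweep(X1, 2, m1)) + crossprod(sweep(X0, 2, m0))) / (n1 + n0 - 2)
  w <- drop(MASS::ginv(S) %*% (m1 - m0))
  list(type = "lda", w = w, mid = (m1 + m0) / 2, logprior = log(n1 / n0))
}

predict_lda <- function(state, X) {
  drop(sweep(X, 2, state$mid) %*% state$w) + state$logprior > 0
}

fit_knn <- function(X, y, k) {
  if (k > nrow(X)) abort_train(sprintf("kNN with k = %d but only %d samples",
                                       k, nrow(X)))
  list(type = "knn", k = k, X = X, y = y)
}

predict_knn <- function(state, X) {
  tr <- state$X
  apply(X, 1L, function(x) {
    d2 <- rowSums(sweep(tr, 2, x)^2)
    nn <- order(d2)[seq_len(state$k)]  # stable order: distance ties by index
    mean(state$y[nn]) >= 0.5
  })
}
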