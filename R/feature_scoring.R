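FS_TYPES <- c("pval", "rank", "norm")

#' Define a one-vs-rest binary contrast
#'
#' The pipeline models two contrasts: total regression vs the rest
#' (`"TO-vs-rest"`) and minimal regression vs the rest (`"MI-vs-rest"`).
#'
#' @param target_class `"TO"` or `"MI"`.
#' @return a `crt_contrast` list with `target_class` and `contrast_name`.
#' @export
binary_contrast <- function(target_class = c("TO", "MI")) {
  target_class <- match.arg(target_class)
  structure(list(target_class = target_class,
                 contrast_name = paste0(target_class, "-vs-rest")),
            class = "crt_contrast")
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both groups have zero variance and equal
#' means the test is degenerate and returns `t = 0, p = 1` (an uninformative
#' gene must rank last, not crash).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    abort_stat("welch_t needs >= 2 observations per group")
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  if (se2 == 0) {
    if (mean(x) != mean(y))
      abort_stat("zero within-group variance with unequal means")
    return(list(t = 0, df = nx + ny - 2, p = 1))
  }
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Row-wise Welch test of X[, idx1] vs X[, idx2]; returns p and the signed
# log2 mean difference d (group 1 minus group 2). Vectorized for grid runs.
welch_t_rows <- function(X, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(X[, idx1, drop = FALSE])
  m2 <- rowMeans(X[, idx2, drop = FALSE])
  v1 <- rowSums((X[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((X[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  d <- m1 - m2
  t <- ifelse(se2 > 0, d / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
               n1 + n2 - 2)
  p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), 1)
  list(p = p, d = d)
}

#' Min-max normalization to the unit interval
#'
#' `norm(x_i) = (x_i - min(x)) / (max(x) - min(x))`; an all-equal vector maps
#' to all zeros so a degenerate score column does not abort a grid run.
#'
#' @param x numeric vector, finite, length >= 1.
#' @return vector in \[0, 1\].
#' @export
minmax_norm <- function(x) {
  if (length(x) < 1L || any(!is.finite(x)))
    abort_stat("minmax_norm needs a non-empty finite vector")
  r <- max(x) - min(x)
  if (r == 0) return(rep(0, length(x)))
  (x - min(x)) / r
}

#' Per-gene differential statistics and the three feature scores
#'
#' For each gene, computes the two-sided Welch p-value `p` and signed log2
#' mean difference `d` (target minus rest) for the given one-vs-rest
#' contrast, then the three feature scores:
#' \itemize{
#'   \item `fs_pval = -log10(p)`
#'   \item `fs_rank = rank(-log10 p) * rank(|d|)` (ascending ranks, average ties)
#'   \item `fs_norm = norm(-log10 p) * norm(|d|)` (min-max normalization)
#' }
#' p-values are clamped below at 1e-300 before the log to avoid infinities.
#'
#' @param cohort a `crt_cohort`.
#' @param contrast a [binary_contrast()].
#' @return data.frame (class `crt_feature_table`) with columns
#'   `gene, p, d, abs_d, fs_pval, fs_rank, fs_norm`.
#' @export
compute_feature_table <- function(cohort, contrast) {
  stopifnot(inherits(contrast, "crt_contrast"))
  tgt <- which(cohort$labels == contrast$target_class)
  rest <- which(cohort$labels != contrast$target_class)
  if (length(tgt) < 2L || length(rest) < 2L)
    abort_stat(sprintf("contrast %s needs >= 2 samples in each group",
                       contrast$contrast_name))
  wt <- welch_t_rows(cohort$expression, tgt, rest)
  feature_table(rownames(cohort$expression), wt$p, wt$d)
}

# Assemble a feature table from per-gene (p, d); shared by compute and tests.
feature_table <- function(gene, p, d) {
  fs_pval <- -log10(pmax(p, 1e-300))
  abs_d <- abs(d)
  fs_rank <- rank(fs_pval, ties.method = "average") *
    rank(abs_d, ties.method = "average")
  fs_norm <- minmax_norm(fs_pval) * minmax_norm(abs_d)
  structure(data.frame(gene = gene, p = p, d = d, abs_d = abs_d,
                       fs_pval = fs_pval, fs_rank = fs_rank, fs_norm = fs_norm,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("crt_feature_table", "data.frame"))
}

#' Select the top-k genes by a feature score
#'
#' Genes are ordered by descending score; ties are broken by smaller p-value,
#' then lexicographic gene ID.
#'
#' @param table a `crt_feature_table`.
#' @param fs_type one of `"pval"`, `"rank"`, `"norm"`.
#' @param k number of genes, `1 <= k <= nrow(table)`.
#' @return ordered character vector of k gene IDs.
#' @export
select_top_k <- function(table, fs_type = FS_TYPES, k) {
  fs_type <- match.arg(fs_type, FS_TYPES)
  if (k < 1L || k > nrow(table))
    abort_selection(sprintf("k = %d outside [1, %d]", k, nrow(table)))
  score <- table[[paste0("fs_", fs_type)]]
  ord <- order(-score, table$p, table$gene)
  table$gene[ord][seq_len(k)]
}
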