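norm_symbol <- function(x) toupper(trimws(x))

#' Match gene symbols between a reference and an external platform
#'
#' Symbols are compared after uppercasing and whitespace trimming (HGNC-style
#' matching); the intersection is returned in reference order with reference
#' spelling.
#'
#' @param ref_genes reference gene list (order defines output order).
#' @param ext_genes external gene list.
#' @return character vector of common genes.
#' @export
match_symbols <- function(ref_genes, ext_genes) {
  if (!length(ref_genes) || !length(ext_genes))
    abort_match("gene lists must be non-empty")
  common <- ref_genes[norm_symbol(ref_genes) %in% norm_symbol(ext_genes)]
  if (!length(common)) abort_match("no gene symbols in common")
  common
}

#' Build the reference quantile profile over common genes
#'
#' `q_r` is the mean across reference samples of each sample's r-th smallest
#' value on the common genes; an external sample's rank-r gene will later be
#' assigned `q_r`.
#'
#' @param ref reference expression matrix.
#' @param common character vector of common genes (subset of `ref` rows),
#'   length >= 2.
#' @return a `crt_quantile_profile`: list with `m` and sorted vector `q`.
#' @export
build_quantile_profile <- function(ref, common) {
  if (length(common) < 2L) abort_profile("need >= 2 common genes")
  if (!all(common %in% rownames(ref)))
    abort_profile("common genes missing from the reference matrix")
  sub <- ref[common, , drop = FALSE]
  q <- rowMeans(apply(sub, 2L, sort))
  structure(list(m = length(common), q = as.numeric(q)),
            class = "crt_quantile_profile")
}

#' Quantile-normalize an external dataset onto the reference profile
#'
#' Per external sample independently, the gene ranked r among that sample's
#' common-gene values receives the reference value `q_r`. Ties are broken by
#' reference gene order, making the map deterministic. Output is restricted
#' to the common genes (reference spelling, reference order).
#'
#' @param ext external expression matrix.
#' @param profile a [build_quantile_profile()].
#' @param common common gene list used to build the profile.
#' @return harmonized expression matrix, `length(common)` x samples.
#' @export
quantile_map <- function(ext, profile, common) {
  stopifnot(inherits(profile, "crt_quantile_profile"))
  if (length(common) != profile$m)
    abort_profile(sprintf("profile built for %d genes but %d supplied",
                          profile$m, length(common)))
  idx <- match(norm_symbol(common), norm_symbol(rownames(ext)))
  if (anyNA(idx))
    abort_profile(sprintf("external matrix lacks common gene(s): %s",
                          paste(common[is.na(idx)], collapse = ", ")))
  sub <- ext[idx, , drop = FALSE]
  out <- matrix(NA_real_, nrow = profile$m, ncol = ncol(sub),
                dimnames = list(common, colnames(sub)))
  for (j in seq_len(ncol(sub))) {
    ord <- order(sub[, j], seq_len(profile$m))  # ties: reference gene order
    out[ord, j] <- profile$q
  }
  expression_matrix(out)
}

#' Rebuild the sequential model on platform-common genes
#'
#' Each submodel's selected gene list is intersected with the common genes
#' and the submodel is retrained on the reference cohort restricted to that
#' intersection. Used when an external validation platform covers only part
#' of the selected signatures; the rebuild algorithm defaults to the linear
#' SVM for both submodels (more accurate than the elastic net at reduced
#' feature counts).
#'
#' @param cohort reference `crt_cohort` (training data).
#' @param best_to,best_mi the selected feature set for each contrast: either
#'   a character vector of genes, or a list with `fs_type` and `k` which is
#'   re-derived from the cohort's whole-data feature table.
#' @param common common gene list from [match_symbols()].
#' @param rebuild_algorithm_to,rebuild_algorithm_mi algorithms for the
#'   rebuilt submodels (default `"svm"`).
#' @param seed training seed.
#' @return a `crt_sequential_model`; each submodel records its reduced
#'   feature count in `n_common_features`.
#' @export
rebuild_on_common <- function(cohort, best_to, best_mi, common,
                              rebuild_algorithm_to = "svm",
                              rebuild_algorithm_mi = "svm", seed = 1L) {
  rebuild_one <- function(sel, target, algorithm) {
    contrast <- binary_contrast(target)
    genes <- if (is.character(sel)) sel
             else select_top_k(compute_feature_table(cohort, contrast),
                               sel$fs_type, sel$k)
    kept <- genes[norm_symbol(genes) %in% norm_symbol(common)]
    if (!length(kept))
      abort_rebuild(sprintf("no selected %s gene is on the common platform",
                            target))
    m <- train_binary(cohort, contrast, kept, algorithm, seed = seed,
                      fs_type = if (is.list(sel)) sel$fs_type else NA_character_)
    m$n_common_features <- length(kept)
    m$n_selected_features <- length(genes)
    m
  }
  to_m <- rebuild_one(best_to, "TO", rebuild_algorithm_to)
  mi_m <- rebuild_one(best_mi, "MI", rebuild_algorithm_mi)
  sequential_model(to_m, mi_m)
}
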