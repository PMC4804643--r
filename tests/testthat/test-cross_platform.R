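test_that("symbol matching is case-insensitive and reference-ordered", {
  expect_equal(match_symbols(c("TP53", "BRCA1", "EGFR"),
                             c("EGFR", "TP53", "KRAS")),
               c("TP53", "EGFR"))
  expect_equal(match_symbols(c("TP53", "BRCA1"), c(" brca1 ", "kras")),
               "BRCA1")
  expect_error(match_symbols(c("A", "B"), c("C", "D")),
               class = "crt_match_error")
  expect_error(match_symbols(character(0), "A"), class = "crt_match_error")
})

test_that("quantile profile averages per-sample order statistics", {
  # two samples whose sorted common-gene values are (1,3,5) and (2,4,6)
  ref <- expression_matrix(matrix(c(3, 5, 1, 2, 4, 6), 3, 2),
                           gene_ids = c("A", "B", "C"),
                           sample_ids = c("S1", "S2"))
  prof <- build_quantile_profile(ref, c("A", "B", "C"))
  expect_equal(prof$q, c(1.5, 3.5, 5.5))

  single <- build_quantile_profile(ref[, 1, drop = FALSE], c("A", "B", "C"))
  expect_equal(single$q, unname(sort(ref[, 1])))

  const <- expression_matrix(matrix(7, 3, 2), gene_ids = c("A", "B", "C"),
                             sample_ids = c("S1", "S2"))
  expect_equal(build_quantile_profile(const, c("A", "B", "C"))$q, rep(7, 3))

  expect_error(build_quantile_profile(ref, "A"), class = "crt_profile_error")
})

test_that("quantile_map performs deterministic rank replacement", {
  prof <- structure(list(m = 3L, q = c(1.5, 3.5, 5.5)),
                    class = "crt_quantile_profile")
  ext <- expression_matrix(matrix(c(10, 0, 7), 3, 1),
                           gene_ids = c("A", "B", "C"), sample_ids = "E1")
  out <- quantile_map(ext, prof, c("A", "B", "C"))
  expect_equal(as.vector(out), c(5.5, 1.5, 3.5))

  # all-equal sample: ties broken by reference gene order
  flat <- expression_matrix(matrix(2, 3, 1), gene_ids = c("A", "B", "C"),
                            sample_ids = "E1")
  expect_equal(as.vector(quantile_map(flat, prof, c("A", "B", "C"))),
               c(1.5, 3.5, 5.5))

  expect_error(quantile_map(ext, prof, c("A", "B")),
               class = "crt_profile_error")
  expect_error(quantile_map(ext[1:2, , drop = FALSE], prof, c("A", "B", "C")),
               class = "crt_profile_error")
})

test_that("quantile_map is monotone, multiset-exact, and idempotent", {
  sim <- strong_cohort(14, n_genes = 120)
  ref <- sim$cohort$expression
  ext <- distort_platform(ref, platform_distortion_spec(seed = 3))
  common <- match_symbols(rownames(ref), rownames(ext))
  prof <- build_quantile_profile(ref, common)
  mapped <- quantile_map(ext, prof, common)

  for (j in c(1L, 40L, 77L)) {
    # within-sample rank order of common genes is preserved
    expect_equal(order(mapped[, j]), order(ext[common, j], seq_along(common)))
    # every mapped sample carries exactly the profile's value multiset
    expect_equal(unname(sort(mapped[, j])), sort(prof$q), tolerance = 1e-12)
  }
  # mapping an already-mapped dataset changes nothing
  expect_equal(quantile_map(mapped, prof, common), mapped, tolerance = 1e-12)
})

test_that("rebuild_on_common intersects features and retrains", {
  sim <- strong_cohort(15, n_genes = 200)
  tab_to <- compute_feature_table(sim$cohort, binary_contrast("TO"))
  tab_mi <- compute_feature_table(sim$cohort, binary_contrast("MI"))
  f_to <- select_top_k(tab_to, "norm", 20)
  f_mi <- select_top_k(tab_mi, "norm", 20)

  # common list dropping half the TO features
  common <- setdiff(rownames(sim$cohort$expression), f_to[1:10])
  model <- rebuild_on_common(sim$cohort, f_to, f_mi, common)
  expect_equal(model$to_model$n_common_features, 10L)
  expect_setequal(model$to_model$feature_genes, setdiff(f_to, f_to[1:10]))
  expect_equal(model$mi_model$feature_genes, f_mi)  # untouched superset

  # selections can be given as (fs_type, k) and are re-derived
  model2 <- rebuild_on_common(sim$cohort, list(fs_type = "norm", k = 20),
                              list(fs_type = "norm", k = 20), common)
  expect_setequal(model2$to_model$feature_genes, model$to_model$feature_genes)

  expect_error(
    rebuild_on_common(sim$cohort, f_to, f_mi,
                      setdiff(rownames(sim$cohort$expression), f_to)),
    class = "crt_rebuild_error")
})
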