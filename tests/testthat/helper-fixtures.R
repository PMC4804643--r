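# Shared fixtures, all generated in code (no stored data).

# small strong-signal cohort: planted shifts at 2x the noise sd are easily
# learnable, so classifier-level tests stay fast and stable
strong_spec <- function(seed = 1L, n_genes = 400L, delta = 2) {
  planted <- max(4L, n_genes %/% 10L)
  synthetic_spec(seed = seed, n_genes = n_genes,
                 n_planted_to = planted, n_planted_mi = planted,
                 delta_to = delta, delta_mi = delta)
}

strong_cohort <- function(seed = 1L, ...) generate_cohort(strong_spec(seed, ...))

# the 3-gene worked example used throughout the feature-score tests
toy_table <- function() {
  crtpredict:::feature_table(c("g1", "g2", "g3"),
                             p = c(0.01, 0.1, 0.5),
                             d = c(0.5, 2, 1))
}

# linearly separable 2-feature toy: class A near (0,0), class B near (5,5)
separable_toy <- function(seed = 42L) {
  withr::with_seed(seed, {
    n <- 6L
    X <- rbind(matrix(rnorm(2 * n, 0, 0.1), ncol = 2),
               matrix(rnorm(2 * n, 5, 0.1), ncol = 2))
    expr <- expression_matrix(t(X), gene_ids = c("F1", "F2"),
                              sample_ids = sprintf("T%02d", seq_len(2 * n)))
    labels <- dworak_labels(colnames(expr), rep(c("MO", "TO"), each = n))
    bind_cohort(expr, labels)
  })
}

# truth labels collapsed to the three evaluated classes
truth3_of <- function(labels) {
  out <- as.character(labels)
  out[out == "NT"] <- "MO"
  names(out) <- names(labels)
  out
}

write_expr_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
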