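# brute-force evaluation of the Welch formulas, kept independent of the
# implementation path (used as the oracle in the agreement property)
welch_brute <- function(x, y) {
  nx <- length(x); ny <- length(y)
  mx <- sum(x) / nx; my <- sum(y) / ny
  vx <- sum((x - mx)^2) / (nx - 1); vy <- sum((y - my)^2) / (ny - 1)
  t <- (mx - my) / sqrt(vx / nx + vy / ny)
  df <- (vx / nx + vy / ny)^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

test_that("welch_t matches hand-computed values and degenerate rules", {
  res <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.02131164, tolerance = 1e-6)

  same <- welch_t(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  flat <- welch_t(c(5, 5, 5), c(5, 5, 5))
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)

  expect_error(welch_t(1, c(1, 2)), class = "crt_stat_error")
})

test_that("welch_t agrees with the brute-force oracle to 1e-10", {
  withr::with_seed(99, {
    for (i in 1:100) {
      x <- rnorm(sample(2:12, 1), mean = runif(1, -3, 3), sd = runif(1, 0.2, 3))
      y <- rnorm(sample(2:12, 1), mean = runif(1, -3, 3), sd = runif(1, 0.2, 3))
      got <- welch_t(x, y)
      ref <- welch_brute(x, y)
      expect_equal(got$t, ref$t, tolerance = 1e-10)
      expect_equal(got$df, ref$df, tolerance = 1e-10)
      expect_equal(got$p, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("minmax_norm follows the printed formula", {
  expect_equal(minmax_norm(c(0, 5, 10)), c(0, 0.5, 1))
  expect_equal(minmax_norm(c(1, 2, 4)), c(0, 1 / 3, 1))
  expect_equal(minmax_norm(c(3, 3, 3)), c(0, 0, 0))
  expect_error(minmax_norm(c(1, NA)), class = "crt_stat_error")
  withr::with_seed(2, {
    for (i in 1:20) {
      v <- rnorm(sample(2:30, 1))
      out <- minmax_norm(v)
      expect_equal(out[which.min(v)], 0)
      expect_equal(out[which.max(v)], 1)
      expect_true(all(out >= 0 & out <= 1))
    }
  })
})

test_that("the 3-gene worked example reproduces all three scores", {
  tab <- toy_table()
  expect_equal(tab$fs_pval, c(2, 1, -log10(0.5)), tolerance = 1e-12)
  expect_equal(tab$fs_rank, c(3, 6, 2))
  expect_equal(tab$fs_norm, c(0, 0.4114, 0), tolerance = 5e-5)

  # the top gene differs by score: pval favors the smallest p, rank/norm
  # promote the gene with the larger effect size
  expect_equal(select_top_k(tab, "pval", 1), "g1")
  expect_equal(select_top_k(tab, "rank", 1), "g2")
  expect_equal(select_top_k(tab, "norm", 1), "g2")
})

test_that("select_top_k orders, tie-breaks, and bounds k", {
  tab <- toy_table()
  expect_setequal(select_top_k(tab, "rank", 3), tab$gene)
  expect_error(select_top_k(tab, "rank", 4), class = "crt_selection_error")
  expect_error(select_top_k(tab, "rank", 0), class = "crt_selection_error")

  # all-zero norm column: ties broken by smaller p then gene id
  flat <- crtpredict:::feature_table(c("b", "a", "c"),
                                     p = c(0.2, 0.2, 0.1), d = c(1, 1, 1))
  expect_equal(select_top_k(flat, "norm", 3), c("c", "a", "b"))
})

test_that("a p = 1 gene scores zero under pval and norm", {
  tab <- crtpredict:::feature_table(c("g1", "g2"), p = c(1, 0.01), d = c(9, 1))
  expect_equal(tab$fs_pval[1], 0)
  expect_equal(tab$fs_norm[1], 0)
})

test_that("equal effect sizes collapse the three scores to the same ranking", {
  withr::with_seed(31, {
    for (i in 1:10) {
      G <- 30L
      tab <- crtpredict:::feature_table(sprintf("g%02d", 1:G),
                                        p = runif(G), d = rep(1.7, G))
      for (k in c(1L, 5L, 15L)) {
        expect_setequal(select_top_k(tab, "pval", k),
                        select_top_k(tab, "rank", k))
        expect_setequal(select_top_k(tab, "pval", k),
                        select_top_k(tab, "norm", k))
      }
    }
  })
})

test_that("fs_norm is invariant to positive affine rescaling of |d|", {
  withr::with_seed(13, {
    G <- 40L
    p <- runif(G)
    d <- runif(G, 0.1, 4)
    a <- crtpredict:::feature_table(sprintf("g%02d", 1:G), p, d)
    b <- crtpredict:::feature_table(sprintf("g%02d", 1:G), p, 2.5 * d + 7)
    expect_equal(a$fs_norm, b$fs_norm, tolerance = 1e-12)
  })
})

test_that("compute_feature_table requires two samples per group", {
  sim <- strong_cohort(1, n_genes = 50)
  tab <- compute_feature_table(sim$cohort, binary_contrast("TO"))
  expect_equal(nrow(tab), 50L)
  expect_true(all(tab$p > 0 & tab$p <= 1))

  # scalar welch_t and the vectorized row path must agree gene by gene
  to <- sim$cohort$labels == "TO"
  for (g in rownames(sim$cohort$expression)[1:5]) {
    ref <- welch_t(sim$cohort$expression[g, to], sim$cohort$expression[g, !to])
    expect_equal(tab$p[tab$gene == g], ref$p, tolerance = 1e-12)
  }

  tiny <- subset_tiny <- sim$cohort
  tiny$labels[] <- factor(rep(c("MO", "TO"), c(76, 1)),
                          levels = levels(tiny$labels))
  expect_error(compute_feature_table(tiny, binary_contrast("TO")),
               class = "crt_stat_error")
})
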