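#' Specification for a synthetic rectal-cancer cohort
#'
#' Defaults mirror the modeled study cohort: 77 samples with Dworak grade
#' counts (10 MI, 36 MO, 13 NT, 18 TO), log2-scale expression with per-gene
#' baselines drawn from `baseline_mean_range`, Gaussian within-gene noise, and
#' disjoint planted TO-specific and MI-specific differentially expressed gene
#' sets (mean shifts `delta_to` / `delta_mi`).
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (default 2000).
#' @param class_sizes counts for (MI, MO, NT, TO); default `c(10, 36, 13, 18)`.
#' @param baseline_mean_range log2 interval for per-gene baseline means.
#' @param within_gene_sd s.d. of the per-observation Gaussian noise.
#' @param n_planted_to,n_planted_mi sizes of the planted gene sets.
#' @param delta_to,delta_mi log2 mean shift added to the target class for
#'   planted genes.
#' @return a `crt_synthetic_spec` list.
#' @export
synthetic_spec <- function(seed = 1L, n_genes = 2000L,
                           class_sizes = c(MI = 10L, MO = 36L, NT = 13L, TO = 18L),
                           baseline_mean_range = c(4, 12), within_gene_sd = 1,
                           n_planted_to = 100L, delta_to = 1,
                           n_planted_mi = 100L, delta_mi = 1) {
  class_sizes <- as.integer(class_sizes)
  if (length(class_sizes) != 4L || any(class_sizes <= 0L))
    abort_spec("class_sizes must be four positive counts (MI, MO, NT, TO)")
  names(class_sizes) <- DWORAK_CLASSES
  if (n_planted_to + n_planted_mi > n_genes)
    abort_spec("planted TO and MI gene sets cannot be disjoint: too few genes")
  if (within_gene_sd <= 0) abort_spec("within_gene_sd must be positive")
  if (baseline_mean_range[2L] < baseline_mean_range[1L])
    abort_spec("baseline_mean_range must be an interval")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 class_sizes = class_sizes,
                 baseline_mean_range = as.numeric(baseline_mean_range),
                 within_gene_sd = within_gene_sd,
                 n_planted_to = as.integer(n_planted_to), delta_to = delta_to,
                 n_planted_mi = as.integer(n_planted_mi), delta_mi = delta_mi),
            class = "crt_synthetic_spec")
}

#' Generate a seeded synthetic cohort with planted differential expression
#'
#' Expression of gene g in sample s is
#' `mu_g + delta * 1[g planted for s's class] + eps`, with
#' `mu_g ~ Uniform(baseline_mean_range)` and
#' `eps ~ Normal(0, within_gene_sd)`. Labels are assigned in class blocks
#' (MI, MO, NT, TO) with exactly the requested counts.
#'
#' @param spec a [synthetic_spec()].
#' @param truth optional planted truth from a previous call; when supplied,
#'   the planted gene sets, shifts, and per-gene baselines are reused, so an
#'   independent test cohort shares its signal genes (and platform baselines)
#'   with a training cohort while the noise is redrawn.
#' @return list with elements `cohort` (a `crt_cohort`) and `truth`
#'   (list: `to_genes`, `mi_genes`, `deltas`, `baseline_mu`).
#' @export
generate_cohort <- function(spec, truth = NULL) {
  stopifnot(inherits(spec, "crt_synthetic_spec"))
  withr::with_seed(spec$seed, {
    G <- spec$n_genes
    genes <- sprintf("SYNG%04d", seq_len(G))
    n <- sum(spec$class_sizes)
    samples <- sprintf("S%03d", seq_len(n))
    grade <- rep(DWORAK_CLASSES, times = spec$class_sizes)
    labels <- dworak_labels(samples, grade)

    if (is.null(truth)) {
      planted <- sample.int(G, spec$n_planted_to + spec$n_planted_mi)
      truth <- list(to_genes = genes[planted[seq_len(spec$n_planted_to)]],
                    mi_genes = genes[planted[spec$n_planted_to + seq_len(spec$n_planted_mi)]],
                    deltas = c(to = spec$delta_to, mi = spec$delta_mi),
                    baseline_mu = stats::setNames(
                      runif(G, spec$baseline_mean_range[1L],
                            spec$baseline_mean_range[2L]), genes))
    } else {
      if (length(intersect(truth$to_genes, truth$mi_genes)))
        abort_spec("planted TO and MI gene sets must be disjoint")
      if (!all(c(truth$to_genes, truth$mi_genes) %in% genes))
        abort_spec("supplied truth names genes outside this spec's gene universe")
      if (is.null(truth$baseline_mu) || !identical(names(truth$baseline_mu), genes))
        abort_spec("supplied truth must carry baseline_mu for this gene universe")
    }

    # baselines are gene properties shared by any cohort measured on the
    # same platform, so a reused truth pins them down along with the signal
    mu <- unname(truth$baseline_mu)
    values <- mu + matrix(rnorm(G * n, sd = spec$within_gene_sd), nrow = G)
    values[genes %in% truth$to_genes, grade == "TO"] <-
      values[genes %in% truth$to_genes, grade == "TO"] + truth$deltas[["to"]]
    values[genes %in% truth$mi_genes, grade == "MI"] <-
      values[genes %in% truth$mi_genes, grade == "MI"] + truth$deltas[["mi"]]
    dimnames(values) <- list(genes, samples)

    list(cohort = bind_cohort(expression_matrix(values), labels), truth = truth)
  })
}

#' Specification for a simulated "second platform"
#'
#' Emulates the gap between two microarray platforms: a reduced gene set
#' (`keep_fraction`) and an affine intensity distortion `y = scale*x + offset`
#' plus Gaussian noise.
#'
#' @param seed integer RNG seed.
#' @param keep_fraction fraction of genes retained (0, 1].
#' @param scale multiplicative factor a.
#' @param offset additive shift b.
#' @param noise_sd s.d. of additive Gaussian noise (>= 0).
#' @return a `crt_platform_spec` list.
#' @export
platform_distortion_spec <- function(seed = 1L, keep_fraction = 0.6,
                                     scale = 0.8, offset = 1.5, noise_sd = 0.2) {
  if (keep_fraction <= 0 || keep_fraction > 1)
    abort_spec("keep_fraction must be in (0, 1]")
  if (noise_sd < 0) abort_spec("noise_sd must be >= 0")
  structure(list(seed = as.integer(seed), keep_fraction = keep_fraction,
                 scale = scale, offset = offset, noise_sd = noise_sd),
            class = "crt_platform_spec")
}

#' Derive a distorted second-platform dataset
#'
#' Retains a seeded random subset of `ceiling(keep_fraction * n_genes)` genes
#' (in original row order) and maps every value through
#' `y = scale * x + offset + Normal(0, noise_sd)`. Sample IDs are preserved.
#'
#' @param expr expression matrix.
#' @param spec a [platform_distortion_spec()].
#' @return distorted expression matrix.
#' @export
distort_platform <- function(expr, spec) {
  stopifnot(inherits(spec, "crt_platform_spec"))
  expr <- expression_matrix(expr)
  withr::with_seed(spec$seed, {
    keep <- sort(sample.int(nrow(expr), ceiling(spec$keep_fraction * nrow(expr))))
    out <- expr[keep, , drop = FALSE]
    out <- spec$scale * out + spec$offset
    if (spec$noise_sd > 0)
      out <- out + matrix(rnorm(length(out), sd = spec$noise_sd), nrow = nrow(out))
    expression_matrix(out)
  })
}
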