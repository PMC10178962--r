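#' Specify a synthetic PRE/PROG cohort
#'
#' Defines the generative law for a two-stage (pre-treatment vs
#' progressed/resistant) expression cohort: multivariate normal on the
#' normalized log-expression scale, with genes organised into correlation
#' blocks and a standardized mean shift (in SD units) applied to PROG
#' samples.
#'
#' Correlation structure: genes within block \eqn{b} share correlation
#' \code{within_cor[b]}; genes in different blocks share
#' \code{sign(b1) * sign(b2) * between_cor}, so one scalar \code{between_cor}
#' with per-block signs (+1 for up-regulated modules, -1 for a down-regulated
#' module, 0 for independent background genes) reproduces the
#' cluster/anti-cluster geometry seen in resistant-melanoma panels.
#'
#' @param genes Character vector of gene symbols.
#' @param effect_sizes Numeric vector (recycled), PROG minus PRE mean shift
#'   per gene in units of \code{noise_sd}.
#' @param blocks Integer vector assigning each gene to a correlation block.
#' @param within_cor Numeric vector, within-block correlation per block.
#' @param between_cor Scalar correlation between signed blocks.
#' @param block_signs Numeric vector of +1 / -1 / 0 per block.
#' @param n_pre,n_prog Sample counts per stage (each >= 2).
#' @param paired_fraction Fraction of PROG samples sharing a patient id with
#'   a PRE sample; the first \code{floor(paired_fraction * n_prog)} PROG
#'   samples reuse PRE patient ids in order.
#' @param noise_sd Residual SD of each gene.
#' @param baseline_mean,baseline_sd Per-gene baseline expression levels are
#'   drawn once (deterministically from \code{seed}) from
#'   N(\code{baseline_mean}, \code{baseline_sd}); they emulate gene-specific
#'   abundance and are removed by any z-scoring downstream.
#' @param seed Integer RNG seed; a fixed seed makes \code{simulate_cohort}
#'   bit-reproducible.
#' @return A \code{cohort_spec} object.
#' @seealso \code{\link{simulate_cohort}}, \code{\link{template_cohort_spec}}
#' @export
cohort_spec <- function(genes, effect_sizes = 0, blocks = 1L,
                        within_cor = 0, between_cor = 0,
                        block_signs = 1, n_pre = 17L, n_prog = 13L,
                        paired_fraction = 1, noise_sd = 1,
                        baseline_mean = 8, baseline_sd = 2, seed = 1L) {
  genes <- as.character(genes)
  p <- length(genes)
  if (!p) stop("'genes' must be non-empty")
  if (anyDuplicated(genes)) stop("duplicate gene symbols in spec")
  if (n_pre < 2 || n_prog < 2) stop("need at least 2 samples per stage")
  effect_sizes <- rep_len(as.numeric(effect_sizes), p)
  blocks <- rep_len(as.integer(blocks), p)
  bl <- sort(unique(blocks))
  within_cor <- rep_len(as.numeric(within_cor), length(bl))
  block_signs <- rep_len(as.numeric(block_signs), length(bl))
  if (any(abs(within_cor) > 1) || abs(between_cor) > 1)
    stop("correlations must lie in [-1, 1]")
  if (paired_fraction < 0 || paired_fraction > 1)
    stop("'paired_fraction' must be in [0, 1]")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  spec <- structure(list(
    genes = genes, effect_sizes = stats::setNames(effect_sizes, genes),
    blocks = stats::setNames(blocks, genes), block_levels = bl,
    within_cor = stats::setNames(within_cor, bl),
    between_cor = between_cor,
    block_signs = stats::setNames(block_signs, bl),
    n_pre = as.integer(n_pre), n_prog = as.integer(n_prog),
    paired_fraction = paired_fraction, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    seed = as.integer(seed)), class = "cohort_spec")
  # fail construction, not simulation, on an invalid covariance
  check_spec_covariance(spec)
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d genes, %d blocks, %d PRE + %d PROG samples, seed %d\n",
              length(x$genes), length(x$block_levels), x$n_pre, x$n_prog, x$seed))
  cat(sprintf("  informative genes: %d (|effect| > 0)\n",
              sum(x$effect_sizes != 0)))
  invisible(x)
}

# Build the gene-gene correlation matrix implied by a spec.
spec_correlation <- function(spec) {
  p <- length(spec$genes)
  b <- spec$blocks
  sgn <- spec$block_signs[as.character(b)]
  R <- outer(sgn, sgn) * spec$between_cor
  for (bl in spec$block_levels) {
    idx <- which(b == bl)
    R[idx, idx] <- spec$within_cor[as.character(bl)]
  }
  diag(R) <- 1
  dimnames(R) <- list(spec$genes, spec$genes)
  R
}

check_spec_covariance <- function(spec) {
  for (bl in spec$block_levels) {
    m <- sum(spec$blocks == bl)
    if (m > 1) {
      rho <- spec$within_cor[as.character(bl)]
      # equicorrelation block PSD iff rho >= -1/(m-1)
      if (rho < -1 / (m - 1) - 1e-12)
        stop(sprintf("block %s covariance is not positive semi-definite (rho = %g, %d genes)",
                     bl, rho, m))
    }
  }
  R <- spec_correlation(spec)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("block covariance is not positive semi-definite (min eigenvalue %.3g); check between_cor %g against the block structure",
                 min(ev), spec$between_cor))
  invisible(R)
}

#' Ground truth of a synthetic spec
#'
#' Deterministic function of the spec alone: the true per-gene effects, the
#' set of informative genes and the block memberships, for recovery tests.
#'
#' @param spec A \code{cohort_spec}.
#' @return A list with \code{effects}, \code{informative}, \code{blocks}.
#' @export
cohort_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  list(effects = spec$effect_sizes,
       informative = names(spec$effect_sizes)[spec$effect_sizes != 0],
       blocks = spec$blocks)
}

#' Simulate a PRE/PROG cohort
#'
#' Draws \code{n_pre + n_prog} samples from the multivariate normal law of
#' the spec; PROG samples are shifted by \code{effect_sizes * noise_sd}.
#' The RNG is seeded from \code{spec$seed} (offset by \code{seed_offset}), so
#' identical inputs produce bit-identical output.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param dataset_id Dataset label recorded in the sample metadata.
#' @param seed_offset Integer added to \code{spec$seed}, used by
#'   \code{\link{simulate_multi_cohort}} to decorrelate datasets.
#' @return An \code{\link{expression_set}}.
#' @export
simulate_cohort <- function(spec, dataset_id = "D1", seed_offset = 0L) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- check_spec_covariance(spec)
  Sigma <- spec$noise_sd^2 * R
  p <- length(spec$genes)
  n <- spec$n_pre + spec$n_prog
  set.seed(spec$seed + as.integer(seed_offset))
  baseline <- stats::rnorm(p, spec$baseline_mean, spec$baseline_sd)
  X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
  stage <- c(rep("PRE", spec$n_pre), rep("PROG", spec$n_prog))
  shift <- spec$effect_sizes * spec$noise_sd
  X[stage == "PROG", ] <- sweep(X[stage == "PROG", , drop = FALSE], 2, shift, "+")
  X <- sweep(X, 2, baseline, "+")
  values <- t(X)
  sample_id <- sprintf("%s_S%02d", dataset_id, seq_len(n))
  rownames(values) <- spec$genes
  colnames(values) <- sample_id
  n_paired <- floor(spec$paired_fraction * spec$n_prog)
  patient <- character(n)
  patient[stage == "PRE"] <- sprintf("%s_P%02d", dataset_id, seq_len(spec$n_pre))
  prog_patient <- sprintf("%s_P%02d",
                          dataset_id,
                          c(seq_len(n_paired),
                            spec$n_pre + seq_len(spec$n_prog - n_paired)))
  patient[stage == "PROG"] <- prog_patient
  expression_set(values,
                 data.frame(sample_id = sample_id, stage = stage,
                            patient_id = patient, dataset_id = dataset_id,
                            stringsAsFactors = FALSE))
}

#' Simulate several cohorts with dataset-specific batch distortion
#'
#' Each dataset is drawn from the same spec (stage effects preserved) and
#' then distorted by a per-dataset affine transform
#' \code{scale * x + location}, emulating platform/normalization differences
#' between studies. Z-score merging (\code{\link{merge_common_genes}})
#' removes such distortions exactly.
#'
#' @param spec A \code{\link{cohort_spec}}.
#' @param n_datasets Number of datasets (>= 2).
#' @param location Per-dataset additive shift (recycled).
#' @param scale Per-dataset multiplicative factor (recycled, > 0).
#' @return A list of \code{expr_set}, one per dataset (\code{"D1"} ...).
#' @export
simulate_multi_cohort <- function(spec, n_datasets, location = 0, scale = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (n_datasets < 2) stop("'n_datasets' must be at least 2")
  location <- rep_len(as.numeric(location), n_datasets)
  scale <- rep_len(as.numeric(scale), n_datasets)
  if (any(scale <= 0)) stop("'scale' factors must be positive")
  lapply(seq_len(n_datasets), function(d) {
    id <- sprintf("D%d", d)
    es <- simulate_cohort(spec, dataset_id = id, seed_offset = 1000L * d)
    es$values <- es$values * scale[d] + location[d]
    es
  })
}

#' The 18-gene resistance-panel template spec
#'
#' A ready-made spec shaped like a pre-treatment vs progressed melanoma
#' cohort profiled over an 18-gene proteomics-derived panel: 17 PRE and 13
#' PROG samples, three correlation blocks (two up-regulated modules led by
#' HMOX1/ICAM1 and MMP2/TP53, one anti-correlated down-regulated module led
#' by SPARC/VIM), standardized stage effects of mixed sign, and full PRE/PROG
#' patient pairing. Optional background genes (\code{BG0001}, ...) are
#' independent of the panel; a fraction of them carry their own stage
#' effects so that transcriptome-wide differential-expression and pathway
#' steps have signal beyond the panel.
#'
#' @param n_background Number of background genes to append (default 0).
#' @param background_effect_fraction Fraction of background genes given a
#'   +/-0.8 SD stage effect (alternating sign).
#' @param seed RNG seed stored in the spec.
#' @return A \code{\link{cohort_spec}}.
#' @export
template_cohort_spec <- function(n_background = 0L,
                                 background_effect_fraction = 0.1,
                                 seed = 1L) {
  genes <- c("HMOX1", "ENG", "ICAM1", "GRN", "CTSS", "LGALS3",
             "MMP2", "TP53", "ENO2", "BIRC5", "FGF2", "EGFR",
             "SPARC", "VIM", "DKK1", "CXCL8", "CAPG", "CSF2")
  effects <- c(1.0, 0.6, 0.8, 0.55, 0.25, 0.2,
               1.1, 0.7, 0.3, 0.35, 0.25, 0.0,
               -1.0, -0.6, -0.35, -0.3, -0.25, 0.0)
  blocks <- rep(1:3, each = 6L)
  within <- c(0.65, 0.5, 0.45)
  signs <- c(1, 1, -1)
  if (n_background > 0) {
    bg <- sprintf("BG%04d", seq_len(n_background))
    n_eff <- floor(background_effect_fraction * n_background)
    bg_eff <- numeric(n_background)
    if (n_eff > 0) bg_eff[seq_len(n_eff)] <- 0.8 * rep_len(c(1, -1), n_eff)
    genes <- c(genes, bg)
    effects <- c(effects, bg_eff)
    blocks <- c(blocks, rep(4L, n_background))
    within <- c(within, 0)
    signs <- c(signs, 0)
  }
  cohort_spec(genes, effect_sizes = effects, blocks = blocks,
              within_cor = within, between_cor = 0.25, block_signs = signs,
              n_pre = 17L, n_prog = 13L, paired_fraction = 1,
              noise_sd = 1, seed = seed)
}

#' Simulate gene-set collections over a gene universe
#'
#' Draws random gene sets for exercising the enrichment and pathway-scoring
#' steps, optionally planting named sets (e.g. a set concentrated in
#' up-regulated panel genes) so that truth is known.
#'
#' @param universe Character vector of available gene symbols.
#' @param n_sets Number of random sets.
#' @param size_range Integer range of set sizes.
#' @param planted Named list of character vectors appended verbatim.
#' @param seed RNG seed.
#' @return A \code{gene_sets} list.
#' @export
simulate_gene_sets <- function(universe, n_sets = 20L, size_range = c(10L, 40L),
                               planted = list(), seed = 1L) {
  set.seed(seed)
  size_range[2] <- min(size_range[2], length(universe))
  sets <- lapply(seq_len(n_sets), function(i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    sort(sample(universe, sz))
  })
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_len(n_sets))
  if (length(planted)) {
    stopifnot(!is.null(names(planted)))
    sets <- c(planted, sets)
  }
  structure(sets, class = c("gene_sets", "list"))
}
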