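#' Kruskal-Wallis test of a gene (or score) against stage
#'
#' Rank-based, tie-corrected two-group Kruskal-Wallis with the chi-square
#' approximation, as used throughout for stage association. Zero-variance
#' input is flagged degenerate and assigned p = 1 rather than NaN.
#'
#' @param x Numeric vector of values, or an \code{expr_set} (then \code{gene}
#'   selects the row and stage labels come from the metadata).
#' @param g Group labels (ignored when \code{x} is an \code{expr_set}).
#' @param gene Gene symbol, when \code{x} is an \code{expr_set}.
#' @return List with \code{statistic}, \code{p.value}, \code{degenerate}.
#' @export
kruskal_by_stage <- function(x, g = NULL, gene = NULL) {
  if (inherits(x, "expr_set")) {
    if (is.null(gene)) stop("supply 'gene' when passing an expr_set")
    g <- stage_labels(x)
    x <- expr_values(x)[gene, ]
  }
  g <- factor(g)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("both stages must be present with at least 2 samples each")
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p.value = 1, degenerate = TRUE))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       degenerate = FALSE)
}

#' Adjust p-values for multiplicity
#'
#' Thin, validating wrapper around \code{stats::p.adjust};
#' Benjamini-Hochberg by default.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @param method Adjustment method (see \code{\link[stats]{p.adjust}}).
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Per-gene odds ratios for the progressed stage
#'
#' For each panel gene, fits a univariable logistic regression of stage
#' (PROG = 1) on the gene's expression standardized per dataset (z-score
#' across all samples of each dataset), and reports the per-SD odds ratio
#' with Wald 95\% CI and p-value, plus the Kruskal-Wallis stage p-value and
#' Benjamini-Hochberg adjusted p-values across the panel. Perfect separation
#' is flagged rather than raised.
#'
#' @param x An \code{expr_set}.
#' @param panel Genes to test (default: all genes).
#' @param standardize Standardize expression per gene within dataset before
#'   the fit (default TRUE; ORs are then per-SD and comparable across genes).
#' @return A data frame of class \code{association_table} with columns
#'   \code{gene, or, ci_low, ci_high, p, p_adj, kw_p, separation}.
#' @export
gene_odds_ratios <- function(x, panel = gene_ids(x), standardize = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  y <- stage01(x)
  if (length(unique(y)) < 2) stop("both stages must be present")
  vals <- expr_values(x)[panel, , drop = FALSE]
  if (standardize) {
    raw <- vals
    vals <- zscore_values(vals, sample_info(x)$dataset_id)
    drop_genes <- attr(vals, "dropped_genes")
    if (length(drop_genes)) {
      # keep constant genes on the raw scale; they get a degenerate OR row
      vals[drop_genes, ] <- raw[drop_genes, , drop = FALSE]
      warning("zero-variance gene(s) not standardized: ",
              paste(drop_genes, collapse = ", "))
    }
  }
  rows <- lapply(panel, function(g) {
    xi <- vals[g, ]
    fit_logistic_or(xi, y)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(gene = panel, out, stringsAsFactors = FALSE)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)   # separated/degenerate fits carry no Wald p
  out$p_adj[ok] <- adjust_pvalues(out$p[ok])
  out <- out[, c("gene", "or", "ci_low", "ci_high", "p", "p_adj", "kw_p",
                 "separation")]
  out$kw_p <- vapply(panel, function(g)
    kruskal_by_stage(vals[g, ], factor(y))$p.value, numeric(1))
  class(out) <- c("association_table", "data.frame")
  out
}

# single-covariate logistic fit -> OR row; detects (quasi-)separation via
# the glm convergence warning / exploding coefficient.
fit_logistic_or <- function(xi, y) {
  if (stats::sd(xi) == 0) {
    return(data.frame(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      p = 1, kw_p = 1, separation = FALSE))
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ xi, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[["xi"]]
  se <- sqrt(diag(stats::vcov(fit)))[["xi"]]
  if (abs(beta) > 15) sep <- TRUE
  if (sep) {
    or <- if (beta > 0) Inf else 0
    return(data.frame(or = or, ci_low = 0, ci_high = Inf, p = NA_real_,
                      kw_p = NA_real_, separation = TRUE))
  }
  z <- beta / se
  data.frame(or = exp(beta),
             ci_low = exp(beta - stats::qnorm(0.975) * se),
             ci_high = exp(beta + stats::qnorm(0.975) * se),
             p = 2 * stats::pnorm(-abs(z)),
             kw_p = NA_real_, separation = FALSE)
}

#' Spearman correlation matrix of a panel
#'
#' Pairwise Spearman rho (average ranks for ties) with two-sided p-values
#' from the t approximation. Zero-variance genes have undefined rho; they
#' are kept in the matrix as NA and listed in the \code{degenerate} field.
#'
#' @param x An \code{expr_set} (>= 3 samples).
#' @param panel Genes to correlate (default: all).
#' @return Object of class \code{gene_cor}: list with \code{rho}, \code{p}
#'   (symmetric matrices) and \code{degenerate} (character vector).
#' @export
spearman_matrix <- function(x, panel = gene_ids(x)) {
  stopifnot(inherits(x, "expr_set"))
  vals <- expr_values(x)[panel, , drop = FALSE]
  n <- ncol(vals)
  if (n < 3) stop("need at least 3 samples")
  degenerate <- panel[apply(vals, 1, function(v) length(unique(v)) == 1L)]
  ranks <- t(apply(vals, 1, rank))
  rho <- suppressWarnings(stats::cor(t(ranks)))  # Pearson on ranks == Spearman
  rho[degenerate, ] <- NA_real_
  rho[, degenerate] <- NA_real_
  diag(rho) <- ifelse(panel %in% degenerate, NA_real_, 1)
  # t approximation, as cor.test(..., exact = FALSE)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[!is.finite(p)] <- 0  # |rho| = 1
  diag(p) <- NA_real_
  structure(list(rho = rho, p = p, degenerate = degenerate, n = n),
            class = "gene_cor")
}

#' @export
print.gene_cor <- function(x, ...) {
  cat(sprintf("gene_cor: %d x %d Spearman matrix over %d samples",
              nrow(x$rho), ncol(x$rho), x$n))
  if (length(x$degenerate))
    cat(sprintf(" (%d degenerate gene(s))", length(x$degenerate)))
  cat("\n")
  invisible(x)
}

#' Hierarchical clustering of a correlation matrix
#'
#' Agglomerative clustering with complete linkage on the distance
#' \code{1 - rho}. When \code{k} is missing it is chosen by maximum mean
#' silhouette width over \code{k in 2:min(8, n-1)} (smallest k wins ties).
#'
#' @param corr A \code{gene_cor} (or a plain correlation matrix).
#' @param k Number of clusters, or NULL for silhouette selection.
#' @return Named integer vector of cluster labels, with the chosen \code{k}
#'   and the \code{hclust} tree attached as attributes.
#' @export
hierarchical_clusters <- function(corr, k = NULL) {
  rho <- if (inherits(corr, "gene_cor")) corr$rho else corr
  if (anyNA(rho)) stop("correlation matrix contains NA (degenerate genes); drop them first")
  n <- nrow(rho)
  d <- stats::as.dist(1 - rho)
  tree <- stats::hclust(d, method = "complete")
  if (is.null(k)) {
    ks <- 2:min(8, n - 1)
    if (!length(ks)) stop("too few genes to cluster")
    sil <- vapply(ks, function(kk) {
      lab <- stats::cutree(tree, k = kk)
      mean(cluster::silhouette(lab, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  if (k < 2 || k > n) stop("'k' must lie in [2, n_genes]")
  labels <- stats::cutree(tree, k = k)
  attr(labels, "k") <- k
  attr(labels, "tree") <- tree
  labels
}

#' PCA of samples over a gene panel
#'
#' Centered (optionally unit-variance) PCA via SVD of the samples-by-genes
#' matrix. Per-variable contributions to each component are
#' \code{100 * loading^2 / sum(loading^2)}; a variable is flagged
#' above-average on a component when its contribution exceeds
#' \code{100 / n_genes}. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making results platform-stable.
#'
#' @param x An \code{expr_set} (>= 3 samples).
#' @param panel Genes to use (>= 2).
#' @param scale. Scale genes to unit variance (default TRUE). A constant
#'   gene with \code{scale. = TRUE} is an error naming the gene.
#' @return Object of class \code{panel_pca}: list with \code{scores}
#'   (samples x PC), \code{loadings}, \code{variance_explained},
#'   \code{contributions} (percent, columns sum to 100),
#'   \code{above_average} (logical matrix).
#' @export
panel_pca <- function(x, panel = gene_ids(x), scale. = TRUE) {
  stopifnot(inherits(x, "expr_set"))
  if (length(panel) < 2) stop("need at least 2 genes")
  vals <- t(expr_values(x)[panel, , drop = FALSE])
  if (nrow(vals) < 3) stop("need at least 3 samples")
  sds <- apply(vals, 2, stats::sd)
  if (scale. && any(sds == 0))
    stop("constant gene(s) cannot be scaled: ",
         paste(panel[sds == 0], collapse = ", "))
  pc <- stats::prcomp(vals, center = TRUE, scale. = scale.)
  # deterministic sign: largest |loading| positive on every component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, contributions = contrib,
                 above_average = contrib > 100 / length(panel),
                 panel = panel),
            class = "panel_pca")
}

#' @export
print.panel_pca <- function(x, ...) {
  cat(sprintf("panel_pca: %d genes, %d samples; PC1+PC2 explain %.1f%% of variance\n",
              length(x$panel), nrow(x$scores),
              100 * sum(x$variance_explained[1:min(2, length(x$variance_explained))])))
  invisible(x)
}

#' Stage separation along a principal component
#'
#' Kruskal-Wallis test of a component's sample scores by group; identical in
#' behaviour to \code{\link{kruskal_by_stage}} applied to the score vector.
#'
#' @param pca A \code{panel_pca}.
#' @param labels Group labels aligned with the PCA's samples.
#' @param component Component index (default 1).
#' @return As \code{\link{kruskal_by_stage}}.
#' @export
pc_separation_test <- function(pca, labels, component = 1L) {
  stopifnot(inherits(pca, "panel_pca"))
  if (component > ncol(pca$scores)) stop("component does not exist")
  kruskal_by_stage(pca$scores[, component], labels)
}
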