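#' Enumerate gene subsets of a universe
#'
#' Every subset with size in \code{[min_size, max_size]} is represented once
#' as an ascending bitmask over the universe (bit \code{i} set = gene
#' \code{i+1} included). For an 18-gene universe with no size bounds this is
#' the full 2^18 - 1 = 262,143 subsets.
#'
#' @param universe Character vector (or \code{gene_panel}) of gene symbols,
#'   at most 25.
#' @param min_size,max_size Subset size bounds.
#' @return List with \code{masks} (integer vector), \code{sizes},
#'   \code{count}, \code{universe}.
#' @export
enumerate_panels <- function(universe, min_size = 1L,
                             max_size = length(universe)) {
  universe <- as.character(universe)
  p <- length(universe)
  if (!p) stop("'universe' must be non-empty")
  if (p > 25) stop("universe too large for exhaustive enumeration (> 25 genes)")
  if (min_size < 1 || max_size > p || min_size > max_size)
    stop("size bounds must satisfy 1 <= min_size <= max_size <= |universe|")
  masks <- seq_len(2^p - 1)
  sizes <- cpp_popcount(as.integer(masks))
  keep <- sizes >= min_size & sizes <= max_size
  list(masks = as.integer(masks[keep]), sizes = sizes[keep],
       count = sum(keep), universe = universe)
}

# decode a bitmask into gene symbols
mask_to_genes <- function(mask, universe) {
  universe[bitwAnd(mask, bitwShiftL(1L, seq_along(universe) - 1L)) != 0L]
}

#' Fit a risk panel by exhaustive subset search
#'
#' The discovery procedure: every gene subset of the universe (bitmask
#' ascending) is fitted by ridge-stabilized two-class LDA and scored by the
#' resubstitution Mann-Whitney AUC of its linear risk score; the subset with
#' the highest AUC wins (ties broken toward the smaller panel, then the
#' lower bitmask). The winning panel is refitted and summarized with an
#' optimal cutpoint and the full classifier-marker table.
#'
#' Subsets whose covariance stays singular after shrinkage escalation are
#' recorded as skipped, never silently scored. The search is deterministic:
#' identical input yields an identical winner and ranking.
#'
#' Note the resubstitution convention: the apparent AUC of the best of
#' hundreds of thousands of panels is optimistically biased, which is why
#' \code{\link{validate_panel}} on independent cohorts is part of the
#' workflow (see the package vignette).
#'
#' @param x An \code{expr_set}.
#' @param universe Gene universe to search (default: all genes of \code{x};
#'   at most 25).
#' @param min_size,max_size Panel size bounds.
#' @param top_k Number of top panels retained in the ranking table.
#' @param cutpoint_criterion Passed to \code{\link{optimal_cutpoint}}.
#' @return Object of class \code{risk_panel}: list with \code{panel}
#'   (\code{gene_panel}), \code{model} (\code{panel_lda}), \code{metrics}
#'   (\code{classifier_metrics}), \code{ranking} (top-K data frame),
#'   \code{n_evaluated}, \code{n_skipped}, \code{universe}, \code{call}.
#' @seealso \code{\link{validate_panel}}, \code{\link{risk_scores}}
#' @export
#' @examples
#' spec <- template_cohort_spec(seed = 7)
#' cohort <- simulate_cohort(spec)
#' fit <- fit_risk_panel(cohort, max_size = 3)  # small search for speed
#' fit
fit_risk_panel <- function(x, universe = gene_ids(x), min_size = 1L,
                           max_size = length(universe), top_k = 50L,
                           cutpoint_criterion = "youden") {
  stopifnot(inherits(x, "expr_set"))
  universe <- sort(as.character(universe))  # canonical order
  missing_genes <- setdiff(universe, gene_ids(x))
  if (length(missing_genes))
    stop("universe gene(s) missing from matrix: ",
         paste(missing_genes, collapse = ", "))
  if (length(universe) > 25)
    stop("universe too large for exhaustive search (> 25 genes)")
  X <- t(expr_values(x)[universe, , drop = FALSE])
  y <- stage01(x)
  res <- cpp_panel_search(X, as.integer(y), as.integer(min_size),
                          as.integer(max_size))
  ok <- res$skipped == 0L
  if (!any(ok)) stop("every subset was skipped (singular covariance)")
  # argmax AUC; ties -> smaller panel, then ascending bitmask (masks ascend
  # already, so order() below is stable on mask)
  o <- order(-res$auc[ok], res$size[ok], res$mask[ok])
  best_mask <- res$mask[ok][o[1]]
  panel_genes <- mask_to_genes(best_mask, universe)
  model <- fit_panel_lda(x, panel_genes)
  scores <- predict(model, x)
  cp <- optimal_cutpoint(scores, y, criterion = cutpoint_criterion)
  metrics <- confusion_metrics(scores, y, cp)
  kidx <- o[seq_len(min(top_k, sum(ok)))]
  ranking <- data.frame(
    mask = res$mask[ok][kidx],
    genes = vapply(res$mask[ok][kidx],
                   function(m) paste(mask_to_genes(m, universe), collapse = ","),
                   character(1)),
    size = res$size[ok][kidx],
    auc = res$auc[ok][kidx],
    stringsAsFactors = FALSE)
  structure(list(panel = gene_panel(panel_genes, name = "best_panel"),
                 model = model, metrics = metrics, ranking = ranking,
                 n_evaluated = length(res$mask),
                 n_skipped = sum(res$skipped),
                 universe = universe, mask = best_mask,
                 call = match.call()),
            class = "risk_panel")
}

#' @export
print.risk_panel <- function(x, ...) {
  cat("Risk panel fitted by exhaustive LDA/AUC subset search\n")
  cat(sprintf("  subsets evaluated: %d (%d skipped)\n",
              x$n_evaluated, x$n_skipped))
  cat(sprintf("  best panel (%d genes): %s\n", length(x$panel),
              paste(unclass(x$panel), collapse = ", ")))
  cat(sprintf("  apparent AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$metrics$auc, x$metrics$ci_low, x$metrics$ci_high))
  invisible(x)
}

#' @export
summary.risk_panel <- function(object, ...) {
  cat("Exhaustive risk-panel search\n")
  cat(sprintf("universe: %d genes; subsets evaluated: %d; skipped: %d\n",
              length(object$universe), object$n_evaluated, object$n_skipped))
  cat(sprintf("\nbest panel (%d genes): %s\n", length(object$panel),
              paste(unclass(object$panel), collapse = ", ")))
  print(object$metrics)
  cat("\ncoefficients (beta):\n")
  print(round(object$model$beta, 4))
  cat("\ntop of ranking:\n")
  print(utils::head(object$ranking, 10), row.names = FALSE)
  invisible(object)
}

#' @export
coef.risk_panel <- function(object, ...) object$model$beta

#' @rdname fit_risk_panel
#' @param object A \code{risk_panel}.
#' @param newdata,type,cutpoint,... Passed to
#'   \code{\link{predict.panel_lda}}.
#' @export
predict.risk_panel <- function(object, newdata, type = c("score", "class"),
                               cutpoint = object$metrics$cutpoint, ...) {
  predict(object$model, newdata, type = match.arg(type), cutpoint = cutpoint)
}

#' Plot the ROC curve of a fitted risk panel
#'
#' @param x A \code{risk_panel}.
#' @param newdata Optional \code{expr_set} to score (default: not available;
#'   the stored resubstitution metrics have no data attached, so supply the
#'   cohort).
#' @param ... Passed to \code{plot}.
#' @export
plot.risk_panel <- function(x, newdata, ...) {
  if (missing(newdata)) stop("supply the cohort to score ('newdata')")
  scores <- predict(x, newdata)
  rc <- roc_curve(scores, stage_labels(newdata))
  graphics::plot(rc$fpr, rc$tpr, type = "s", xlab = "1 - specificity",
                 ylab = "sensitivity",
                 main = sprintf("ROC, AUC = %.3f",
                                roc_auc(scores, stage_labels(newdata))$auc),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(rc)
}

#' Validate a panel across independent cohorts
#'
#' For each validation dataset: risk scores (with the discovery coefficients
#' by default, or refitted per dataset), Kruskal-Wallis p of score by stage,
#' logistic odds ratio of stage on the standardized score with Wald CI, and
#' the classifier-marker table at a per-dataset optimal cutpoint. KW and
#' logistic p-values are Benjamini-Hochberg adjusted across datasets.
#' Datasets missing panel genes are flagged, not dropped silently.
#'
#' @param fit A \code{risk_panel} or \code{panel_lda}.
#' @param datasets List of \code{expr_set} cohorts.
#' @param refit Refit the LDA coefficients within each dataset
#'   (default FALSE: score with the discovery beta).
#' @return Data frame with one row per dataset: \code{dataset, n, kw_p,
#'   kw_p_adj, or, or_ci_low, or_ci_high, or_p, or_p_adj, sensitivity,
#'   specificity, ppv, npv, auc, auc_ci_low, auc_ci_high, missing_genes}.
#' @export
validate_panel <- function(fit, datasets, refit = FALSE) {
  model <- if (inherits(fit, "risk_panel")) fit$model else fit
  stopifnot(inherits(model, "panel_lda"))
  if (inherits(datasets, "expr_set")) datasets <- list(datasets)
  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    id <- unique(sample_info(d)$dataset_id)
    id <- if (length(id) == 1) id else sprintf("dataset%d", i)
    miss <- setdiff(model$panel, gene_ids(d))
    if (length(miss)) {
      return(data.frame(dataset = id, n = ncol(expr_values(d)),
                        kw_p = NA_real_, or = NA_real_, or_ci_low = NA_real_,
                        or_ci_high = NA_real_, or_p = NA_real_,
                        sensitivity = NA_real_, specificity = NA_real_,
                        ppv = NA_real_, npv = NA_real_, auc = NA_real_,
                        auc_ci_low = NA_real_, auc_ci_high = NA_real_,
                        cutpoint = NA_real_,
                        missing_genes = paste(miss, collapse = ","),
                        stringsAsFactors = FALSE))
    }
    m <- if (refit) fit_panel_lda(d, model$panel) else model
    sc <- predict(m, d)
    tests <- score_group_tests(sc, stage_labels(d))
    cp <- optimal_cutpoint(sc, stage_labels(d))
    cm <- confusion_metrics(sc, stage_labels(d), cp)
    data.frame(dataset = id, n = length(sc), kw_p = tests$kw_p,
               or = tests$or, or_ci_low = tests$or_ci_low,
               or_ci_high = tests$or_ci_high, or_p = tests$or_p,
               sensitivity = cm$sensitivity, specificity = cm$specificity,
               ppv = cm$ppv, npv = cm$npv, auc = cm$auc,
               auc_ci_low = cm$ci_low, auc_ci_high = cm$ci_high,
               cutpoint = cp, missing_genes = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$kw_p_adj <- NA_real_
  out$or_p_adj <- NA_real_
  ok <- !is.na(out$kw_p)
  if (any(ok)) out$kw_p_adj[ok] <- adjust_pvalues(out$kw_p[ok])
  ok2 <- !is.na(out$or_p)
  if (any(ok2)) out$or_p_adj[ok2] <- adjust_pvalues(out$or_p[ok2])
  cols <- c("dataset", "n", "kw_p", "kw_p_adj", "or", "or_ci_low",
            "or_ci_high", "or_p", "or_p_adj", "sensitivity", "specificity",
            "ppv", "npv", "auc", "auc_ci_low", "auc_ci_high", "cutpoint",
            "missing_genes")
  out[, cols]
}
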