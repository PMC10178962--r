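#' Fit a two-class linear discriminant risk model
#'
#' Fisher's two-class closed form with equal priors and a ridge-stabilized
#' pooled covariance:
#' \deqn{\beta \propto (S + \lambda I)^{-1} (\mu_{PROG} - \mu_{PRE})}
#' The coefficient vector is oriented so that PROG samples score higher on
#' average; the per-sample risk score is the pure dot product
#' \eqn{\sum_i x_i \beta_i} with no intercept (the decision cutpoint carries
#' the offset).
#'
#' The default shrinkage \code{1e-6 * trace(S)/p} is escalated tenfold at a
#' time (up to \code{0.1 * trace(S)/p}) whenever the pooled covariance is
#' numerically singular — routine when the panel size approaches the sample
#' count, as it does during exhaustive subset search.
#'
#' @param x An \code{expr_set}, or a samples-by-genes numeric matrix.
#' @param panel Genes to use (default: all genes of \code{x}).
#' @param labels Binary stage labels (ignored for \code{expr_set} input);
#'   anything coercible to a PRE/PROG factor or 0/1 vector.
#' @param shrinkage Ridge added to the pooled covariance, as a fraction of
#'   \code{trace(S)/p}; \code{NULL} uses the escalating default.
#' @return Object of class \code{panel_lda}: list with \code{panel},
#'   \code{beta}, \code{threshold} (midpoint of the class mean scores),
#'   \code{class_means} (mean score per class), \code{shrinkage} (the value
#'   actually used, absolute).
#' @export
fit_panel_lda <- function(x, panel = NULL, labels = NULL, shrinkage = NULL) {
  prep <- prepare_xy(x, panel, labels)
  X <- prep$X; y <- prep$y; panel <- prep$panel
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("both classes need at least 2 samples")
  p <- ncol(X)
  mu1 <- colMeans(X[y == 1, , drop = FALSE])
  mu0 <- colMeans(X[y == 0, , drop = FALSE])
  S <- pooled_covariance(X, y)
  tr <- sum(diag(S))
  if (tr <= 0) stop("pooled covariance has zero trace (all genes constant)")
  lambda_frac <- if (is.null(shrinkage)) 1e-6 else shrinkage
  beta <- NULL
  repeat {
    lambda <- lambda_frac * tr / p
    beta <- tryCatch(solve(S + diag(lambda, p), mu1 - mu0),
                     error = function(e) NULL)
    if (!is.null(beta) && all(is.finite(beta))) break
    if (!is.null(shrinkage))
      stop("pooled covariance is singular at the requested shrinkage; ",
           "increase 'shrinkage'")
    lambda_frac <- lambda_frac * 10
    if (lambda_frac > 0.1)
      stop("pooled covariance is singular even at maximal shrinkage")
  }
  scores <- drop(X %*% beta)
  m1 <- mean(scores[y == 1]); m0 <- mean(scores[y == 0])
  if (m1 < m0) {  # orientation: PROG scores higher
    beta <- -beta; scores <- -scores
    tmp <- m1; m1 <- -tmp; m0 <- -m0
  }
  structure(list(panel = panel, beta = stats::setNames(beta, panel),
                 threshold = (m1 + m0) / 2,
                 class_means = c(PRE = m0, PROG = m1),
                 shrinkage = lambda_frac * tr / p),
            class = "panel_lda")
}

# internal: normalize (expr_set | matrix) + panel + labels into X (samples x
# genes), y (0/1), panel
prepare_xy <- function(x, panel, labels) {
  if (inherits(x, "expr_set")) {
    if (is.null(panel)) panel <- gene_ids(x)
    missing_genes <- setdiff(panel, gene_ids(x))
    if (length(missing_genes))
      stop("panel gene(s) missing from matrix: ",
           paste(missing_genes, collapse = ", "))
    X <- t(expr_values(x)[panel, , drop = FALSE])
    y <- stage01(x)
  } else {
    X <- as.matrix(x)
    if (is.null(labels)) stop("supply 'labels' with matrix input")
    y <- as_binary_labels(labels)
    if (is.null(panel)) panel <- colnames(X)
    if (is.null(panel)) panel <- sprintf("V%d", seq_len(ncol(X)))
    colnames(X) <- panel
  }
  list(X = X, y = y, panel = panel)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("PRE", "PROG"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.integer(labels == "PROG"))
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be PRE/PROG or 0/1")
  labels
}

pooled_covariance <- function(X, y) {
  X1 <- X[y == 1, , drop = FALSE]; X0 <- X[y == 0, , drop = FALSE]
  n1 <- nrow(X1); n0 <- nrow(X0)
  ((n1 - 1) * stats::cov(X1) + (n0 - 1) * stats::cov(X0)) / (n1 + n0 - 2)
}

#' @export
print.panel_lda <- function(x, ...) {
  cat(sprintf("panel_lda: %d genes, threshold %.4g\n", length(x$panel),
              x$threshold))
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.panel_lda <- function(object, ...) object$beta

#' Risk scores from a fitted discriminant model
#'
#' \code{predict} returns the linear risk score \eqn{\sum_i x_i \beta_i} per
#' sample, or the PRE/PROG call at a cutpoint (strictly greater-than rule).
#'
#' @param object A \code{panel_lda}.
#' @param newdata An \code{expr_set} or samples-by-genes matrix containing
#'   the model's panel genes.
#' @param type \code{"score"} (default) or \code{"class"}.
#' @param cutpoint Decision cutpoint for \code{type = "class"}; defaults to
#'   the model's threshold.
#' @param ... Ignored.
#' @return Named numeric vector of scores, or a PRE/PROG factor.
#' @export
predict.panel_lda <- function(object, newdata, type = c("score", "class"),
                              cutpoint = object$threshold, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "expr_set")) {
    missing_genes <- setdiff(object$panel, gene_ids(newdata))
    if (length(missing_genes))
      stop("panel gene(s) missing from newdata: ",
           paste(missing_genes, collapse = ", "))
    X <- t(expr_values(newdata)[object$panel, , drop = FALSE])
  } else {
    X <- as.matrix(newdata)[, object$panel, drop = FALSE]
  }
  scores <- drop(X %*% object$beta)
  if (type == "score") return(scores)
  factor(ifelse(scores > cutpoint, "PROG", "PRE"), levels = c("PRE", "PROG"))
}

#' ROC AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney construction (ties count 1/2): the probability
#' that a random PROG sample scores above a random PRE sample. The 95\% CI
#' uses the DeLong placement variance with an untruncated normal interval,
#' so the upper bound may exceed 1 for near-perfect classifiers — this
#' matches the reporting convention of cohort studies that print e.g.
#' "0.943-1.021"; use \code{clip = TRUE} for a presentation-clipped copy.
#'
#' @param scores Numeric scores.
#' @param labels PRE/PROG or 0/1 labels.
#' @param conf_level Confidence level (default 0.95).
#' @param clip Clip the reported CI into [0, 1] (default FALSE).
#' @return List with \code{auc}, \code{ci_low}, \code{ci_high}, \code{se},
#'   \code{clipped} flag.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95, clip = FALSE) {
  y <- as_binary_labels(labels)
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))  # midranks handle ties at 1/2
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong placements
  psi_pos <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)),
                    numeric(1))
  psi_neg <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)),
                    numeric(1))
  v <- stats::var(psi_pos) / n1 + stats::var(psi_neg) / n0
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- auc - zq * se; hi <- auc + zq * se
  clipped <- FALSE
  if (clip) {
    clipped <- lo < 0 || hi > 1
    lo <- max(0, lo); hi <- min(1, hi)
  }
  list(auc = auc, ci_low = lo, ci_high = hi, se = se, clipped = clipped)
}

#' Empirical ROC curve
#'
#' Sensitivity/1-specificity pairs over all distinct thresholds (strict
#' greater-than rule), ordered from (0,0) to (1,1). The trapezoidal area
#' under this curve equals the Mann-Whitney AUC.
#'
#' @inheritParams roc_auc
#' @return Data frame with columns \code{threshold}, \code{fpr}, \code{tpr}.
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[y == 1] > t) , numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[y == 0] > t) , numeric(1))
  data.frame(threshold = c(Inf, thr, -Inf),
             fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Optimal decision cutpoint on a score axis
#'
#' Maximizes the chosen criterion over midpoints between adjacent distinct
#' scores (Youden's J = sensitivity + specificity - 1 by default). Ties are
#' broken toward higher specificity, then toward the lower cutpoint, making
#' the result deterministic.
#'
#' @inheritParams roc_auc
#' @param criterion \code{"youden"} (default) or a function
#'   \code{f(sens, spec)} returning the value to maximize.
#' @return The cutpoint (numeric). Constant scores yield \code{NA} with a
#'   warning (cutpoint undefined).
#' @export
optimal_cutpoint <- function(scores, labels, criterion = "youden") {
  y <- as_binary_labels(labels)
  us <- sort(unique(scores))
  if (length(us) < 2) {
    warning("scores are constant; cutpoint undefined")
    return(NA_real_)
  }
  crit <- if (is.function(criterion)) criterion
          else switch(criterion,
                      youden = function(sens, spec) sens + spec - 1,
                      stop("unknown criterion: ", criterion))
  cand <- (us[-length(us)] + us[-1]) / 2
  sens <- vapply(cand, function(cp) mean(scores[y == 1] > cp), numeric(1))
  spec <- vapply(cand, function(cp) mean(scores[y == 0] <= cp), numeric(1))
  val <- mapply(crit, sens, spec)
  best <- which(val == max(val))
  if (length(best) > 1) best <- best[order(-spec[best], cand[best])][1]
  cand[best]
}

#' Classifier metrics at a cutpoint
#'
#' Confusion-matrix summary of the rule "call PROG when score > cutpoint":
#' sensitivity, specificity, PPV, NPV plus the Mann-Whitney AUC with DeLong
#' CI. Undefined rates (empty denominators) are reported as \code{NaN} and
#' listed in the \code{undefined} field rather than raised.
#'
#' @inheritParams roc_auc
#' @param cutpoint Decision cutpoint (finite).
#' @return Object of class \code{classifier_metrics}: list with fields
#'   \code{auc}, \code{ci_low}, \code{ci_high}, \code{sensitivity},
#'   \code{specificity}, \code{ppv}, \code{npv}, \code{cutpoint},
#'   \code{undefined}.
#' @export
confusion_metrics <- function(scores, labels, cutpoint) {
  if (!is.finite(cutpoint)) stop("'cutpoint' must be finite")
  y <- as_binary_labels(labels)
  pred <- as.integer(scores > cutpoint)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  safe_div <- function(a, b) if (b == 0) NaN else a / b
  au <- roc_auc(scores, y)
  out <- list(auc = au$auc, ci_low = au$ci_low, ci_high = au$ci_high,
              sensitivity = safe_div(tp, tp + fn),
              specificity = safe_div(tn, tn + fp),
              ppv = safe_div(tp, tp + fp),
              npv = safe_div(tn, tn + fn),
              cutpoint = cutpoint)
  out$undefined <- names(out)[vapply(out, function(v) any(is.nan(v)), logical(1))]
  class(out) <- "classifier_metrics"
  out
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f) at cutpoint %.4g\n",
              x$auc, x$ci_low, x$ci_high, x$cutpoint))
  cat(sprintf("sensitivity %.3f  specificity %.3f  PPV %.3f  NPV %.3f\n",
              x$sensitivity, x$specificity, x$ppv, x$npv))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

# metrics as a single-row data.frame (Table-style export)
metrics_row <- function(m) {
  data.frame(sensitivity = m$sensitivity, specificity = m$specificity,
             ppv = m$ppv, npv = m$npv, auc = m$auc,
             auc_ci_low = m$ci_low, auc_ci_high = m$ci_high,
             cutpoint = m$cutpoint)
}
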