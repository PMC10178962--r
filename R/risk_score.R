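#' Per-sample risk scores
#'
#' The linear risk score \eqn{\sum_i x_i \beta_i} of a fitted model over a
#' cohort; a thin delegate to \code{\link{predict.panel_lda}} so there is a
#' single source of truth for score computation.
#'
#' @param fit A \code{panel_lda} or \code{risk_panel}.
#' @param x An \code{expr_set}.
#' @return Named numeric vector of scores (one per sample).
#' @export
risk_scores <- function(fit, x) {
  model <- if (inherits(fit, "risk_panel")) fit$model else fit
  stopifnot(inherits(model, "panel_lda"))
  predict(model, x)
}

#' Patient-level risk-score change from PRE to PROG
#'
#' For every patient with biopsies at both stages: mean PROG score minus
#' mean PRE score (multiple biopsies per stage are averaged before
#' differencing). The change is a difference on the score scale, not a
#' ratio: LDA scores may be negative, so a ratio would be ill-defined.
#' Patients lacking either stage are omitted and listed in the
#' \code{incomplete} attribute.
#'
#' @param scores Named per-sample scores (as from \code{\link{risk_scores}}).
#' @param samples Sample metadata (\code{data.frame} with \code{sample_id},
#'   \code{stage}, \code{patient_id}, \code{dataset_id}), or an
#'   \code{expr_set}.
#' @return Named numeric vector of per-patient changes, with attributes
#'   \code{incomplete} (patient ids lacking a stage) and \code{dataset}
#'   (per-patient dataset id).
#' @export
score_fold_change <- function(scores, samples) {
  if (inherits(samples, "expr_set")) samples <- sample_info(samples)
  samples <- samples[match(names(scores), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("scores contain samples absent from the annotation")
  patients <- unique(samples$patient_id)
  fc <- numeric(0); ds <- character(0); incomplete <- character(0)
  for (p in patients) {
    rows <- samples$patient_id == p
    pre <- scores[rows & samples$stage == "PRE"]
    prog <- scores[rows & samples$stage == "PROG"]
    if (!length(pre) || !length(prog)) {
      incomplete <- c(incomplete, p)
      next
    }
    fc[p] <- mean(prog) - mean(pre)
    ds[p] <- samples$dataset_id[rows][1]
  }
  if (!length(fc)) stop("no patient has samples at both stages")
  attr(fc, "incomplete") <- incomplete
  attr(fc, "dataset") <- ds
  fc
}

#' Stratify patients by risk-score change
#'
#' Applies the rule: \code{Down} if FC < 0; \code{Slightly_up} if
#' 0 <= FC < z; \code{Up} if FC >= z, where \code{z = 0.25 * max(FC)}
#' within each stratification group. The boundary conventions (FC = 0 is
#' Slightly_up, FC = z is Up) close the half-open intervals the strict
#' inequalities of the rule leave unassigned. When no FC is positive the
#' threshold is degenerate: the whole group is labelled \code{Down} and
#' flagged.
#'
#' @param fc Numeric vector of per-patient score changes (as from
#'   \code{\link{score_fold_change}}).
#' @param dataset Optional per-patient dataset ids; when given, \code{z} is
#'   computed within each dataset separately (score scales differ across
#'   cohorts before merging). Defaults to the \code{dataset} attribute of
#'   \code{fc} if present, else a single group.
#' @return Data frame with columns \code{patient_id, fc, dataset, z,
#'   stratum} (factor Down/Slightly_up/Up); degenerate groups carry
#'   \code{z = NA}.
#' @export
stratify_fc <- function(fc, dataset = NULL) {
  if (!length(fc)) stop("'fc' must be non-empty")
  if (is.null(dataset)) dataset <- attr(fc, "dataset")
  if (is.null(dataset)) dataset <- rep("all", length(fc))
  dataset <- rep_len(as.character(dataset), length(fc))
  ids <- names(fc)
  if (is.null(ids)) ids <- sprintf("patient%d", seq_along(fc))
  out <- data.frame(patient_id = ids, fc = as.numeric(fc), dataset = dataset,
                    z = NA_real_, stratum = NA_character_,
                    stringsAsFactors = FALSE)
  for (d in unique(dataset)) {
    rows <- which(dataset == d)
    mx <- max(out$fc[rows])
    if (mx <= 0) {  # degenerate: no positive change to scale against
      out$stratum[rows] <- "Down"
      next
    }
    z <- 0.25 * mx
    out$z[rows] <- z
    out$stratum[rows] <- ifelse(out$fc[rows] < 0, "Down",
                                ifelse(out$fc[rows] < z, "Slightly_up", "Up"))
  }
  out$stratum <- factor(out$stratum, levels = c("Down", "Slightly_up", "Up"))
  out
}

#' Group tests of a score against stage
#'
#' The validation-row statistics for a score vector: Kruskal-Wallis p-value
#' of score by stage, and logistic regression of stage (PROG = 1) on the
#' standardized score giving an odds ratio per SD with Wald CI and p-value.
#' Perfect separation is flagged.
#'
#' @param scores Numeric per-sample scores.
#' @param labels PRE/PROG or 0/1 labels.
#' @return List with \code{kw_p, or, or_ci_low, or_ci_high, or_p,
#'   separation}.
#' @export
score_group_tests <- function(scores, labels) {
  y <- as_binary_labels(labels)
  kw <- kruskal_by_stage(scores, factor(y))
  z <- if (stats::sd(scores) > 0) (scores - mean(scores)) / stats::sd(scores)
       else scores
  lr <- fit_logistic_or(z, y)
  list(kw_p = kw$p.value, or = lr$or, or_ci_low = lr$ci_low,
       or_ci_high = lr$ci_high, or_p = lr$p, separation = lr$separation)
}
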