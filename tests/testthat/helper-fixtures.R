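# Small builders shared across the suite. Fixtures are constructed in code;
# nothing is read from disk except the shipped panel file.

# expression_set from a plain matrix + stage labels
make_es <- function(values, stage, patient = NULL, dataset = "D1") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("G%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  ann <- data.frame(sample_id = colnames(values), stage = stage,
                    stringsAsFactors = FALSE)
  if (!is.null(patient)) ann$patient_id <- patient
  ann$dataset_id <- dataset
  expression_set(values, ann)
}

# cohort with iid N(0,1) genes and optional per-gene PROG shifts
make_gaussian_cohort <- function(n_pre, n_prog, effects, seed,
                                 genes = sprintf("G%02d", seq_along(effects))) {
  spec <- cohort_spec(genes, effect_sizes = effects,
                      blocks = seq_along(genes), within_cor = 0,
                      between_cor = 0, n_pre = n_pre, n_prog = n_prog,
                      baseline_mean = 0, baseline_sd = 0, seed = seed)
  simulate_cohort(spec)
}

# independent trapezoid AUC oracle: area under the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  y <- as.integer(as.character(labels) %in% c("PROG", "1"))
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[y == 1] > t), numeric(1)), 1)
  fpr <- c(0, vapply(thr, function(t) mean(scores[y == 0] > t), numeric(1)), 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# brute-force Mann-Whitney pair statistic (ties count 1/2)
pairwise_auc <- function(scores, labels) {
  y <- as.integer(as.character(labels) %in% c("PROG", "1"))
  pos <- scores[y == 1]; neg <- scores[y == 0]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}
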