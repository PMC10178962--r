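#' Configure an end-to-end analysis run
#'
#' Bundles every tunable of the discovery / validation / pathway workflow.
#' Exactly one input source must be given: a synthetic \code{cohort_spec}
#' (the default study design) or paths to expression + annotation TSVs
#' (first pair = discovery cohort, the rest validation cohorts). The single
#' \code{seed} fans out to fixed per-stage child seeds, so any stage rerun
#' in isolation reproduces its part of a full run.
#'
#' @param spec A \code{\link{cohort_spec}} for synthetic input, or NULL.
#' @param expr_paths,annot_paths Character vectors of TSV paths, or NULL.
#' @param universe Gene universe for the exhaustive search; defaults to all
#'   cohort genes when there are at most 25, otherwise it must be supplied.
#' @param n_validation Number of synthetic validation cohorts (spec input
#'   only).
#' @param validation_location_sd,validation_log_scale_sd SDs of the random
#'   per-dataset location shift and log scale factor emulating batch
#'   distortion in the validation cohorts.
#' @param min_size,max_size,top_k Search bounds and ranking depth
#'   (\code{max_size = NULL} means the full universe).
#' @param deg_alpha DEG screen threshold (default 0.1).
#' @param pathway_alpha Pathway-selection threshold on the risk-score
#'   correlation p (default 0.05).
#' @param cutpoint_criterion Passed to \code{\link{optimal_cutpoint}}.
#' @param gmt_path Optional GMT file of gene sets; when NULL, gene sets are
#'   simulated over the cohort genes with the fitted panel planted as a
#'   positive-control set.
#' @param n_gene_sets Number of simulated gene sets.
#' @param seed Master RNG seed.
#' @return A \code{run_config} list.
#' @export
run_config <- function(spec = NULL, expr_paths = NULL, annot_paths = NULL,
                       universe = NULL, n_validation = 4L,
                       validation_location_sd = 2,
                       validation_log_scale_sd = 0.25,
                       min_size = 1L, max_size = NULL, top_k = 50L,
                       deg_alpha = 0.1, pathway_alpha = 0.05,
                       cutpoint_criterion = "youden", gmt_path = NULL,
                       n_gene_sets = 20L, seed = 1L) {
  if (is.null(spec) == is.null(expr_paths))
    stop("exactly one of 'spec' or 'expr_paths' must be given")
  if (!is.null(expr_paths)) {
    if (is.null(annot_paths) || length(annot_paths) != length(expr_paths))
      stop("'annot_paths' must accompany 'expr_paths' one-to-one")
  }
  for (a in c(deg_alpha, pathway_alpha))
    if (!(a > 0 && a <= 1)) stop("alphas must lie in (0, 1]")
  structure(list(spec = spec, expr_paths = expr_paths,
                 annot_paths = annot_paths, universe = universe,
                 n_validation = as.integer(n_validation),
                 validation_location_sd = validation_location_sd,
                 validation_log_scale_sd = validation_log_scale_sd,
                 min_size = as.integer(min_size), max_size = max_size,
                 top_k = as.integer(top_k), deg_alpha = deg_alpha,
                 pathway_alpha = pathway_alpha,
                 cutpoint_criterion = cutpoint_criterion,
                 gmt_path = gmt_path, n_gene_sets = as.integer(n_gene_sets),
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

# load or simulate the discovery cohort
config_discovery_cohort <- function(config) {
  if (!is.null(config$spec)) {
    spec <- config$spec
    spec$seed <- config$seed
    simulate_cohort(spec, dataset_id = "DISC")
  } else {
    read_expression_tsv(config$expr_paths[1], config$annot_paths[1])
  }
}

config_universe <- function(config, cohort) {
  u <- config$universe
  if (is.null(u)) {
    if (length(gene_ids(cohort)) > 25)
      stop("cohort has > 25 genes; supply 'universe' in run_config()")
    u <- gene_ids(cohort)
  }
  as.character(u)
}

#' Run the discovery stage
#'
#' Per-gene association statistics over the search universe (odds ratios,
#' Kruskal-Wallis p, BH adjustment), per-gene classifier markers (oriented
#' single-gene AUC, PPV, NPV at the optimal cutpoint), the exhaustive panel
#' search, per-sample risk scores and patient-level fold-change strata.
#' Writes \code{gene_association.tsv}, \code{gene_classifiers.tsv},
#' \code{search_ranking.tsv}, \code{panel_metrics.tsv},
#' \code{risk_scores.tsv}, \code{patient_strata.tsv} under \code{out_dir}.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory (created if needed); NULL skips writing.
#' @return List with \code{cohort}, \code{fit} (a \code{risk_panel}),
#'   \code{association}, \code{gene_classifiers}, \code{scores}, \code{fc},
#'   \code{strata}.
#' @export
run_discovery <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- config_discovery_cohort(config)
  universe <- config_universe(config, cohort)
  assoc <- suppressWarnings(gene_odds_ratios(cohort, universe))
  gene_cls <- do.call(rbind, lapply(universe, function(g) {
    m <- fit_panel_lda(cohort, g)     # orients the single-gene score
    sc <- predict(m, cohort)
    cp <- optimal_cutpoint(sc, stage_labels(cohort),
                           criterion = config$cutpoint_criterion)
    cbind(data.frame(gene = g, stringsAsFactors = FALSE),
          metrics_row(confusion_metrics(sc, stage_labels(cohort), cp)))
  }))
  max_size <- if (is.null(config$max_size)) length(universe)
              else min(config$max_size, length(universe))
  fit <- fit_risk_panel(cohort, universe, min_size = config$min_size,
                        max_size = max_size, top_k = config$top_k,
                        cutpoint_criterion = config$cutpoint_criterion)
  scores <- predict(fit, cohort)
  fc <- score_fold_change(scores, cohort)
  strata <- stratify_fc(fc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(assoc, file.path(out_dir, "gene_association.tsv"))
    write_tsv(gene_cls, file.path(out_dir, "gene_classifiers.tsv"))
    write_tsv(fit$ranking, file.path(out_dir, "search_ranking.tsv"))
    write_tsv(cbind(data.frame(panel = paste(unclass(fit$panel), collapse = ","),
                               n_evaluated = fit$n_evaluated),
                    metrics_row(fit$metrics)),
              file.path(out_dir, "panel_metrics.tsv"))
    si <- sample_info(cohort)
    write_tsv(data.frame(sample_id = names(scores),
                         patient_id = si$patient_id, dataset_id = si$dataset_id,
                         stage = as.character(si$stage), score = scores,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "risk_scores.tsv"))
    write_tsv(strata, file.path(out_dir, "patient_strata.tsv"))
  }
  list(cohort = cohort, fit = fit, association = assoc,
       gene_classifiers = gene_cls, scores = scores, fc = fc,
       strata = strata)
}

# synthetic validation cohorts with seeded batch distortion
config_validation_cohorts <- function(config) {
  if (!is.null(config$spec)) {
    if (config$n_validation < 1) return(list())
    spec <- config$spec
    spec$seed <- config$seed
    set.seed(config$seed + 500L)
    d <- config$n_validation
    loc <- stats::rnorm(d, 0, config$validation_location_sd)
    scl <- exp(stats::rnorm(d, 0, config$validation_log_scale_sd))
    if (d == 1)
      simulate_multi_cohort(spec, 2, location = c(loc, 0), scale = c(scl, 1))[1]
    else
      simulate_multi_cohort(spec, d, location = loc, scale = scl)
  } else {
    n <- length(config$expr_paths)
    if (n < 2) return(list())
    lapply(2:n, function(i)
      read_expression_tsv(config$expr_paths[i], config$annot_paths[i]))
  }
}

#' Run the validation stage
#'
#' Scores each validation cohort with the discovery coefficients and reports
#' the per-dataset validation table (Kruskal-Wallis p, odds ratio with CI,
#' BH-adjusted p-values, classifier markers) plus, when at least two
#' cohorts exist, a merged-cohort row computed on the within-dataset z-score
#' merge of discovery + validation data. Writes \code{validation.tsv}.
#'
#' @param config A \code{\link{run_config}}.
#' @param discovery Result of \code{\link{run_discovery}}.
#' @param out_dir Output directory or NULL.
#' @return List with \code{table} (per-dataset + merged rows),
#'   \code{datasets}, \code{merged}.
#' @export
run_validation <- function(config, discovery, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  datasets <- config_validation_cohorts(config)
  if (!length(datasets)) stop("no validation datasets configured")
  tab <- validate_panel(discovery$fit, datasets, refit = FALSE)
  merged <- NULL
  if (length(datasets) >= 2) {  # a merged row needs a true multi-cohort setting
    merged <- merge_common_genes(c(list(discovery$cohort), datasets))
    mrow <- validate_panel(discovery$fit, list(merged), refit = FALSE)
    mrow$dataset <- "MERGED"
    tab <- rbind(tab, mrow)
    # re-adjust across the full family incl. the merged row
    ok <- !is.na(tab$kw_p); tab$kw_p_adj[ok] <- adjust_pvalues(tab$kw_p[ok])
    ok <- !is.na(tab$or_p); tab$or_p_adj[ok] <- adjust_pvalues(tab$or_p[ok])
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, file.path(out_dir, "validation.tsv"))
  }
  list(table = tab, datasets = datasets, merged = merged)
}

#' Run the pathway stage
#'
#' DEG screen, hypergeometric over-representation, per-sample pathway
#' activity scores, selection of pathways correlated with the risk score,
#' pathway PCA index/clusters, per-stratum Kruskal-Wallis tests of selected
#' pathway scores among PROG samples, and a correlation-network export.
#' Writes \code{pathway_enrichment.tsv}, \code{pathway_scores.tsv},
#' \code{pathway_selection.tsv}, \code{pathway_pca.tsv},
#' \code{pathway_strata_tests.tsv}, \code{network.sif}.
#'
#' @param config A \code{\link{run_config}}.
#' @param discovery Result of \code{\link{run_discovery}}.
#' @param out_dir Output directory or NULL.
#' @return List with \code{degs}, \code{enrichment}, \code{scores},
#'   \code{selection}, \code{pca}, \code{strata_tests}, \code{network}.
#' @export
run_pathways <- function(config, discovery, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- discovery$cohort
  sets <- if (!is.null(config$gmt_path)) read_gene_sets(config$gmt_path)
          else simulate_gene_sets(gene_ids(cohort),
                                  n_sets = config$n_gene_sets,
                                  planted = list(PANEL_SET =
                                                   as.character(discovery$fit$panel)),
                                  seed = config$seed + 900L)
  degs <- select_degs(cohort, config$deg_alpha)
  enrichment <- if (length(degs)) ora_enrichment(degs, gene_ids(cohort), sets)
                else {
                  message("no DEGs at alpha = ", config$deg_alpha,
                          "; enrichment skipped")
                  NULL
                }
  pscores <- suppressWarnings(pathway_sample_scores(cohort, sets))
  risk <- discovery$scores
  selection <- pathways_correlated_with_score(pscores, risk,
                                              alpha = config$pathway_alpha)
  chosen <- selection$pathway[selection$selected]
  pca_input <- if (length(chosen) >= 2) pscores[chosen, , drop = FALSE]
               else pscores
  ppca <- pathway_pca_index(pca_input, stage_labels(cohort))
  strata_tests <- pathway_strata_tests(pscores[intersect(chosen, rownames(pscores)),
                                               , drop = FALSE],
                                       cohort, discovery$strata)
  net_genes <- union(as.character(discovery$fit$panel),
                     utils::head(degs, 150))
  network <- correlation_network(cohort, intersect(net_genes, gene_ids(cohort)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(enrichment))
      write_tsv(enrichment, file.path(out_dir, "pathway_enrichment.tsv"))
    write_tsv(data.frame(pathway = rownames(pscores), pscores,
                         check.names = FALSE, stringsAsFactors = FALSE),
              file.path(out_dir, "pathway_scores.tsv"))
    write_tsv(selection, file.path(out_dir, "pathway_selection.tsv"))
    write_tsv(data.frame(sample_id = names(ppca$index), index = ppca$index,
                         cluster = ppca$clusters,
                         stage = as.character(stage_labels(cohort)),
                         stringsAsFactors = FALSE),
              file.path(out_dir, "pathway_pca.tsv"))
    if (!is.null(strata_tests))
      write_tsv(strata_tests, file.path(out_dir, "pathway_strata_tests.tsv"))
    write_network(network, file.path(out_dir, "network.sif"), "sif")
  }
  list(degs = degs, enrichment = enrichment, scores = pscores,
       selection = selection, pca = ppca, strata_tests = strata_tests,
       network = network)
}

# KW of each pathway's scores among PROG samples grouped by the patient's
# fold-change stratum; NULL when fewer than two strata are populated.
pathway_strata_tests <- function(pscores, cohort, strata) {
  if (!nrow(pscores)) return(NULL)
  si <- sample_info(cohort)
  prog <- si$stage == "PROG"
  stratum <- strata$stratum[match(si$patient_id[prog], strata$patient_id)]
  keep <- !is.na(stratum)
  if (length(unique(stratum[keep])) < 2) return(NULL)
  cols <- which(prog)[keep]
  rows <- lapply(rownames(pscores), function(nm) {
    v <- pscores[nm, cols]
    kt <- if (length(unique(v)) == 1) list(statistic = 0, p.value = 1)
          else {
            k <- stats::kruskal.test(v, factor(stratum[keep]))
            list(statistic = unname(k$statistic), p.value = k$p.value)
          }
    data.frame(pathway = nm, kw_stat = kt$statistic, kw_p = kt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' Discovery, validation and pathway stages in sequence, with every table
#' written under \code{out_dir} and a \code{manifest.json} recording the
#' configuration actually used (seeds, alphas, search bounds, cutpoint
#' criterion), so any table can be regenerated from config + seed alone.
#' With a fixed seed the written reports are byte-identical across runs.
#'
#' @param config A \code{\link{run_config}}.
#' @param out_dir Output directory.
#' @return Invisibly, a list with \code{discovery}, \code{validation},
#'   \code{pathways}.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  discovery <- run_discovery(config, out_dir)
  validation <- run_validation(config, discovery, out_dir)
  pathways <- run_pathways(config, discovery, out_dir)
  manifest <- list(
    seed = config$seed,
    input = if (is.null(config$spec)) "files" else "synthetic",
    n_genes = length(gene_ids(discovery$cohort)),
    universe = config_universe(config, discovery$cohort),
    search = list(min_size = config$min_size,
                  max_size = config$max_size,
                  n_evaluated = discovery$fit$n_evaluated,
                  n_skipped = discovery$fit$n_skipped,
                  shrinkage = discovery$fit$model$shrinkage),
    alphas = list(deg = config$deg_alpha, pathway = config$pathway_alpha),
    cutpoint_criterion = config$cutpoint_criterion,
    n_validation = length(validation$datasets),
    best_panel = as.character(discovery$fit$panel))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(discovery = discovery, validation = validation,
                 pathways = pathways))
}
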