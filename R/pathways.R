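#' Select differentially expressed genes by stage
#'
#' Genes whose per-gene Kruskal-Wallis stage p-value (PROG vs PRE) falls
#' below \code{alpha} (default 0.1, a deliberately permissive screen feeding
#' the enrichment step).
#'
#' @param x An \code{expr_set}.
#' @param alpha Selection threshold on the unadjusted p-value.
#' @return Character vector of selected genes, with the per-gene p-values of
#'   all genes attached as attribute \code{p}.
#' @export
select_degs <- function(x, alpha = 0.1) {
  stopifnot(inherits(x, "expr_set"))
  g <- stage_labels(x)
  p <- apply(expr_values(x), 1, function(v) kruskal_by_stage(v, g)$p.value)
  sel <- names(p)[p < alpha]
  attr(sel, "p") <- p
  sel
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric tail test of DEG overlap with each gene set:
#' with \code{N} universe genes, \code{K} set members in the universe,
#' \code{n} DEGs and overlap \code{k}, the p-value is P(X >= k). P-values
#' are Benjamini-Hochberg adjusted across sets. Sets with no member in the
#' universe get p = 1 and a flag.
#'
#' @param degs Character vector of selected genes (must be within
#'   \code{universe}).
#' @param universe Character vector of all tested genes.
#' @param sets A \code{gene_sets} list (or named list of character vectors).
#' @return Data frame with columns \code{pathway, set_size, overlap, p,
#'   p_adj, empty_universe}.
#' @export
ora_enrichment <- function(degs, universe, sets) {
  universe <- unique(as.character(universe))
  degs <- unique(as.character(degs))
  stray <- setdiff(degs, universe)
  if (length(stray))
    stop("DEG(s) outside the universe: ", paste(stray, collapse = ", "))
  N <- length(universe); n <- length(degs)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    if (K == 0)
      return(data.frame(pathway = nm, set_size = 0L, overlap = 0L, p = 1,
                        empty_universe = TRUE, stringsAsFactors = FALSE))
    k <- length(intersect(degs, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, set_size = K, overlap = k, p = p,
               empty_universe = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(pmin(out$p, 1))
  out[, c("pathway", "set_size", "overlap", "p", "p_adj", "empty_universe")]
}

#' Single-sample pathway activity scores
#'
#' The agglomerate z-score: for each pathway and sample, the mean (or
#' another aggregator) of the member genes' z-scores, where z-scores are
#' computed per gene across samples within each dataset. Pathways with no
#' member gene in the matrix are dropped with a warning.
#'
#' @param x An \code{expr_set}.
#' @param sets A \code{gene_sets} list.
#' @param aggregator Function reducing a vector of member z-scores to one
#'   number (default \code{mean}; \code{median} is the common robust
#'   alternative).
#' @return Numeric matrix, pathways x samples, with attribute
#'   \code{n_members} (genes actually used per pathway).
#' @export
pathway_sample_scores <- function(x, sets, aggregator = mean) {
  stopifnot(inherits(x, "expr_set"))
  z <- zscore_values(expr_values(x), sample_info(x)$dataset_id)
  dropped <- attr(z, "dropped_genes")
  if (length(dropped)) z <- z[setdiff(rownames(z), dropped), , drop = FALSE]
  present <- lapply(sets, function(s) intersect(unique(s), rownames(z)))
  empty <- names(sets)[vapply(present, length, integer(1)) == 0]
  if (length(empty)) {
    warning("pathway(s) with no member in the matrix dropped: ",
            paste(empty, collapse = ", "))
    present <- present[setdiff(names(sets), empty)]
  }
  if (!length(present)) stop("no pathway has members in the matrix")
  scores <- t(vapply(present,
                     function(m) apply(z[m, , drop = FALSE], 2, aggregator),
                     numeric(ncol(z))))
  colnames(scores) <- colnames(z)
  attr(scores, "n_members") <- vapply(present, length, integer(1))
  scores
}

#' Select pathways correlated with a risk score
#'
#' Spearman correlation of each pathway's per-sample activity score with a
#' per-sample risk score; pathways with correlation p below \code{alpha} are
#' selected. Constant pathway scores have undefined rho and are excluded
#' with a flag. Family-wise handling is optional: \code{adjust = TRUE}
#' applies the threshold to BH-adjusted p-values.
#'
#' @param scores Pathway x sample matrix (from
#'   \code{\link{pathway_sample_scores}}).
#' @param risk Named per-sample risk scores covering the matrix columns.
#' @param alpha Selection threshold (default 0.05).
#' @param adjust Apply BH adjustment before thresholding (default FALSE).
#' @return Data frame with \code{pathway, rho, p, p_adj, selected,
#'   degenerate}.
#' @export
pathways_correlated_with_score <- function(scores, risk, alpha = 0.05,
                                           adjust = FALSE) {
  if (!is.null(names(risk))) {
    miss <- setdiff(colnames(scores), names(risk))
    if (length(miss)) stop("risk scores missing for sample(s): ",
                           paste(miss, collapse = ", "))
    risk <- risk[colnames(scores)]
  } else if (length(risk) != ncol(scores)) {
    stop("'risk' must align with the score matrix columns")
  }
  rows <- lapply(rownames(scores), function(nm) {
    v <- scores[nm, ]
    if (stats::sd(v) == 0)
      return(data.frame(pathway = nm, rho = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    ct <- suppressWarnings(stats::cor.test(v, risk, method = "spearman",
                                           exact = FALSE))
    data.frame(pathway = nm, rho = unname(ct$estimate), p = ct$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  ok <- !out$degenerate
  if (any(ok)) out$p_adj[ok] <- adjust_pvalues(out$p[ok])
  crit <- if (adjust) out$p_adj else out$p
  out$selected <- !out$degenerate & crit < alpha
  out[, c("pathway", "rho", "p", "p_adj", "selected", "degenerate")]
}

#' Pathway PCA index and sample clusters
#'
#' PCA of the samples-by-pathways activity matrix (centered, unscaled: the
#' activity scores share the z-score scale). The index is the sign-fixed PC1
#' sample score; samples are clustered by complete-linkage hierarchical
#' clustering on the first two components (k = 3 by default). Stage
#' association is tested by Kruskal-Wallis on the index and by a rank test
#' of the stage indicator across clusters.
#'
#' @param scores Pathway x sample matrix.
#' @param labels PRE/PROG labels aligned with the samples.
#' @param k Number of sample clusters (default 3).
#' @return Object of class \code{pathway_pca}: list with \code{index}
#'   (named per-sample PC1 score), \code{clusters}, \code{pca}
#'   (\code{panel_pca}), \code{index_test}, \code{cluster_test},
#'   \code{variance_explained_12}.
#' @export
pathway_pca_index <- function(scores, labels, k = 3L) {
  if (nrow(scores) < 2) stop("need at least 2 pathways")
  if (ncol(scores) < 3) stop("need at least 3 samples")
  es <- expression_set(scores,
                       data.frame(sample_id = colnames(scores),
                                  stage = as.character(labels),
                                  stringsAsFactors = FALSE))
  pca <- panel_pca(es, scale. = FALSE)
  index <- stats::setNames(pca$scores[, 1], colnames(scores))
  pc12 <- pca$scores[, seq_len(min(2, ncol(pca$scores))), drop = FALSE]
  tree <- stats::hclust(stats::dist(pc12), method = "complete")
  clusters <- stats::cutree(tree, k = min(k, ncol(scores)))
  y <- as_binary_labels(as.character(labels))
  cluster_test <- if (length(unique(clusters)) > 1 && length(unique(y)) > 1) {
    kt <- stats::kruskal.test(y, factor(clusters))  # clusters may be singletons
    list(statistic = unname(kt$statistic), p.value = kt$p.value)
  } else list(statistic = 0, p.value = 1)
  structure(list(index = index, clusters = clusters, pca = pca,
                 index_test = pc_separation_test(pca, labels, 1L),
                 cluster_test = cluster_test,
                 variance_explained_12 =
                   sum(pca$variance_explained[seq_len(min(2, length(pca$variance_explained)))])),
            class = "pathway_pca")
}

#' @export
print.pathway_pca <- function(x, ...) {
  cat(sprintf("pathway_pca: %d samples, %d clusters; PC1+PC2 explain %.1f%% of variance\n",
              length(x$index), length(unique(x$clusters)),
              100 * x$variance_explained_12))
  cat(sprintf("  index vs stage: KW p = %.3g\n", x$index_test$p.value))
  invisible(x)
}

#' Gene correlation network above a threshold
#'
#' Undirected edges between gene pairs whose Spearman correlation exceeds
#' the threshold in absolute value (strict inequality). Zero-variance genes
#' are excluded with a flag; edges are emitted in deterministic
#' (row-major, gene-sorted) order.
#'
#' @param x An \code{expr_set} (>= 3 samples).
#' @param genes Genes to include (default: all).
#' @param threshold Absolute-correlation threshold (default 0.3).
#' @return Data frame with \code{gene_a, gene_b, rho}; excluded genes in
#'   attribute \code{excluded}.
#' @export
correlation_network <- function(x, genes = gene_ids(x), threshold = 0.3) {
  genes <- sort(unique(as.character(genes)))
  sm <- spearman_matrix(x, genes)
  excluded <- sm$degenerate
  keep <- setdiff(genes, excluded)
  rho <- sm$rho[keep, keep, drop = FALSE]
  edges <- which(upper.tri(rho) & abs(rho) > threshold, arr.ind = TRUE)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  out <- data.frame(gene_a = keep[edges[, 1]], gene_b = keep[edges[, 2]],
                    rho = rho[edges], stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

#' Export a correlation network
#'
#' @param edges Edge data frame from \code{\link{correlation_network}}.
#' @param path Output file.
#' @param format \code{"sif"} (tab-separated \code{gene_a interacts gene_b})
#'   or \code{"graphml"}.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(edges, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\tcor\t%s", edges$gene_a, edges$gene_b)
    writeLines(lines, path)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
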