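#' Z-score expression within each dataset
#'
#' Per-gene centering and unit-SD scaling (sample SD, n-1) computed across
#' all samples of each dataset, both stages pooled — standardizing within
#' stage would erase the PRE/PROG effect the analysis measures. Genes with
#' zero variance in any dataset are dropped and reported via the
#' \code{dropped_genes} attribute.
#'
#' Idempotent up to floating point: z-scoring twice equals z-scoring once.
#'
#' @param x An \code{expr_set} (possibly spanning several dataset ids).
#' @return A z-scored \code{expr_set} with a \code{dropped_genes} attribute.
#' @export
zscore_within_dataset <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  z <- zscore_values(expr_values(x), sample_info(x)$dataset_id)
  dropped <- attr(z, "dropped_genes")
  if (length(dropped)) {
    warning("dropping zero-variance gene(s): ", paste(dropped, collapse = ", "))
    z <- z[setdiff(rownames(z), dropped), , drop = FALSE]
  }
  out <- expression_set(z, sample_info(x))
  attr(out, "dropped_genes") <- dropped
  out
}

#' Merge cohorts on common genes after z-scoring
#'
#' The multi-cohort construction: each dataset is z-scored within itself
#' (\code{\link{zscore_within_dataset}}), restricted to the intersection of
#' gene universes (sorted, deterministic order), and column-concatenated.
#' Sample and dataset ids are preserved; per-dataset affine distortions
#' \code{a*x + b} (a > 0) of any gene are removed exactly by construction.
#'
#' @param datasets List of at least two \code{expr_set} cohorts with
#'   distinct sample ids.
#' @return An \code{expr_set} whose \code{provenance} attribute records the
#'   source dataset ids and per-dataset sample counts.
#' @export
merge_common_genes <- function(datasets) {
  if (!is.list(datasets) || length(datasets) < 2)
    stop("need at least 2 datasets to merge")
  stopifnot(all(vapply(datasets, inherits, logical(1), "expr_set")))
  gene_sets <- lapply(datasets, gene_ids)
  common <- sort(Reduce(intersect, gene_sets))
  if (!length(common))
    stop("gene intersection is empty; per-dataset gene counts: ",
         paste(vapply(gene_sets, length, integer(1)), collapse = ", "))
  zmats <- lapply(datasets, function(d) {
    z <- suppressWarnings(zscore_within_dataset(d[common, ]))
    if (length(attr(z, "dropped_genes")))
      stop("zero-variance gene(s) within a dataset: ",
           paste(attr(z, "dropped_genes"), collapse = ", "))
    z
  })
  values <- do.call(cbind, lapply(zmats, expr_values))
  samples <- do.call(rbind, lapply(zmats, sample_info))
  if (anyDuplicated(samples$sample_id))
    stop("sample ids clash across datasets; make them unique before merging")
  out <- expression_set(values, samples)
  attr(out, "provenance") <- data.frame(
    dataset_id = vapply(datasets, function(d)
      paste(unique(sample_info(d)$dataset_id), collapse = "+"), character(1)),
    n_samples = vapply(datasets, function(d) ncol(expr_values(d)), integer(1)),
    stringsAsFactors = FALSE)
  out
}
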