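#' Construct an expression set
#'
#' The central data container of the package: a numeric gene-by-sample
#' expression matrix plus per-sample metadata. Values are expected on a
#' normalized (log-like) scale; the container is agnostic to the platform
#' that produced them.
#'
#' @param values Numeric matrix, genes as rows (unique rownames = gene
#'   symbols), samples as columns (unique colnames = sample ids). No missing
#'   values are allowed: missing data is a hard error here, never silently
#'   propagated into downstream statistics.
#' @param samples Data frame of per-sample metadata with columns
#'   \code{sample_id}, \code{stage} (one of \code{"PRE"}, \code{"PROG"}),
#'   and optionally \code{patient_id} (defaults to \code{sample_id}) and
#'   \code{dataset_id} (defaults to \code{"D1"}). Every column of
#'   \code{values} must have a matching row.
#'
#' @return An object of class \code{expr_set}: a list with elements
#'   \code{values} (the matrix) and \code{samples} (the metadata, ordered
#'   to match the matrix columns).
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("A", "B"), c("s1", "s2", "s3")))
#' ann <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                   stage = c("PRE", "PRE", "PROG"))
#' es <- expression_set(m, ann)
expression_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains missing or non-finite values; ",
         "missing data must be resolved before analysis")
  if (!is.data.frame(samples))
    stop("'samples' must be a data.frame")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  required <- c("sample_id", "stage")
  miss <- setdiff(required, names(samples))
  if (length(miss))
    stop("sample annotation lacks column(s): ", paste(miss, collapse = ", "))
  samples$sample_id <- as.character(samples$sample_id)
  if (!("patient_id" %in% names(samples))) samples$patient_id <- samples$sample_id
  if (!("dataset_id" %in% names(samples))) samples$dataset_id <- "D1"
  samples$patient_id <- as.character(samples$patient_id)
  samples$dataset_id <- as.character(samples$dataset_id)
  stage <- as.character(samples$stage)
  bad_stage <- setdiff(unique(stage), c("PRE", "PROG"))
  if (length(bad_stage))
    stop("unknown stage label(s): ", paste(bad_stage, collapse = ", "),
         " (expected PRE or PROG)")
  samples$stage <- factor(stage, levels = c("PRE", "PROG"))
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample ids in annotation")
  unann <- setdiff(colnames(values), samples$sample_id)
  if (length(unann))
    stop("samples present in matrix but absent from annotation: ",
         paste(unann, collapse = ", "))
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  tab <- table(x$samples$stage)
  cat(sprintf("expr_set: %d genes x %d samples (%d PRE, %d PROG), %d dataset(s)\n",
              nrow(x$values), ncol(x$values), tab[["PRE"]], tab[["PROG"]],
              length(unique(x$samples$dataset_id))))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Accessors for expr_set objects
#'
#' @param x An \code{expr_set}.
#' @return \code{expr_values}: the numeric matrix; \code{sample_info}: the
#'   metadata data frame; \code{stage_labels}: the PRE/PROG factor aligned to
#'   the matrix columns; \code{gene_ids}: the gene symbols.
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  x$values
}

#' @rdname expr_values
#' @export
sample_info <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  x$samples
}

#' @rdname expr_values
#' @export
stage_labels <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  x$samples$stage
}

#' @rdname expr_values
#' @export
gene_ids <- function(x) {
  stopifnot(inherits(x, "expr_set"))
  rownames(x$values)
}

#' Subset an expression set
#'
#' @param x An \code{expr_set}.
#' @param i Gene selector (names, indices or logical).
#' @param j Sample selector.
#' @param ... Ignored.
#' @export
`[.expr_set` <- function(x, i, j, ...) {
  v <- x$values
  if (missing(i)) i <- seq_len(nrow(v))
  if (missing(j)) j <- seq_len(ncol(v))
  if (is.character(i)) {
    missing_genes <- setdiff(i, rownames(v))
    if (length(missing_genes))
      stop("genes not present: ", paste(missing_genes, collapse = ", "))
  }
  v <- v[i, j, drop = FALSE]
  s <- x$samples[match(colnames(v), x$samples$sample_id), , drop = FALSE]
  rownames(s) <- NULL
  structure(list(values = v, samples = s), class = "expr_set")
}

# internal: 0/1 indicator of PROG per sample
stage01 <- function(x) as.integer(stage_labels(x) == "PROG")

# internal: per-gene z-score computed within each dataset (sample SD, n-1).
# Genes with zero variance in any dataset are reported via the
# "dropped_genes" attribute and removed.
zscore_values <- function(values, dataset_id) {
  out <- values
  degenerate <- character(0)
  for (d in unique(dataset_id)) {
    cols <- which(dataset_id == d)
    sub <- values[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    degenerate <- union(degenerate, rownames(values)[sdv == 0])
    out[, cols] <- (sub - mu) / sdv
  }
  attr(out, "dropped_genes") <- degenerate
  out
}
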