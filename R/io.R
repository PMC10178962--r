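#' Read an expression matrix with sample annotations
#'
#' Expression files are UTF-8 tab-separated text: the first column holds gene
#' symbols, the header row holds sample ids. The annotation file is keyed by
#' \code{sample_id} and must carry a \code{stage} column (\code{PRE} or
#' \code{PROG}); \code{patient_id} and \code{dataset_id} are optional.
#' Loading never silently drops genes or samples: duplicated gene symbols,
#' non-numeric cells, missing annotations and unknown stage labels are all
#' hard errors.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the sample-annotation TSV.
#' @return An \code{\link{expression_set}}.
#' @export
read_expression_tsv <- function(path, annotation_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2) stop("expression file has no sample columns: ", path)
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene symbol(s) in ", path, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  body <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                   dimnames = list(genes, colnames(body))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s' in %s",
                 genes[bad[1]], colnames(body)[bad[2]], path))
  }
  ann <- utils::read.delim(annotation_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  expression_set(values, ann)
}

#' Write an expression set as TSV
#'
#' Serializes the matrix and annotations as two tab-separated files. Floats
#' are written with 17 significant digits so that a write/read round trip is
#' lossless (bit-identical values, byte-identical re-serialization).
#'
#' @param x An \code{expr_set}.
#' @param path Output path for the expression TSV.
#' @param annotation_path Output path for the annotation TSV.
#' @return Invisibly, \code{x}.
#' @export
write_expression_tsv <- function(x, path, annotation_path) {
  stopifnot(inherits(x, "expr_set"))
  if (ncol(x$values) == 0L) stop("refusing to write an expression set with no samples")
  vals <- x$values
  chr <- vapply(seq_len(ncol(vals)),
                function(j) sprintf("%.17g", vals[, j]), character(nrow(vals)))
  chr <- matrix(chr, nrow = nrow(vals),
                dimnames = list(rownames(vals), colnames(vals)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("gene", colnames(vals)), collapse = "\t"), con)
  writeLines(paste(rownames(vals),
                   apply(chr, 1, paste, collapse = "\t"), sep = "\t"), con)
  utils::write.table(x$samples, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(x)
}

#' Read a gene panel from plain text
#'
#' One gene per line. Lines of the form \code{"ALIAS/SYMBOL"} resolve to the
#' final \code{/}-separated token; a small built-in alias map translates
#' protein-style names from oncology antibody arrays (e.g. \code{P53},
#' \code{GM-CSF}, \code{ICAM-1}, \code{Endoglin/CD105}) to HGNC symbols.
#' Matching elsewhere in the package is case-sensitive and exact.
#'
#' @param path Path to the panel file.
#' @param name Panel name (defaults to the file name).
#' @return A character vector of gene symbols with class \code{gene_panel}.
#' @export
read_panel <- function(path, name = basename(path)) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("panel file is empty: ", path)
  genes <- vapply(lines, resolve_gene_alias, character(1), USE.NAMES = FALSE)
  gene_panel(genes, name = name)
}

# protein-name -> HGNC translations for panels written with antibody-array
# labels; applied to the full line before the "last /-token" fallback.
PANEL_ALIASES <- c(
  "Endoglin/CD105" = "ENG",
  "CXCL8/IL8"      = "CXCL8",
  "SPARC/BM-40"    = "SPARC",
  "HO-1/HMOX1"     = "HMOX1",
  "P53"            = "TP53",
  "GM-CSF"         = "CSF2",
  "ICAM-1"         = "ICAM1",
  "DKK-1"          = "DKK1"
)

resolve_gene_alias <- function(label) {
  if (label %in% names(PANEL_ALIASES)) return(unname(PANEL_ALIASES[label]))
  parts <- strsplit(label, "/", fixed = TRUE)[[1]]
  parts[length(parts)]
}

#' Construct a gene panel
#'
#' @param genes Character vector of gene symbols; must be non-empty with no
#'   duplicates.
#' @param name Panel name.
#' @return A \code{gene_panel} (character vector with a \code{name} attribute).
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- as.character(genes)
  if (!length(genes)) stop("a gene panel must contain at least one gene")
  if (anyDuplicated(genes))
    stop("duplicate gene(s) in panel: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  structure(genes, name = name, class = c("gene_panel", "character"))
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("gene_panel '%s' (%d genes): %s\n", attr(x, "name"), length(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated, fields = name, description,
#' members... Empty sets, duplicated set names and malformed lines are
#' rejected.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class \code{gene_sets}).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d (need name, description, >=1 member)", i))
    nms[i] <- fields[1]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nms))
    stop("duplicate pathway name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  structure(sets, class = c("gene_sets", "list"))
}

#' Write gene sets in GMT format
#'
#' @param sets A named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description column (recycled).
#' @return Invisibly, \code{path}.
#' @export
write_gene_sets <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
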