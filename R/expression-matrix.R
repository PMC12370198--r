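#' Expression matrix container
#'
#' A light container for a gene-by-sample expression matrix with an explicit
#' unit tag, the currency of every pipeline stage. Units form a small closed
#' vocabulary: `counts` (raw), `normalized_counts` (after size factors),
#' `tpm` (transcripts per million; full-transcriptome columns sum to 1e6),
#' `log2` and `zscore` (transformed scales, may be negative).
#'
#' @param values numeric matrix, genes as rows, samples as columns, with
#'   unique non-empty dimnames.
#' @param unit one of `"counts"`, `"normalized_counts"`, `"tpm"`, `"log2"`,
#'   `"zscore"`.
#' @param gene_lengths optional positive numeric vector of gene lengths in
#'   kilobases, named by or aligned to the rows of `values`.
#' @param gene_subset logical; `TRUE` marks a matrix restricted to a gene
#'   subset (e.g. the IC panel), which waives the TPM column-sum invariant.
#' @return An object of class `ic_expr`.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, "counts")
#' @export
expression_matrix <- function(values, unit, gene_lengths = NULL,
                              gene_subset = FALSE) {
  unit <- match.arg(unit, expr_units())
  if (!is.matrix(values) || !is.numeric(values))
    stop_icsig("`values` must be a numeric matrix")
  storage.mode(values) <- "double"
  gn <- rownames(values); sn <- colnames(values)
  if (is.null(gn) || is.null(sn))
    stop_icsig("`values` must have gene row names and sample column names")
  if (anyDuplicated(gn))
    stop_icsig("duplicate gene id(s): ",
               paste(unique(gn[duplicated(gn)]), collapse = ", "))
  if (anyDuplicated(sn))
    stop_icsig("duplicate sample id(s): ",
               paste(unique(sn[duplicated(sn)]), collapse = ", "))
  if (anyNA(values))
    stop_icsig("expression matrices may not contain missing values; ",
               "encode absent genes as explicit zero rows")
  if (unit %in% c("counts", "normalized_counts", "tpm") && any(values < 0))
    stop_icsig("negative values are not allowed for unit '", unit, "'")
  if (!is.null(gene_lengths)) {
    if (!is.null(names(gene_lengths))) {
      missing <- setdiff(gn, names(gene_lengths))
      if (length(missing))
        stop_icsig("gene_lengths missing for: ",
                   paste(missing, collapse = ", "))
      gene_lengths <- gene_lengths[gn]
    } else if (length(gene_lengths) != nrow(values)) {
      stop_icsig("gene_lengths must align with the gene rows")
    } else names(gene_lengths) <- gn
    if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
      stop_icsig("gene_lengths must be positive and finite")
  }
  if (unit == "tpm" && !gene_subset && ncol(values) > 0) {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e-6 * 1e6
    if (any(bad))
      stop_icsig("TPM columns must sum to 1e6 (off: ",
                 paste(sn[bad], collapse = ", "),
                 "); pass gene_subset = TRUE for gene-subset matrices")
  }
  structure(list(values = values, unit = unit, gene_lengths = gene_lengths,
                 gene_subset = isTRUE(gene_subset)),
            class = "ic_expr")
}

expr_units <- function() c("counts", "normalized_counts", "tpm", "log2", "zscore")

#' @export
dim.ic_expr <- function(x) dim(x$values)

#' @export
print.ic_expr <- function(x, ...) {
  cat(sprintf("<ic_expr> %d genes x %d samples, unit = %s%s\n",
              nrow(x$values), ncol(x$values), x$unit,
              if (x$gene_subset) " (gene subset)" else ""))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ic_expr` object.
#' @param genes,samples character vectors of ids to keep (default: all).
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "ic_expr"))
  v <- x$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop_icsig("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stop_icsig("sample(s) absent from matrix: ", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  subset_flag <- x$gene_subset || (!is.null(genes) && nrow(v) < nrow(x$values))
  expression_matrix(v, x$unit,
                    gene_lengths = if (!is.null(x$gene_lengths)) x$gene_lengths[rownames(v)],
                    gene_subset = subset_flag)
}

#' Read and write expression matrices as TSV
#'
#' The on-disk format is UTF-8 tab-delimited text: a header line
#' `gene_id<TAB>sample1<TAB>...`, one row per gene, decimal point (never
#' decimal comma), no quoting. Row and column order are preserved.
#'
#' @param path file path.
#' @param unit declared unit of the stored values (see [expression_matrix()]).
#' @param gene_subset logical, see [expression_matrix()].
#' @return `read_expression_tsv()` returns an `ic_expr`;
#'   `write_expression_tsv()` returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, unit, gene_subset = FALSE) {
  if (!file.exists(path)) stop_icsig("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop_icsig("expected a gene_id column plus >= 1 sample")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(gene_ids))
    stop_icsig("duplicate gene id(s) in ", path, ": ",
               paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop_icsig("duplicate sample id(s) in ", path, ": ",
               paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop_icsig(sprintf("non-numeric cell at gene '%s', sample '%s': '%s'",
                       gene_ids[idx[1L]], sample_ids[idx[2L]],
                       body[idx[1L], idx[2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num, unit, gene_subset = gene_subset)
}

#' @rdname read_expression_tsv
#' @param x an `ic_expr` object.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(inherits(x, "ic_expr"))
  df <- data.frame(gene_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
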