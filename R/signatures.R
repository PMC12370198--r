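#' Median IC signatures per cancer type
#'
#' The unit of cross-species comparison: for every cancer type, a vector of
#' per-gene medians computed on per-gene z-scored expression. Z-scoring before
#' taking medians gives every gene equal weight in the downstream correlation,
#' regardless of its absolute abundance. Restriction to the IC panel happens
#' before z-scoring (so the standardization reflects the analyzed genes);
#' panel genes absent from the matrix are listed and excluded with a warning.
#'
#' @param mat an [expression_matrix()], typically TPM.
#' @param ann a [sample_annotation()].
#' @param ic_genes character vector of panel gene ids (default: all genes).
#' @param zscore z-score per gene before taking medians (default `TRUE`).
#' @return An `ic_grouped` of class `median` signatures (cancer type x gene).
#' @export
median_signatures <- function(mat, ann, ic_genes = NULL, zscore = TRUE) {
  stopifnot(inherits(mat, "ic_expr"))
  if (!is.null(ic_genes)) {
    absent <- setdiff(ic_genes, rownames(mat$values))
    if (length(absent))
      warning("panel gene(s) absent from matrix, excluded: ",
              paste(absent, collapse = ", "), call. = FALSE)
    keep <- intersect(ic_genes, rownames(mat$values))
    if (length(keep) == 0L) stop_icsig("no panel gene present in the matrix")
    mat <- subset_expression(mat, genes = keep)
  }
  if (zscore) mat <- zscore_per_gene(mat)
  group_statistic(mat, ann, "median")
}

#' Pearson correlation distance between signatures
#'
#' `d(a, b) = 1 - r(sig_a, sig_b)` with centered Pearson correlation, so 0
#' means identical expression pattern and 2 perfectly opposed. Correlation
#' compares patterns rather than absolute levels, which is what makes relative
#' IC profiles comparable across species and normalization schemes.
#'
#' @param signatures an `ic_grouped` (cancer type x gene) or a plain numeric
#'   matrix with row labels.
#' @return An object of class `ic_dist`: list with `matrix` (symmetric, zero
#'   diagonal, entries in \[0, 2\]) and `labels`.
#' @export
correlation_distance <- function(signatures) {
  v <- if (inherits(signatures, "ic_grouped")) signatures$values else signatures
  if (!is.matrix(v) || is.null(rownames(v)))
    stop_icsig("`signatures` must be a labelled matrix or ic_grouped")
  if (ncol(v) < 3L)
    stop_icsig("Pearson correlation needs >= 3 genes per signature vector")
  if (ncol(v) < 5L)
    warning("correlation over only ", ncol(v),
            " genes is statistically fragile", call. = FALSE)
  const <- matrixStats::rowSds(v) == 0
  if (any(const))
    stop_icsig("constant signature vector(s): ",
               paste(rownames(v)[const], collapse = ", "))
  d <- 1 - stats::cor(t(v))
  d[d < 0] <- 0          # guard against -1e-16 style float noise
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(matrix = d, labels = rownames(v)), class = "ic_dist")
}

#' @export
print.ic_dist <- function(x, ...) {
  cat(sprintf("<ic_dist> %d labels, range [%.3g, %.3g]\n",
              length(x$labels), min(x$matrix), max(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' @rdname correlation_distance
#' @param x an `ic_dist`.
#' @param path output TSV path (types x types, lower = more similar).
#' @export
write_distance_tsv <- function(x, path) {
  stopifnot(inherits(x, "ic_dist"))
  df <- data.frame(cancer_type = x$labels, x$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
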