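#' Median-of-ratios size factors
#'
#' Library size/composition normalization for raw counts: for each sample the
#' factor is the median, over genes expressed in every sample, of the ratio of
#' that sample's count to the gene's geometric mean across samples. Genes with
#' any zero count are excluded from the reference set (they have no finite
#' log geometric mean). Dividing each column by its factor makes libraries
#' comparable across sequencing depths and compositions.
#'
#' @param mat an [expression_matrix()] with unit `"counts"` and >= 2 samples.
#' @return `size_factors()`: a named positive numeric vector, one factor per
#'   sample. `apply_size_factors()`: an `ic_expr` with unit
#'   `"normalized_counts"`.
#' @examples
#' m <- matrix(c(10, 30, 20, 60), 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' size_factors(expression_matrix(m, "counts"))  # 0.7071 1.4142
#' @export
size_factors <- function(mat) {
  stopifnot(inherits(mat, "ic_expr"))
  if (mat$unit != "counts")
    stop_icsig("size factors are defined on raw counts, got unit '",
               mat$unit, "'")
  v <- mat$values
  if (ncol(v) < 2L) stop_icsig("need >= 2 samples to estimate size factors")
  all_pos <- matrixStats::rowAlls(v > 0)
  if (!any(all_pos))
    stop_icsig("no gene has positive counts in every sample; ",
               "filter samples or genes before normalizing")
  lv <- log(v[all_pos, , drop = FALSE])
  log_geomean <- rowMeans(lv)
  sf <- exp(matrixStats::colMedians(lv - log_geomean))
  names(sf) <- colnames(v)
  sf
}

#' @rdname size_factors
#' @param sf a named size-factor vector as returned by `size_factors()`.
#' @export
apply_size_factors <- function(mat, sf) {
  stopifnot(inherits(mat, "ic_expr"))
  missing <- setdiff(colnames(mat$values), names(sf))
  if (length(missing))
    stop_icsig("no size factor for sample(s): ", paste(missing, collapse = ", "))
  sf <- sf[colnames(mat$values)]
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop_icsig("size factors must be positive and finite")
  expression_matrix(sweep(mat$values, 2L, sf, "/"), "normalized_counts",
                    gene_lengths = mat$gene_lengths,
                    gene_subset = mat$gene_subset)
}

#' Transcripts-per-million conversion
#'
#' Divides counts by gene length (kilobases), then rescales each sample so the
#' column sums to 1e6. TPM is a within-sample relative abundance: doubling all
#' lengths or multiplying a library by a constant leaves it unchanged.
#'
#' @param mat an [expression_matrix()] with unit `"counts"` or
#'   `"normalized_counts"`.
#' @param gene_lengths positive lengths (kb) named by gene; defaults to the
#'   lengths stored in `mat`.
#' @return An `ic_expr` with unit `"tpm"`.
#' @export
to_tpm <- function(mat, gene_lengths = NULL) {
  stopifnot(inherits(mat, "ic_expr"))
  if (!mat$unit %in% c("counts", "normalized_counts"))
    stop_icsig("TPM conversion expects counts, got unit '", mat$unit, "'")
  gene_lengths <- gene_lengths %||% mat$gene_lengths
  if (is.null(gene_lengths))
    stop_icsig("gene lengths are required for TPM conversion")
  if (!is.null(names(gene_lengths))) {
    missing <- setdiff(rownames(mat$values), names(gene_lengths))
    if (length(missing))
      stop_icsig("gene_lengths missing for: ", paste(missing, collapse = ", "))
    gene_lengths <- gene_lengths[rownames(mat$values)]
  } else if (length(gene_lengths) != nrow(mat$values)) {
    stop_icsig("gene_lengths must align with the gene rows")
  }
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop_icsig("gene lengths must be positive and finite")
  rate <- mat$values / gene_lengths
  depth <- colSums(rate)
  zero <- depth == 0
  if (any(zero))
    stop_icsig("zero-depth column(s): ",
               paste(colnames(mat$values)[zero], collapse = ", "))
  tpm <- sweep(rate, 2L, depth, "/") * 1e6
  expression_matrix(tpm, "tpm", gene_lengths = stats::setNames(
    gene_lengths, rownames(mat$values)))
}

#' Log2 and per-gene z-score transforms
#'
#' `log2_transform()` maps every value to `log2(value + pseudocount)`
#' (pseudocount 1 by default, so zeros stay zero). `zscore_per_gene()`
#' centers and scales each gene row to mean 0 and sample (n-1) standard
#' deviation 1; constant rows become all-zero with a warning.
#'
#' @param mat an [expression_matrix()] with non-negative values.
#' @param pseudocount positive offset added before taking logs.
#' @return An `ic_expr` with unit `"log2"` or `"zscore"`.
#' @export
log2_transform <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "ic_expr"))
  assert_scalar_number(pseudocount, "pseudocount")
  if (pseudocount <= 0) stop_icsig("`pseudocount` must be > 0")
  if (any(mat$values < 0))
    stop_icsig("log2 transform requires non-negative input")
  expression_matrix(log2(mat$values + pseudocount), "log2",
                    gene_lengths = mat$gene_lengths,
                    gene_subset = mat$gene_subset)
}

#' @rdname log2_transform
#' @export
zscore_per_gene <- function(mat) {
  stopifnot(inherits(mat, "ic_expr"))
  v <- mat$values
  if (ncol(v) < 2L) stop_icsig("z-scoring needs >= 2 samples")
  mu <- rowMeans(v)
  sd <- matrixStats::rowSds(v)
  const <- sd == 0
  if (any(const)) {
    warning("constant gene row(s) mapped to zero: ",
            paste(rownames(v)[const], collapse = ", "), call. = FALSE)
    sd[const] <- 1
  }
  z <- (v - mu) / sd
  expression_matrix(z, "zscore", gene_lengths = mat$gene_lengths,
                    gene_subset = mat$gene_subset)
}

#' Mean-normalization of per-type summaries
#'
#' Equalizes the contribution of genes with very different inherent abundance:
#' for each gene, per-cancer-type means are divided by the mean of those means
#' across all cancer types, so every gene's cross-type mean becomes exactly 1.
#' Genes whose reference mean is zero carry no signal and are dropped with a
#' warning.
#'
#' @param grouped an `ic_grouped` with `statistic = "mean"` (see
#'   [group_statistic()]).
#' @return An `ic_grouped` of dimensionless mean-normalized scores.
#' @export
mean_normalized_scores <- function(grouped) {
  stopifnot(inherits(grouped, "ic_grouped"))
  if (grouped$statistic != "mean")
    stop_icsig("mean-normalization is defined on per-type means")
  v <- grouped$values
  if (any(v < 0)) stop_icsig("reference means must be non-negative")
  ref <- colMeans(v)
  drop <- ref == 0
  if (any(drop)) {
    warning("gene(s) with zero mean across cancer types dropped: ",
            paste(colnames(v)[drop], collapse = ", "), call. = FALSE)
    v <- v[, !drop, drop = FALSE]
    ref <- ref[!drop]
  }
  if (ncol(v) == 0L) stop_icsig("no gene left after dropping zero-mean genes")
  out <- sweep(v, 2L, ref, "/")
  grouped_stat_matrix(out, "mean", unit = "mean_normalized",
                      species = grouped$species)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
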