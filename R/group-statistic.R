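#' Per-cancer-type summary statistics
#'
#' Collapses a gene-by-sample matrix to a cancer-type-by-gene matrix of
#' per-type means or medians -- the "signature" building block. The median of
#' an even-sized group is the mean of the two central values. Cancer types
#' present in the annotation but absent from the matrix are dropped with a
#' warning (never silently reported as zero).
#'
#' @param mat an [expression_matrix()].
#' @param ann a [sample_annotation()] covering every sample of `mat`.
#' @param statistic `"mean"` or `"median"`.
#' @return An object of class `ic_grouped`: a list with `values`
#'   (cancer type x gene matrix), `statistic`, `unit`, and `species` (named
#'   by cancer type).
#' @examples
#' m <- matrix(c(1, 2, 9, 4), 1, 4,
#'             dimnames = list("g", paste0("s", 1:4)))
#' ann <- sample_annotation(paste0("s", 1:4), "canine",
#'                          c("A", "A", "A", "B"))
#' group_statistic(expression_matrix(m, "tpm", gene_subset = TRUE),
#'                 ann, "median")
#' @export
group_statistic <- function(mat, ann, statistic = c("mean", "median")) {
  stopifnot(inherits(mat, "ic_expr"))
  statistic <- match.arg(statistic)
  check_annotated(mat, ann)
  all_types <- unique(ann$cancer_type)
  ann <- ann[match(colnames(mat$values), ann$sample_id), , drop = FALSE]
  types <- unique(ann$cancer_type)
  empty <- setdiff(all_types, types)
  if (length(empty))
    warning("cancer type(s) with no samples in the matrix excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  out <- matrix(NA_real_, length(types), nrow(mat$values),
                dimnames = list(types, rownames(mat$values)))
  for (ty in types) {
    cols <- which(ann$cancer_type == ty)
    sub <- mat$values[, cols, drop = FALSE]
    out[ty, ] <- if (statistic == "mean") rowMeans(sub)
                 else matrixStats::rowMedians(sub)
  }
  species <- vapply(types, function(ty)
    ann$species[match(ty, ann$cancer_type)], character(1))
  grouped_stat_matrix(out, statistic, unit = mat$unit, species = species)
}

#' @rdname group_statistic
#' @param values cancer type x gene numeric matrix with dimnames.
#' @param unit unit tag inherited from the source matrix.
#' @param species optional named character vector, species per cancer type.
#' @export
grouped_stat_matrix <- function(values, statistic = c("mean", "median"),
                                unit = NULL, species = NULL) {
  statistic <- match.arg(statistic)
  if (!is.matrix(values) || !is.numeric(values) ||
      is.null(rownames(values)) || is.null(colnames(values)))
    stop_icsig("`values` must be a numeric matrix with group and gene names")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop_icsig("duplicate group or gene ids")
  if (!is.null(species)) species <- species[rownames(values)]
  structure(list(values = values, statistic = statistic, unit = unit,
                 species = species),
            class = "ic_grouped")
}

#' @export
print.ic_grouped <- function(x, ...) {
  cat(sprintf("<ic_grouped> %d cancer types x %d genes (%s%s)\n",
              nrow(x$values), ncol(x$values), x$statistic,
              if (!is.null(x$unit)) paste0(" of ", x$unit) else ""))
  invisible(x)
}
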