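#' Immune infiltrate composition scores
#'
#' A marker-averaging proxy for immune-cell presence (deconvolution methods
#' are unavailable for the dog): for each cell type, the score of a cancer
#' type is the mean over that cell type's marker genes of the mean-normalized
#' expression. Because every marker was first divided by its cross-type mean
#' (see [mean_normalized_scores()]), abundant and rare markers contribute
#' equally; a score of 1 means "at the across-types average".
#'
#' @param grouped_norm an `ic_grouped` of mean-normalized per-type means.
#' @param catalog a [gene_catalog()] with `marker_cell_type` assignments.
#' @return A data.frame with columns `cancer_type`, `cell_type`, `score`.
#' @export
infiltrate_profile <- function(grouped_norm, catalog) {
  stopifnot(inherits(grouped_norm, "ic_grouped"))
  v <- grouped_norm$values
  markers <- catalog[!is.na(catalog$marker_cell_type), , drop = FALSE]
  if (nrow(markers) == 0L) stop_icsig("catalog defines no marker genes")
  cell_types <- unique(markers$marker_cell_type)
  rows <- list()
  for (ct in cell_types) {
    genes <- intersect(markers$gene_id[markers$marker_cell_type == ct],
                       colnames(v))
    if (length(genes) == 0L) {
      warning("cell type '", ct, "' has no marker present; dropped",
              call. = FALSE)
      next
    }
    rows[[ct]] <- data.frame(
      cancer_type = rownames(v), cell_type = ct,
      score = rowMeans(v[, genes, drop = FALSE]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  if (length(rows) == 0L) stop_icsig("no cell type with surviving markers")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Immune inhibition ratio
#'
#' Summarizes the balance of the tumor immune environment in a single number
#' per cancer type: the mean mean-normalized expression over inhibitory ICs
#' divided by the same mean over stimulatory ICs. A ratio of 1 indicates
#' balance; above 1, a more inhibitory ("cold") environment. Genes with a
#' complex role contribute to neither score.
#'
#' @inheritParams infiltrate_profile
#' @return A data.frame with columns `cancer_type`, `inhibitory_score`,
#'   `stimulatory_score`, `ratio` (`NA` where the stimulatory score is 0).
#' @export
inhibition_profile <- function(grouped_norm, catalog) {
  stopifnot(inherits(grouped_norm, "ic_grouped"))
  v <- grouped_norm$values
  inh <- intersect(catalog$gene_id[catalog$ic_role == "inhibitory"], colnames(v))
  sti <- intersect(catalog$gene_id[catalog$ic_role == "stimulatory"], colnames(v))
  if (length(inh) == 0L || length(sti) == 0L)
    stop_icsig("need >= 1 inhibitory and >= 1 stimulatory IC in the matrix")
  inhibitory <- rowMeans(v[, inh, drop = FALSE])
  stimulatory <- rowMeans(v[, sti, drop = FALSE])
  ratio <- ifelse(stimulatory > 0, inhibitory / stimulatory, NA_real_)
  if (any(stimulatory == 0))
    warning("stimulatory score 0 for: ",
            paste(rownames(v)[stimulatory == 0], collapse = ", "),
            "; ratio reported as NA", call. = FALSE)
  data.frame(cancer_type = rownames(v),
             inhibitory_score = inhibitory,
             stimulatory_score = stimulatory,
             ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-species conservation score
#'
#' Collapses a pairwise protein alignment of species orthologs to one number:
#' `identity * coverage / 100`, both arguments in percent. 100 means an
#' identical full-length match; the score is symmetric in its arguments and
#' bounded in \[0, 100\].
#'
#' @param identity,coverage percent values in \[0, 100\] (vectorized).
#' @return Numeric score(s) in \[0, 100\].
#' @examples
#' conservation_score(94, 100)  # B7-H4-like, highly conserved
#' conservation_score(50, 50)   # 25
#' @export
conservation_score <- function(identity, coverage) {
  if (!is.numeric(identity) || !is.numeric(coverage))
    stop_icsig("identity and coverage must be numeric")
  if (length(identity) != length(coverage))
    stop_icsig("identity and coverage must have equal length")
  if (any(!is.finite(identity)) || any(!is.finite(coverage)) ||
      any(identity < 0 | identity > 100) || any(coverage < 0 | coverage > 100))
    stop_icsig("identity and coverage must lie in [0, 100]")
  identity * coverage / 100
}
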