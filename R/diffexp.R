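#' Median/mean-based differential IC expression between cancer-type groups
#'
#' Compares a group of cancer types against a reference set of cancer types,
#' gene by gene, on TPM. The group statistic is the chosen statistic (median
#' or mean) over *per-type* statistics, so cancer types are weighted equally
#' regardless of their sample counts. For each retained gene,
#' `fc = group_stat / reference_stat` and `log2_fc = log2(fc)`. The z-score is
#' the gene-wise standardization of `log2_fc` across all retained genes of the
#' comparison, and the p-value is the one-sided standard-normal tail beyond
#' `|z|` (see [one_sided_pval()]). Note this is a descriptive outlier score
#' over the gene panel, not a sampling-based test: its null behaviour is
#' anti-conservative relative to the nominal level (see the package vignette).
#'
#' Genes whose group or reference statistic is exactly 0 carry no finite fold
#' change; they are flagged "undetectable" and excluded (no pseudocount is
#' applied) and do not enter the z standardization.
#'
#' @param mat an [expression_matrix()] (TPM for cross-species work).
#' @param ann a [sample_annotation()].
#' @param group_types,reference_types disjoint non-empty character vectors of
#'   cancer types.
#' @param statistic `"median"` or `"mean"`.
#' @param genes optional gene panel restriction.
#' @return A data.frame sorted by decreasing `fc` with columns `gene_id`,
#'   `group_stat`, `reference_stat`, `fc`, `log2_fc`, `zscore`, `pval`,
#'   `significant` (p < 0.05), `regulation` (`up` if fc > 1 else `down`), and
#'   attribute `undetectable` listing excluded genes.
#' @export
group_diffexp <- function(mat, ann, group_types, reference_types,
                          statistic = c("median", "mean"), genes = NULL) {
  statistic <- match.arg(statistic)
  if (length(group_types) == 0L || length(reference_types) == 0L)
    stop_icsig("group and reference type sets must be non-empty")
  if (length(intersect(group_types, reference_types)))
    stop_icsig("group and reference type sets must be disjoint")
  if (!is.null(genes)) mat <- subset_expression(mat, genes = genes)
  per_type <- group_statistic(mat, ann, statistic)
  missing <- setdiff(c(group_types, reference_types), rownames(per_type$values))
  if (length(missing))
    stop_icsig("cancer type(s) not present: ", paste(missing, collapse = ", "))
  stat_fun <- if (statistic == "median") stats::median else mean
  gstat <- apply(per_type$values[group_types, , drop = FALSE], 2L, stat_fun)
  rstat <- apply(per_type$values[reference_types, , drop = FALSE], 2L, stat_fun)
  diffexp_table(names(gstat), gstat, rstat)
}

# fc / log2_fc / z / p arithmetic shared by group_diffexp and the worked
# printed-table checks, which feed (group, reference) statistic pairs directly.
diffexp_table <- function(gene_id, group_stat, reference_stat) {
  undetectable <- group_stat == 0 | reference_stat == 0
  keep <- !undetectable
  if (sum(keep) < 3L)
    stop_icsig("fewer than 3 genes with detectable expression on both sides; ",
               "the z-score across genes is not meaningful")
  fc <- group_stat[keep] / reference_stat[keep]
  log2_fc <- log2(fc)
  z <- (log2_fc - mean(log2_fc)) / stats::sd(log2_fc)
  out <- data.frame(gene_id = gene_id[keep],
                    group_stat = group_stat[keep],
                    reference_stat = reference_stat[keep],
                    fc = fc, log2_fc = log2_fc, zscore = z,
                    pval = one_sided_pval(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$significant <- out$pval < 0.05
  out$regulation <- ifelse(out$fc > 1, "up", "down")
  out <- out[order(-out$fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "undetectable") <- gene_id[undetectable]
  out
}

#' One-sided standard-normal tail p-value
#'
#' `p = P(Z > |z|)` for standard normal `Z`: `pval(0) = 0.5`,
#' `pval(1.959964) = 0.025`.
#'
#' @param z numeric z-score(s).
#' @return p-value(s) in (0, 0.5].
#' @export
one_sided_pval <- function(z) stats::pnorm(-abs(z))

#' Merge median- and mean-based comparisons into robust calls
#'
#' A gene is flagged `robust` when it is significant (p < 0.05) with the same
#' regulation direction under both the median- and the mean-based variant of
#' the comparison -- the "increased confidence" bolding rule.
#'
#' @param median_records,mean_records results of [group_diffexp()] run with
#'   `statistic = "median"` and `"mean"` on the same comparison.
#' @return The median-based records with an added logical `robust` column;
#'   genes absent from either variant are dropped with a warning.
#' @export
robust_merge <- function(median_records, mean_records) {
  common <- intersect(median_records$gene_id, mean_records$gene_id)
  if (length(common) < length(union(median_records$gene_id,
                                    mean_records$gene_id)))
    warning("gene sets differ between variants; using their intersection",
            call. = FALSE)
  out <- median_records[median_records$gene_id %in% common, , drop = FALSE]
  i <- match(out$gene_id, mean_records$gene_id)
  out$robust <- out$significant & mean_records$significant[i] &
    out$regulation == mean_records$regulation[i]
  rownames(out) <- NULL
  out
}
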