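#' Worked differential-expression examples
#'
#' Machine-readable transcription of the published median-based differential
#' IC expression tables for human cancer-type clusters (table 1) and the
#' canine-vs-human comparison (table 2): per row the comparison, the gene, the
#' printed (group statistic, reference statistic) pair in TPM, and the printed
#' `fc`, `log2_fc`, `zscore`, `pval` and regulation direction, plus the
#' `robust` flag (significant under both median- and mean-based variants).
#' Decimal commas of the source were normalized to decimal points.
#'
#' These rows validate the fold-change arithmetic of [group_diffexp()]: for
#' every table-1 row, `round(group_stat / reference_stat, 2)` and
#' `round(log2(...), 2)` reproduce the printed values. Table-2 statistics are
#' themselves rounded to 2 decimals upstream, so its printed fc/log2_fc can
#' differ from recomputation in the last digit.
#'
#' @return A data.frame with one row per printed record.
#' @export
worked_tables <- function() {
  path <- system.file("extdata", "worked_diffexp_tables.tsv",
                      package = "icsig", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  df$robust <- as.logical(df$robust)
  df
}

#' @rdname worked_tables
#' @export
generate_worked_tables <- worked_tables
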