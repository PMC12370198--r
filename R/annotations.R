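ic_roles <- function() c("inhibitory", "stimulatory", "complex", "none")

#' Sample annotations and the gene catalog
#'
#' Samples carry two categorical labels: the species (e.g. canine, human) and
#' the cancer type. Each cancer type must belong to exactly one species -- a
#' cancer type is the unit of comparison throughout, so an ambiguous species
#' assignment would poison every downstream grouping. The gene catalog assigns
#' every gene an immune-checkpoint role from the closed set inhibitory /
#' stimulatory / complex / none, and optionally an immune-cell-type marker
#' label; a gene may be both an IC and a marker.
#'
#' @param sample_id,species,cancer_type character vectors of equal length.
#' @return `sample_annotation()` returns a validated `data.frame` with columns
#'   `sample_id`, `species`, `cancer_type`.
#' @export
sample_annotation <- function(sample_id, species, cancer_type) {
  ann <- data.frame(sample_id = as.character(sample_id),
                    species = as.character(species),
                    cancer_type = as.character(cancer_type),
                    stringsAsFactors = FALSE)
  if (anyNA(ann) || any(ann == ""))
    stop_icsig("annotations may not contain missing values")
  if (anyDuplicated(ann$sample_id))
    stop_icsig("duplicate sample_id(s): ",
               paste(unique(ann$sample_id[duplicated(ann$sample_id)]),
                     collapse = ", "))
  sp_per_type <- tapply(ann$species, ann$cancer_type,
                        function(s) length(unique(s)))
  bad <- names(sp_per_type)[sp_per_type > 1L]
  if (length(bad))
    stop_icsig("cancer type(s) mapped to more than one species: ",
               paste(bad, collapse = ", "))
  ann
}

#' @rdname sample_annotation
#' @param path CSV file with header `sample_id,species,cancer_type`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_icsig("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "species", "cancer_type")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop_icsig("annotation CSV lacks column(s): ", paste(missing, collapse = ", "))
  sample_annotation(df$sample_id, df$species, df$cancer_type)
}

#' @rdname sample_annotation
#' @param gene_id character vector of unique gene ids.
#' @param ic_role one of `"inhibitory"`, `"stimulatory"`, `"complex"`,
#'   `"none"` per gene.
#' @param marker_cell_type optional cell-type label per gene (`NA` for
#'   non-marker genes).
#' @export
gene_catalog <- function(gene_id, ic_role, marker_cell_type = NA_character_) {
  cat <- data.frame(gene_id = as.character(gene_id),
                    ic_role = as.character(ic_role),
                    marker_cell_type = as.character(marker_cell_type),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(cat$gene_id))
    stop_icsig("duplicate gene_id(s) in catalog: ",
               paste(unique(cat$gene_id[duplicated(cat$gene_id)]),
                     collapse = ", "))
  unknown <- setdiff(unique(cat$ic_role), ic_roles())
  if (length(unknown))
    stop_icsig("unknown ic_role value(s): ", paste(unknown, collapse = ", "),
               "; allowed: ", paste(ic_roles(), collapse = ", "))
  cat$marker_cell_type[!is.na(cat$marker_cell_type) &
                         cat$marker_cell_type == ""] <- NA_character_
  cat
}

#' @rdname sample_annotation
#' @export
read_gene_catalog <- function(path) {
  if (!file.exists(path)) stop_icsig("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = c("NA", ""))
  need <- c("gene_id", "ic_role")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop_icsig("catalog CSV lacks column(s): ", paste(missing, collapse = ", "))
  mk <- if ("marker_cell_type" %in% colnames(df)) df$marker_cell_type else NA
  gene_catalog(df$gene_id, df$ic_role, mk)
}

# Every analyzed sample must be annotated exactly once.
check_annotated <- function(mat, ann) {
  missing <- setdiff(colnames(mat$values), ann$sample_id)
  if (length(missing))
    stop_icsig("sample(s) without annotation: ", paste(missing, collapse = ", "))
  invisible(TRUE)
}
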