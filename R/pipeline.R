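#' Run configuration for the end-to-end pipeline
#'
#' A single declarative config drives the whole analysis graph
#' (normalize -> scores -> signatures -> cluster -> diffexp -> reduce).
#' Configs are plain lists, readable from YAML or JSON. Required fields:
#' `expression` (TSV path), `unit`, `annotations` (CSV path), `catalog`
#' (CSV path), `output_dir`, `seed`. Optional: `gene_lengths` (named list,
#' kb; required when `unit` is counts), `ic_genes` (panel restriction),
#' `comparisons` (list of `name`/`group`/`reference` cancer-type sets),
#' `pseudocount` (default 1), `umap` (n_neighbors/min_dist overrides),
#' `purity_k` (default 2), `gene_subset` (default `TRUE`: the expression TSV
#' is a gene-panel slice, so TPM columns need not sum to 1e6).
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON (`.json`) file.
#' @return The config list, validated.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_icsig("no such config: ", path)
  config <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else stop_icsig("config must be .yaml, .yml or .json")
  validate_run_config(config)
}

validate_run_config <- function(config) {
  need <- c("expression", "unit", "annotations", "catalog", "output_dir", "seed")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop_icsig("config lacks field(s): ", paste(missing, collapse = ", "))
  for (f in c("expression", "annotations", "catalog"))
    if (!file.exists(config[[f]]))
      stop_icsig("config file for '", f, "' does not exist: ", config[[f]])
  config$pseudocount <- config$pseudocount %||% 1
  config$purity_k <- config$purity_k %||% 2
  config
}

#' Run the full IC-signature pipeline
#'
#' Orchestrates every stage from input files to a report bundle: size-factor
#' normalization and TPM conversion when fed raw counts, mean-normalized
#' infiltrate and inhibition score tables, per-type median signatures, the
#' correlation distance matrix and Ward.D2 dendrogram (TSV + Newick),
#' median- and mean-based differential expression per configured comparison
#' with robust flags, PCA scores/loadings/scree with elbow and Horn
#' retention, a seeded UMAP embedding, and a JSON provenance record holding
#' the full effective config so identical config + seed reproduce the bundle
#' byte for byte. Any stage failure aborts with a stage-named error.
#'
#' @param config a config list (see [read_run_config()]) or a path to one.
#' @return Invisibly, a named list of written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_icsig("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  inputs <- stage("load", {
    mat <- read_expression_tsv(config$expression, config$unit,
                               gene_subset = config$gene_subset %||% TRUE)
    ann <- read_annotations(config$annotations)
    catalog <- read_gene_catalog(config$catalog)
    check_annotated(mat, ann)
    list(mat = mat, ann = ann, catalog = catalog)
  })
  mat <- inputs$mat; ann <- inputs$ann; catalog <- inputs$catalog

  tpm <- stage("normalize", {
    if (mat$unit == "counts") {
      lengths <- unlist(config$gene_lengths)
      if (is.null(lengths))
        stop("gene_lengths required for unit 'counts'")
      norm <- apply_size_factors(mat, size_factors(mat))
      to_tpm(norm, lengths)
    } else if (mat$unit == "tpm") mat
    else stop("unit must be 'counts' or 'tpm' for the full pipeline")
  })
  ic_genes <- unlist(config$ic_genes) %||%
    catalog$gene_id[catalog$ic_role != "none"]
  ic_genes <- intersect(ic_genes, rownames(tpm$values))

  stage("scores", {
    means <- mean_normalized_scores(group_statistic(tpm, ann, "mean"))
    paths$infiltrate <- write_tsv_bundle(
      infiltrate_profile(means, catalog), out_dir, "scores_infiltrate.tsv")
    paths$inhibition <- write_tsv_bundle(
      inhibition_profile(means, catalog), out_dir, "scores_inhibition.tsv")
  })

  dend <- stage("cluster", {
    sig <- median_signatures(tpm, ann, ic_genes = ic_genes)
    d <- correlation_distance(sig)
    paths$distance <- file.path(out_dir, "distance_matrix.tsv")
    write_distance_tsv(d, paths$distance)
    dd <- ward_cluster(d)
    paths$dendrogram <- file.path(out_dir, "dendrogram.nwk")
    export_newick(dd, paths$dendrogram)
    dd
  })
  purity <- species_purity(dend, ann, k = config$purity_k)

  stage("diffexp", {
    for (cmp in config$comparisons) {
      med <- group_diffexp(tpm, ann, cmp$group, cmp$reference, "median",
                           genes = ic_genes)
      mea <- group_diffexp(tpm, ann, cmp$group, cmp$reference, "mean",
                           genes = ic_genes)
      merged <- robust_merge(med, mea)
      paths[[paste0("diffexp_", cmp$name)]] <- write_tsv_bundle(
        merged, out_dir, paste0("diffexp_", cmp$name, ".tsv"))
    }
  })

  reduction <- stage("reduce", {
    sig_tpm <- group_statistic(subset_expression(tpm, genes = ic_genes),
                               ann, "median")
    pca <- pca_pipeline(sig_tpm, pseudocount = config$pseudocount)
    elbow <- elbow_k(pca)
    horn <- horn_k(sig_tpm, seed = config$seed,
                   pseudocount = config$pseudocount)
    pca$retained_k <- elbow
    paths$pca_scores <- write_tsv_bundle(
      data.frame(cancer_type = rownames(pca$scores), pca$scores,
                 check.names = FALSE), out_dir, "pca_scores.tsv")
    paths$pca_loadings <- write_tsv_bundle(
      data.frame(gene_id = rownames(pca$loadings), pca$loadings,
                 check.names = FALSE), out_dir, "pca_loadings.tsv")
    paths$scree <- file.path(out_dir, "scree.json")
    jsonlite::write_json(list(explained_variance = pca$explained_variance,
                              elbow_k = elbow, horn_k = horn),
                         paths$scree, auto_unbox = TRUE, digits = NA)
    sp_by_type <- ann$species[match(rownames(pca$scores), ann$cancer_type)]
    spc <- species_component(pca, sp_by_type)
    drivers <- top_loading_genes(pca, spc, n = 4)
    paths$drivers <- write_tsv_bundle(drivers, out_dir, "driver_genes.tsv")
    umap_cfg <- embedding_config(
      n_neighbors = config$umap$n_neighbors %||% 15,
      min_dist = config$umap$min_dist %||% 0.1,
      seed = config$seed)
    emb <- umap_embed(zscore_per_gene(log2_transform(
      subset_expression(tpm, genes = ic_genes), config$pseudocount)),
      config = umap_cfg)
    paths$umap <- write_tsv_bundle(
      data.frame(sample_id = rownames(emb), emb, check.names = FALSE),
      out_dir, "umap_coordinates.tsv")
    list(elbow = elbow, horn = horn, species_component = spc,
         drivers = drivers$gene_id)
  })

  stage("provenance", {
    paths$provenance <- file.path(out_dir, "provenance.json")
    jsonlite::write_json(
      list(package = "icsig",
           version = as.character(utils::packageVersion("icsig")),
           config = config,
           defaults = list(pseudocount = config$pseudocount,
                           alpha = 0.05, n_neighbors = 15,
                           linkage = "ward.D2", purity_k = config$purity_k),
           species_purity = purity,
           retained_k = reduction$elbow, horn_k = reduction$horn,
           species_component = reduction$species_component,
           driver_genes = reduction$drivers),
      paths$provenance, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  invisible(paths)
}

write_tsv_bundle <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
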