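# Programmatic fixtures shared across test files. Everything is generated in
# code under fixed seeds; no binary data.

rand_expr <- function(n_genes = 8, n_samples = 6, unit = "counts", seed = 1,
                      gene_subset = unit == "tpm") {
  set.seed(seed)
  v <- matrix(rpois(n_genes * n_samples, lambda = 50) + 1,
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(v * 1, unit, gene_subset = gene_subset)
}

# annotation assigning samples round-robin to `n_types` types over 2 species
rand_ann <- function(sample_ids, n_types = 3, seed = 2) {
  set.seed(seed)
  types <- sprintf("T%d", seq_len(n_types))
  species <- rep_len(c("canine", "human"), n_types)
  ty <- rep_len(types, length(sample_ids))
  sample_annotation(sample_ids, species[match(ty, types)], ty)
}

tiny_catalog <- function() {
  gene_catalog(
    gene_id = c("g01", "g02", "g03", "g04", "g05", "g06", "g07", "g08"),
    ic_role = c("inhibitory", "inhibitory", "stimulatory", "stimulatory",
                "complex", "none", "none", "none"),
    marker_cell_type = c(NA, NA, NA, NA, NA, "NK", "NK", "T-cell"))
}

small_cohort <- function(seed = 7, samples_per_type = c(8, 8), delta = 2, ...) {
  generate_cohort(cohort_spec(n_types_canine = 3, n_types_human = 3,
                              samples_per_type = samples_per_type, n_ic = 12,
                              n_marker = 8, delta = delta, seed = seed, ...))
}
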