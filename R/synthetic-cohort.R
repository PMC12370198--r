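#' Specification of a synthetic two-species cohort
#'
#' Declares the generative world for a two-species, multi-cancer-type
#' expression cohort with the structure every pipeline stage assumes. On the
#' log2 scale, the expression of gene g in a sample of cancer type t is
#'
#' `baseline_g + type_effect_{g,t} + species_effect_g + log2(inhibitory_bias_t) + noise`
#'
#' with `type_effect ~ N(0, tau^2)` drawn once per gene and type,
#' `noise ~ N(0, sigma^2)` per sample, a species effect of `+/- delta`
#' injected only into designated driver genes of the first species, and an
#' optional per-type multiplier on inhibitory ICs.
#'
#' By default (`rescale_tpm = FALSE`) the exponentiated values are reported
#' directly as TPM with the gene-subset flag set: the simulated panel is a
#' slice of a conceptual full transcriptome whose unmodeled remainder absorbs
#' the library normalization, exactly as a 44-gene IC panel extracted from a
#' whole-transcriptome TPM matrix behaves (columns of the slice do not sum to
#' 1e6, and a change in one panel gene does not deflate the others). With
#' `rescale_tpm = TRUE` each column is instead rescaled to sum to 1e6 over
#' the panel itself; note this self-normalization couples every gene to the
#' panel composition and can inject a species shift into non-driver genes.
#'
#' Defaults state a realistic bulk RNA-seq world: 14 canine and 27 human
#' cancer types, 10-45 samples per type, 44 IC genes plus 40 marker genes,
#' per-gene log2 baselines ~ N(3, 2.5) (TPM medians spanning ~0.1 to ~500),
#' type-effect sd `tau = 0.5`, noise sd `sigma = 1`, species effect
#' `delta = 2` on 4 driver genes with mixed signs `(+, +, -, -)` -- two
#' drivers up and two down in the first species, mirroring how real
#' species-divide genes behave.
#'
#' @param n_types_canine,n_types_human cancer types per species.
#' @param samples_per_type integer range (length-2) or vector of counts.
#' @param n_ic,n_marker numbers of immune-checkpoint and marker genes.
#' @param n_driver number of IC genes carrying the species effect.
#' @param delta log2-scale species effect size on driver genes.
#' @param driver_signs vector of +/-1 per driver (recycled).
#' @param tau sd of per-(gene, type) effects on log2 scale.
#' @param sigma sd of per-sample noise on log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-gene log2 baselines.
#' @param inhibitory_bias per-type multiplier applied to inhibitory-IC means;
#'   scalar 1 (none) or a vector recycled over cancer types.
#' @param rescale_tpm rescale each column to sum to 1e6 over the panel
#'   (default `FALSE`: slice-of-transcriptome model, see Details).
#' @param seed mandatory integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_types_canine = 14, n_types_human = 27,
                        samples_per_type = c(10, 45),
                        n_ic = 44, n_marker = 40,
                        n_driver = 4, delta = 2,
                        driver_signs = c(1, 1, -1, -1),
                        tau = 0.5, sigma = 1,
                        baseline_mean = 3, baseline_sd = 2.5,
                        inhibitory_bias = 1, rescale_tpm = FALSE, seed) {
  if (missing(seed)) stop_icsig("`seed` is mandatory for cohort_spec()")
  assert_scalar_number(tau, "tau", lower = 0)
  assert_scalar_number(sigma, "sigma", lower = 0)
  assert_scalar_number(delta, "delta")
  if (n_driver > n_ic)
    stop_icsig("more driver genes than IC genes")
  if (n_ic < 3) stop_icsig("need >= 3 IC genes")
  spec <- list(n_types_canine = as.integer(n_types_canine),
               n_types_human = as.integer(n_types_human),
               samples_per_type = samples_per_type,
               n_ic = as.integer(n_ic), n_marker = as.integer(n_marker),
               n_driver = as.integer(n_driver), delta = delta,
               driver_signs = rep_len(sign(driver_signs), n_driver),
               tau = tau, sigma = sigma,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               inhibitory_bias = inhibitory_bias,
               rescale_tpm = isTRUE(rescale_tpm), seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Generate a synthetic two-species cohort
#'
#' Draws a cohort from a [cohort_spec()]: a TPM expression matrix, sample
#' annotations, a gene catalog (IC roles cycled over
#' inhibitory/stimulatory/complex; marker genes assigned to eight immune cell
#' types), and a `truth` record holding every injected effect for recovery
#' tests. Fully reproducible: the same spec (including seed) yields an
#' identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `expression` (`ic_expr`, unit tpm),
#'   `annotation`, `catalog`, and `truth` (list: `driver_genes`,
#'   `species_effect`, `baseline`, `type_effects`, `inhibitory_bias`,
#'   `log2_expression` pre-TPM matrix, `spec`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n_types <- spec$n_types_canine + spec$n_types_human
  types <- c(sprintf("c%02d", seq_len(spec$n_types_canine)),
             sprintf("h%02d", seq_len(spec$n_types_human)))
  species <- rep(c("canine", "human"),
                 c(spec$n_types_canine, spec$n_types_human))

  spt <- spec$samples_per_type
  n_per_type <- if (length(spt) == 2L && spt[1] != spt[2])
    sample(seq(spt[1], spt[2]), n_types, replace = TRUE)
  else rep_len(as.integer(spt[1]), n_types)

  n_genes <- spec$n_ic + spec$n_marker
  genes <- c(sprintf("IC%02d", seq_len(spec$n_ic)),
             if (spec$n_marker > 0) sprintf("MK%02d", seq_len(spec$n_marker)))
  roles <- c(rep_len(c("inhibitory", "stimulatory", "complex"), spec$n_ic),
             rep("none", spec$n_marker))
  cell_types <- c("NK", "T-cell", "cytotoxic T-cell", "B-cell", "macrophage",
                  "mast", "neutrophil", "T-reg")
  marker_ct <- c(rep(NA_character_, spec$n_ic),
                 if (spec$n_marker > 0) rep_len(cell_types, spec$n_marker))
  catalog <- gene_catalog(genes, roles, marker_ct)

  driver_genes <- genes[seq_len(spec$n_driver)]
  species_effect <- stats::setNames(numeric(n_genes), genes)
  species_effect[driver_genes] <- spec$delta * spec$driver_signs

  baseline <- stats::setNames(
    stats::rnorm(n_genes, spec$baseline_mean, spec$baseline_sd), genes)
  type_effects <- matrix(stats::rnorm(n_genes * n_types, 0, spec$tau),
                         n_genes, n_types, dimnames = list(genes, types))
  bias <- stats::setNames(rep_len(spec$inhibitory_bias, n_types), types)
  if (any(bias <= 0)) stop_icsig("inhibitory_bias must be positive")
  inhibitory <- catalog$ic_role == "inhibitory"

  n_samples <- sum(n_per_type)
  sample_type <- rep(types, n_per_type)
  sample_species <- rep(species, n_per_type)
  sample_ids <- sprintf("%s_s%03d", sample_type,
                        unlist(lapply(n_per_type, seq_len)))

  mean_log2 <- baseline + type_effects[, sample_type, drop = FALSE] +
    outer(species_effect, as.numeric(sample_species == "canine")) +
    outer(as.numeric(inhibitory), log2(bias[sample_type]))
  log2_expr <- mean_log2 +
    matrix(stats::rnorm(n_genes * n_samples, 0, spec$sigma),
           n_genes, n_samples)
  dimnames(log2_expr) <- list(genes, sample_ids)

  raw <- 2^log2_expr
  tpm <- if (spec$rescale_tpm) sweep(raw, 2L, colSums(raw), "/") * 1e6 else raw

  list(expression = expression_matrix(tpm, "tpm",
                                      gene_subset = !spec$rescale_tpm),
       annotation = sample_annotation(sample_ids, sample_species, sample_type),
       catalog = catalog,
       truth = list(driver_genes = driver_genes,
                    species_effect = species_effect,
                    baseline = baseline,
                    type_effects = type_effects,
                    inhibitory_bias = bias,
                    log2_expression = log2_expr,
                    spec = unclass(spec)))
}
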