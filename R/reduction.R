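#' PCA of IC signatures
#'
#' The standard transcriptomics PCA recipe: `log2(x + pseudocount)` to
#' compress the dynamic range, then per-variable centering and unit-variance
#' scaling so every gene contributes equally, then eigendecomposition of the
#' covariance (via SVD). Variables that are constant after the log transform
#' carry no variance and are dropped with a warning. Component signs are
#' canonicalized so the largest-|loading| entry of each component is positive,
#' making reports reproducible across linear-algebra backends.
#'
#' @param mat observations x variables: an `ic_grouped` (cancer types as
#'   observations), an [expression_matrix()] (samples as observations,
#'   transposed internally), or a plain numeric matrix.
#' @param pseudocount offset for the log2 step; set `log2 = FALSE` for data
#'   already on log scale.
#' @param log2 apply the log2 transform first (default `TRUE`).
#' @return An object of class `ic_pca`: `scores` (obs x comp), `loadings`
#'   (variable x comp, orthonormal columns), `explained_variance` (fractions
#'   summing to 1), `sdev`, and `retained_k` (`NA` until set by a retention
#'   rule).
#' @export
pca_pipeline <- function(mat, pseudocount = 1, log2 = TRUE) {
  x <- reduction_input(mat)
  if (nrow(x) < 3L) stop_icsig("PCA needs >= 3 observations")
  if (log2) {
    if (any(x < 0)) stop_icsig("log2 step requires non-negative input")
    x <- base::log2(x + pseudocount)
  }
  sds <- matrixStats::colSds(x)
  const <- sds == 0
  if (any(const)) {
    warning("constant variable(s) dropped: ",
            paste(colnames(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign canonicalization: largest-|loading| entry positive
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  p$rotation[, flip] <- -p$rotation[, flip]
  p$x[, flip] <- -p$x[, flip]
  ev <- p$sdev^2
  structure(list(scores = p$x, loadings = p$rotation,
                 explained_variance = ev / sum(ev), sdev = p$sdev,
                 retained_k = NA_integer_),
            class = "ic_pca")
}

reduction_input <- function(mat) {
  if (inherits(mat, "ic_grouped")) return(mat$values)
  if (inherits(mat, "ic_expr")) return(t(mat$values))
  if (is.matrix(mat) && is.numeric(mat)) {
    x <- mat
    if (is.null(rownames(x))) rownames(x) <- paste0("obs", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("var", seq_len(ncol(x)))
    return(x)
  }
  stop_icsig("unsupported input; expected matrix, ic_expr or ic_grouped")
}

#' @export
print.ic_pca <- function(x, ...) {
  cat(sprintf("<ic_pca> %d observations x %d components; top fractions: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.2f", utils::head(x$explained_variance, 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Elbow rule for component retention
#'
#' On the scree of the top `max_m` explained-variance points, the elbow is the
#' point with the largest perpendicular distance from the straight line
#' joining the first and last scree points. A monotone-straight scree has no
#' interior elbow and yields `k = 1` with a warning.
#'
#' @param explained_variance per-component variance fractions (or an `ic_pca`).
#' @param max_m number of leading scree points considered (default 10).
#' @return Integer `k`, the number of components to retain.
#' @examples
#' elbow_k(c(5, 3, 1, 0.9, 0.8))  # 3
#' @export
elbow_k <- function(explained_variance, max_m = 10) {
  if (inherits(explained_variance, "ic_pca"))
    explained_variance <- explained_variance$explained_variance
  y <- as.numeric(explained_variance)
  if (length(y) < 3L) stop_icsig("elbow rule needs >= 3 scree points")
  y <- utils::head(y, max_m)
  m <- length(y)
  x <- seq_len(m)
  # perpendicular distance of each point from the chord (1, y1) -- (m, ym)
  dx <- m - 1; dy <- y[m] - y[1]
  dist <- abs(dy * x - dx * y - dy * 1 + dx * y[1]) / sqrt(dx^2 + dy^2)
  interior <- dist[-c(1L, m)]
  if (all(interior <= sqrt(.Machine$double.eps))) {
    warning("scree is straight; no interior elbow, returning k = 1",
            call. = FALSE)
    return(1L)
  }
  as.integer(which.max(dist))
}

#' Horn's parallel analysis
#'
#' Component retention against a permutation null: each variable's values are
#' permuted independently `n_perm` times (destroying inter-variable
#' correlation while preserving marginals), and a component is retained while
#' its eigenvalue exceeds the `quantile` of the null eigenvalues at the same
#' rank. On pure noise this retains ~0 components.
#'
#' @param mat same input as [pca_pipeline()] -- the observed eigenvalues are
#'   computed by the same log2/scale pipeline.
#' @param n_perm number of permutations (>= 20 recommended; fewer warns).
#' @param quantile null quantile (default 0.95).
#' @param seed integer RNG seed (mandatory: permutations must be reproducible).
#' @inheritParams pca_pipeline
#' @return Integer `k` (possibly 0).
#' @export
horn_k <- function(mat, n_perm = 100, quantile = 0.95, seed, pseudocount = 1,
                   log2 = TRUE) {
  if (missing(seed)) stop_icsig("`seed` is mandatory for horn_k()")
  if (n_perm < 20) warning("n_perm < 20 gives unstable null quantiles",
                           call. = FALSE)
  x <- reduction_input(mat)
  if (log2) x <- base::log2(x + pseudocount)
  x <- x[, matrixStats::colSds(x) > 0, drop = FALSE]
  obs <- stats::prcomp(x, center = TRUE, scale. = TRUE)$sdev^2
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      xp <- apply(x, 2L, sample)
      ev <- stats::prcomp(xp, center = TRUE, scale. = TRUE)$sdev^2
      length(ev) <- length(obs)   # pad with NA if a permutation loses rank
      ev
    }, numeric(length(obs)))
  })
  thr <- apply(null, 1L, stats::quantile, probs = quantile, na.rm = TRUE)
  exceeds <- obs > thr
  k <- if (exceeds[1L]) {
    runs <- rle(exceeds)
    if (runs$values[1L]) runs$lengths[1L] else 0L
  } else 0L
  as.integer(k)
}

#' Driver genes from component loadings
#'
#' The `n` variables with the largest absolute loading on a target component,
#' annotated (not filtered) with whether each also sits in the top-`n` of any
#' "exclusivity" component -- the question being whether a driver of one axis
#' of variation is merely a generalist. Ties in |loading| break by gene id.
#'
#' @param pca an `ic_pca`.
#' @param component target component index.
#' @param n number of genes to report (default 4).
#' @param exclusivity_components indices of components to cross-check.
#' @return data.frame with `gene_id`, `loading`, `abs_loading`,
#'   `also_top_in` (comma-separated component names or `""`).
#' @export
top_loading_genes <- function(pca, component, n = 4,
                              exclusivity_components = integer()) {
  stopifnot(inherits(pca, "ic_pca"))
  L <- pca$loadings
  if (component > ncol(L)) stop_icsig("component index out of range")
  if (n > nrow(L)) stop_icsig("n exceeds the number of genes")
  top_of <- function(j) {
    l <- L[, j]
    ord <- order(-abs(l), rownames(L))
    rownames(L)[ord[seq_len(n)]]
  }
  sel <- top_of(component)
  also <- vapply(sel, function(g) {
    hit <- vapply(exclusivity_components, function(j) g %in% top_of(j),
                  logical(1))
    paste(colnames(L)[exclusivity_components[hit]], collapse = ",")
  }, character(1))
  data.frame(gene_id = sel, loading = L[sel, component],
             abs_loading = abs(L[sel, component]), also_top_in = also,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify the species-separating component
#'
#' Component ordering is dataset-specific, so "the species axis" is found
#' operationally: the component whose scores have the largest absolute
#' point-biserial correlation with the species indicator.
#'
#' @param pca an `ic_pca` whose observations are cancer types (or samples).
#' @param species character/factor vector of species per observation, aligned
#'   with the score rows.
#' @param k restrict the search to the first `k` components (default: all).
#' @return Integer component index.
#' @export
species_component <- function(pca, species, k = NULL) {
  stopifnot(inherits(pca, "ic_pca"))
  species <- as.factor(species)
  if (nlevels(species) != 2L)
    stop_icsig("species must have exactly two levels")
  if (length(species) != nrow(pca$scores))
    stop_icsig("species labels must align with score rows")
  ind <- as.numeric(species == levels(species)[1L])
  k <- k %||% ncol(pca$scores)
  cors <- abs(apply(pca$scores[, seq_len(k), drop = FALSE], 2L,
                    function(s) suppressWarnings(stats::cor(s, ind))))
  cors[is.na(cors)] <- 0
  as.integer(which.max(cors))
}

#' Seeded UMAP embedding
#'
#' A thin, reproducibility-focused wrapper around [uwot::umap()] with the
#' standard defaults (`n_neighbors = 15`, `n_components = 2`,
#' `min_dist = 0.1`). The algorithm itself is delegated; this function fixes
#' the seed, forces single-threaded optimization so the same seed and input
#' give identical coordinates, and shrinks `n_neighbors` with a warning when
#' there are too few observations.
#'
#' @param mat same input as [pca_pipeline()]; should already be standardized.
#' @param config an [embedding_config()].
#' @return observation x 2 coordinate matrix.
#' @export
umap_embed <- function(mat, config = embedding_config(seed = 42)) {
  x <- reduction_input(mat)
  nn <- config$n_neighbors
  if (nrow(x) <= nn) {
    nn <- max(2L, nrow(x) - 1L)
    warning("n_neighbors reduced to ", nn, " for ", nrow(x), " observations",
            call. = FALSE)
  }
  emb <- with_seed(config$seed,
    uwot::umap(x, n_neighbors = nn, n_components = config$n_components,
               min_dist = config$min_dist, n_threads = 1, n_sgd_threads = 1))
  rownames(emb) <- rownames(x)
  colnames(emb) <- paste0("UMAP", seq_len(ncol(emb)))
  emb
}

#' @rdname umap_embed
#' @param n_neighbors,n_components,min_dist UMAP tuning parameters; the
#'   defaults are the conventional ones (15 neighbours, 2 output dimensions,
#'   minimum embedding distance 0.1).
#' @param seed mandatory integer seed.
#' @export
embedding_config <- function(n_neighbors = 15, n_components = 2,
                             min_dist = 0.1, seed) {
  if (missing(seed)) stop_icsig("`seed` is mandatory for embedding_config()")
  assert_scalar_number(n_neighbors, "n_neighbors", lower = 2)
  assert_scalar_number(n_components, "n_components", lower = 1)
  assert_scalar_number(min_dist, "min_dist", lower = 0)
  list(n_neighbors = as.integer(n_neighbors),
       n_components = as.integer(n_components),
       min_dist = min_dist, seed = as.integer(seed))
}
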