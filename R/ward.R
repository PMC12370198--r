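#' Ward.D2 agglomerative clustering
#'
#' Agglomerates the cancer-type distance matrix with the Ward.D2 convention:
#' the Lance-Williams update
#' \deqn{d(k, ij)^2 = \frac{(n_i+n_k)\,d(k,i)^2 + (n_j+n_k)\,d(k,j)^2 - n_k\, d(i,j)^2}{n_i+n_j+n_k}}
#' is applied to *squared* dissimilarities while merge heights are reported on
#' the original scale. Ward linkage satisfies reducibility, so heights are
#' non-decreasing (no inversions). Ties in the minimal merge distance are
#' broken by the lowest label-sorted pair, making the result deterministic.
#'
#' The return value is a standard `hclust` object, so [stats::cutree()],
#' [stats::as.dendrogram()] and [ape::as.phylo()] apply.
#'
#' @param dist an [correlation_distance()] result, or any symmetric
#'   non-negative labelled matrix / `dist` object.
#' @return An object of classes `ic_dendrogram` and `hclust`.
#' @export
ward_cluster <- function(dist) {
  d <- as_dist_matrix(dist)
  n <- nrow(d)
  if (n < 2L) stop_icsig("clustering needs >= 2 labels")
  labels <- rownames(d)
  # rank of each singleton's label in sort order, used for tie-breaking
  label_rank <- match(labels, sort(labels))

  Dsq <- d^2
  active <- seq_len(n)
  cluster_id <- -seq_len(n)        # hclust convention: negatives = singletons
  size <- rep(1L, n)
  rep_rank <- label_rank           # smallest label rank among members
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    # minimal off-diagonal squared distance among active clusters
    sub <- Dsq[active, active, drop = FALSE]
    diag(sub) <- Inf
    dmin <- min(sub)
    cand <- which(sub <= dmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie rule: lowest (label-sorted) representative pair
    reps <- cbind(pmin(rep_rank[active[cand[, 1L]]], rep_rank[active[cand[, 2L]]]),
                  pmax(rep_rank[active[cand[, 1L]]], rep_rank[active[cand[, 2L]]]))
    pick <- order(reps[, 1L], reps[, 2L])[1L]
    i <- active[cand[pick, 1L]]; j <- active[cand[pick, 2L]]

    height[step] <- sqrt(dmin)
    merge[step, ] <- order_merge_pair(cluster_id[i], cluster_id[j])

    others <- setdiff(active, c(i, j))
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      Dsq[i, others] <- Dsq[others, i] <-
        ((ni + nk) * Dsq[i, others] + (nj + nk) * Dsq[j, others] -
           nk * dmin) / (ni + nj + nk)
    }
    size[i] <- size[i] + size[j]
    rep_rank[i] <- min(rep_rank[i], rep_rank[j])
    cluster_id[i] <- step
    active <- setdiff(active, j)
  }

  out <- structure(list(merge = merge, height = height,
                        order = leaf_order(merge),
                        labels = labels, method = "ward.D2",
                        call = match.call(), dist.method = "pearson"),
                   class = c("ic_dendrogram", "hclust"))
  out
}

# hclust merge-row convention: singletons (negative) before clusters, two
# singletons by increasing observation index, two clusters by merge row.
order_merge_pair <- function(a, b) {
  if (a < 0 && b < 0) c(max(a, b), min(a, b))
  else if (a > 0 && b > 0) c(min(a, b), max(a, b))
  else if (a < 0) c(a, b) else c(b, a)
}

# left-to-right leaf traversal of the merge matrix
leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

as_dist_matrix <- function(dist) {
  if (inherits(dist, "ic_dist")) return(dist$matrix)
  if (inherits(dist, "dist")) {
    m <- as.matrix(dist)
    if (is.null(rownames(m)))
      dimnames(m) <- list(paste0("L", seq_len(nrow(m))),
                          paste0("L", seq_len(nrow(m))))
    return(m)
  }
  if (is.matrix(dist) && is.numeric(dist)) {
    if (nrow(dist) != ncol(dist) || any(abs(dist - t(dist)) > 1e-12) ||
        any(diag(dist) != 0) || any(dist < 0))
      stop_icsig("distance matrix must be symmetric, non-negative, zero-diagonal")
    if (is.null(rownames(dist)))
      stop_icsig("distance matrix must carry labels")
    return(dist)
  }
  stop_icsig("unsupported distance input")
}

#' Newick export of a dendrogram
#'
#' Writes the clustering tree with branch lengths derived from merge heights
#' (each branch spans the height difference between child and parent merges).
#' Labels containing Newick-reserved characters (`(){}[]:;,'` or whitespace)
#' are single-quoted. The written file re-parses (e.g. with
#' [ape::read.tree()]) to the same topology.
#'
#' @param dend an `hclust`-like object from [ward_cluster()].
#' @param path output file path; if `NULL`, the Newick string is returned.
#' @return The Newick string, invisibly when `path` is given.
#' @export
export_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "hclust"))
  merge <- dend$merge; height <- dend$height
  labels <- dend$labels %||% as.character(seq_len(nrow(merge) + 1L))
  fmt <- function(x) sprintf("%.12g", x)
  node_str <- function(node, parent_h) {
    if (node < 0L)
      return(paste0(quote_newick(labels[-node]), ":", fmt(parent_h)))
    h <- height[node]
    paste0("(", node_str(merge[node, 1L], h), ",",
           node_str(merge[node, 2L], h), "):", fmt(parent_h - h))
  }
  root <- nrow(merge)
  nwk <- paste0("(", node_str(merge[root, 1L], height[root]), ",",
                node_str(merge[root, 2L], height[root]), ");")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

quote_newick <- function(label) {
  needs <- grepl("[][(){}:;,' \t]", label, perl = TRUE)
  ifelse(needs,
         paste0("'", gsub("'", "''", label), "'"),
         label)
}

#' Signature clustering restricted to a gene subset
#'
#' Reruns the full signature pipeline (z-score per gene, per-type medians,
#' Pearson correlation distance, Ward.D2) on a stated gene subset -- the
#' validation used to ask whether a handful of identified driver genes alone
#' separates the species. With exactly 4 genes the Pearson correlation between
#' 4-long vectors is fragile; this is permitted with a warning.
#'
#' @param mat an [expression_matrix()].
#' @param ann a [sample_annotation()].
#' @param gene_subset character vector of >= 3 gene ids; a missing gene is an
#'   error (the subset is a deliberate claim, not a panel).
#' @return An `ic_dendrogram` over cancer types.
#' @export
subset_cluster <- function(mat, ann, gene_subset) {
  stopifnot(inherits(mat, "ic_expr"))
  if (length(gene_subset) < 3L)
    stop_icsig("gene subset must contain >= 3 genes")
  missing <- setdiff(gene_subset, rownames(mat$values))
  if (length(missing))
    stop_icsig("subset gene(s) missing from matrix: ",
               paste(missing, collapse = ", "))
  sub <- subset_expression(mat, genes = gene_subset)
  sig <- median_signatures(sub, ann)
  ward_cluster(correlation_distance(sig))
}

#' Species purity of a dendrogram cut
#'
#' Operationalizes "separation of cancers by species": the tree is cut into
#' `k` clusters and purity is the fraction of cancer types whose species
#' matches the majority species of their cluster. For two balanced species,
#' purity ranges from ~0.5 (random) to 1 (perfect separation).
#'
#' @param dend an `hclust`-like dendrogram over cancer types.
#' @param ann a [sample_annotation()] (or any data.frame with `cancer_type`
#'   and `species` columns) covering every leaf.
#' @param k number of clusters to cut (default 2, the species question).
#' @return Purity in \[0, 1\].
#' @export
species_purity <- function(dend, ann, k = 2) {
  stopifnot(inherits(dend, "hclust"))
  labels <- dend$labels
  n <- length(labels)
  if (k > n) stop_icsig("k = ", k, " exceeds the number of leaves (", n, ")")
  map <- unique(ann[, c("cancer_type", "species")])
  missing <- setdiff(labels, map$cancer_type)
  if (length(missing))
    stop_icsig("no species annotation for leaf/leaves: ",
               paste(missing, collapse = ", "))
  species <- map$species[match(labels, map$cancer_type)]
  cl <- stats::cutree(dend, k = k)
  sum(tapply(species, cl, function(s) max(table(s)))) / n
}
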