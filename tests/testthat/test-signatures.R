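test_that("median_signatures equals a naive loop and ignores sample order", {
  coh <- small_cohort(seed = 21)
  ic <- coh$catalog$gene_id[coh$catalog$ic_role != "none"]
  sig <- median_signatures(coh$expression, coh$annotation, ic_genes = ic)
  expect_identical(sig$statistic, "median")
  expect_setequal(colnames(sig$values), ic)

  # naive loop oracle: z-score after restriction, then per-type medians
  sub <- coh$expression$values[ic, , drop = FALSE]
  z <- t(apply(sub, 1, function(r) (r - mean(r)) / sd(r)))
  for (ty in rownames(sig$values)) {
    ids <- coh$annotation$sample_id[coh$annotation$cancer_type == ty]
    expect_equal(sig$values[ty, ],
                 apply(z[, ids, drop = FALSE], 1, median), info = ty)
  }

  # permutation invariance
  set.seed(22)
  perm <- sample(colnames(coh$expression$values))
  sig2 <- median_signatures(subset_expression(coh$expression, samples = perm),
                            coh$annotation, ic_genes = ic)
  expect_equal(sig$values[rownames(sig2$values), ], sig2$values)

  # absent panel genes are listed and excluded
  expect_warning(
    s3 <- median_signatures(coh$expression, coh$annotation,
                            ic_genes = c(ic[1:5], "GHOST")),
    "GHOST")
  expect_setequal(colnames(s3$values), ic[1:5])

  # single-sample types return that sample's values
  one <- expression_matrix(
    matrix(c(1, 5, 2, 4, 8, 6), 3,
           dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
    "tpm", gene_subset = TRUE)
  ann1 <- sample_annotation(c("s1", "s2"), c("canine", "human"), c("A", "B"))
  s <- median_signatures(one, ann1, zscore = FALSE)
  expect_equal(s$values["A", ], c(a = 1, b = 5, c = 2))
})

test_that("correlation_distance implements 1 - Pearson r with its invariants", {
  set.seed(23)
  base <- rnorm(10)
  m <- rbind(A = base, B = base, C = -base, D = rnorm(10))
  colnames(m) <- paste0("g", 1:10)
  d <- correlation_distance(m)
  expect_equal(d$matrix["A", "B"], 0)
  expect_equal(d$matrix["A", "C"], 2)
  expect_true(all(d$matrix >= 0 & d$matrix <= 2))
  expect_equal(diag(d$matrix), rep(0, 4), ignore_attr = TRUE)
  expect_equal(d$matrix, t(d$matrix))

  # invariance to per-vector affine rescaling
  m2 <- m
  m2["D", ] <- 3 * m2["D", ] + 7
  expect_equal(correlation_distance(m2)$matrix, d$matrix, tolerance = 1e-12)

  const <- rbind(A = rep(1, 5), B = rnorm(5))
  colnames(const) <- paste0("g", 1:5)
  expect_error(suppressWarnings(correlation_distance(const)), "A")
  expect_error(correlation_distance(m[, 1:2]), ">= 3 genes")
})

test_that("ward_cluster matches R's reference agglomerator on random instances", {
  # independent oracle: stats::hclust's C implementation of ward.D2
  set.seed(24)
  for (n in c(4, 6, 9)) {
    for (rep in 1:30) {
      x <- matrix(rnorm(n * 7), n)
      rownames(x) <- sprintf("L%02d", seq_len(n))
      d <- as.matrix(dist(x))
      mine <- ward_cluster(d)
      ref <- stats::hclust(stats::as.dist(d), method = "ward.D2")
      expect_identical(mine$merge, ref$merge)
      expect_equal(mine$height, ref$height, tolerance = 1e-10)
      expect_setequal(mine$labels[mine$order], rownames(x))
    }
  }
})

test_that("ward_cluster handles degenerate and tied inputs deterministically", {
  # two identical profiles merge first at height 0
  set.seed(25)
  base <- rnorm(8)
  m <- rbind(A = base, B = rnorm(8), C = base, D = rnorm(8))
  colnames(m) <- paste0("g", 1:8)
  dend <- ward_cluster(correlation_distance(m))
  expect_equal(dend$height[1], 0)
  expect_identical(sort(dend$labels[-dend$merge[1, ]]), c("A", "C"))

  # exact ties resolve identically across runs
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  expect_identical(ward_cluster(d)$merge, ward_cluster(d)$merge)
  expect_identical(ward_cluster(d)$merge[1, ], c(-1L, -2L))

  expect_error(ward_cluster(matrix(0, 1, 1, dimnames = list("A", "A"))),
               ">= 2")
})

test_that("newick export round-trips topology, quoting reserved labels", {
  set.seed(26)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    x <- matrix(rnorm(n * 10), n)
    rownames(x) <- sprintf("T%02d", seq_len(n))
    dend <- ward_cluster(as.matrix(dist(x)))
    nwk <- export_newick(dend)
    tr <- ape::read.tree(text = nwk)
    ref <- ape::as.phylo(stats::as.hclust(dend))
    expect_true(ape::all.equal.phylo(tr, ref, use.edge.length = FALSE))
  }

  m <- matrix(rnorm(40), 4,
              dimnames = list(c("glioma (dog)", "B-cell:lymphoma",
                                "osteo;sarcoma", "plain"),
                              paste0("g", 1:10)))
  dend <- ward_cluster(correlation_distance(m))
  f <- withr::local_tempfile(fileext = ".nwk")
  export_newick(dend, f)
  tr <- ape::read.tree(f)
  expect_setequal(gsub("^'|'$", "", tr$tip.label), rownames(m))

  # determinism: fixed input gives an identical string
  expect_identical(export_newick(dend), export_newick(dend))
})

test_that("subset_cluster reruns the pipeline on the subset and recovers drivers", {
  coh <- small_cohort(seed = 27)
  genes <- rownames(coh$expression$values)
  full <- ward_cluster(correlation_distance(
    median_signatures(coh$expression, coh$annotation)))
  same <- subset_cluster(coh$expression, coh$annotation, genes)
  expect_identical(same$merge, full$merge)
  expect_equal(same$height, full$height)

  expect_error(subset_cluster(coh$expression, coh$annotation,
                              c("IC01", "IC02", "GHOST")), "GHOST")
  expect_error(subset_cluster(coh$expression, coh$annotation, c("IC01", "IC02")),
               ">= 3")
  expect_warning(subset_cluster(coh$expression, coh$annotation,
                                coh$truth$driver_genes), "fragile")

  # species effect injected only in the drivers -> purity 1 on those genes
  dend <- suppressWarnings(
    subset_cluster(coh$expression, coh$annotation, coh$truth$driver_genes))
  expect_equal(species_purity(dend, coh$annotation), 1)
})

test_that("species_purity scores tree cuts against the species map", {
  coh <- small_cohort(seed = 28, delta = 6, tau = 0.1)
  ic <- coh$catalog$gene_id[coh$catalog$ic_role != "none"]
  dend <- ward_cluster(correlation_distance(
    median_signatures(coh$expression, coh$annotation, ic_genes = ic)))
  expect_equal(species_purity(dend, coh$annotation, k = 2), 1)
  expect_error(species_purity(dend, coh$annotation, k = 10), "exceeds")

  # hand cases. Balanced tree with alternating species: each k = 2 cluster is
  # an even species mix, purity 0.5. Chain tree: cutting at k = 2 splits off
  # the last leaf, purity (2 + 1)/4.
  ann <- sample_annotation(paste0("s", 1:4),
                           c("canine", "human", "canine", "human"),
                           paste0("T", 1:4))
  balanced <- list(merge = rbind(c(-1L, -2L), c(-3L, -4L), c(1L, 2L)),
                   height = c(1, 1, 3), order = 1:4,
                   labels = paste0("T", 1:4), method = "ward.D2")
  class(balanced) <- "hclust"
  expect_equal(species_purity(balanced, ann, k = 2), 0.5)
  chain <- list(merge = rbind(c(-1L, -2L), c(1L, -3L), c(2L, -4L)),
                height = c(1, 2, 3), order = 1:4,
                labels = paste0("T", 1:4), method = "ward.D2")
  class(chain) <- "hclust"
  expect_equal(species_purity(chain, ann, k = 2), 0.75)

  # random labelings cannot beat the true labeling on species-structured data
  set.seed(29)
  rand <- replicate(20, {
    shuffled <- ann_shuffled <- coh$annotation
    map <- unique(coh$annotation$cancer_type)
    sp <- sample(unique(coh$annotation[, c("cancer_type", "species")])$species)
    ann_shuffled$species <- sp[match(ann_shuffled$cancer_type, map)]
    species_purity(dend, ann_shuffled, k = 2)
  })
  expect_true(mean(rand) < 1)
})
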