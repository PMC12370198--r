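test_that("size_factors matches hand computation and a naive oracle", {
  ident <- rand_expr(6, 2, "counts", seed = 1)
  ident$values[, 2] <- ident$values[, 1]
  expect_equal(unname(size_factors(ident)), c(1, 1))

  m <- expression_matrix(matrix(c(10, 30, 20, 60), 2,
                                dimnames = list(c("g1", "g2"),
                                                c("s1", "s2"))), "counts")
  expect_equal(unname(size_factors(m)), c(sqrt(0.5), sqrt(2)), tolerance = 1e-12)

  # naive loop oracle with some zeros sprinkled in
  mat <- rand_expr(20, 5, "counts", seed = 42)
  mat$values[cbind(c(3, 7, 11), c(1, 4, 5))] <- 0
  sf <- size_factors(mat)
  v <- mat$values
  ref_rows <- apply(v, 1, function(r) all(r > 0))
  geo <- apply(v[ref_rows, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  for (j in seq_len(ncol(v)))
    expect_equal(unname(sf[j]), median(v[ref_rows, j] / geo), info = j)
})

test_that("size_factors is scale-equivariant and normalization is a fixed point", {
  mat <- rand_expr(15, 4, "counts", seed = 10)
  sf <- size_factors(mat)
  scaled <- mat
  scaled$values[, 2] <- scaled$values[, 2] * 3
  sf2 <- size_factors(scaled)
  # scaling one library by c rescales the gene geometric means too, so the
  # equivariance holds on factor ratios: sf2[j]/sf2[k] = c^(±1) * sf[j]/sf[k]
  expect_equal(sf2[2] / sf2[1], 3 * sf[2] / sf[1], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sf2[3] / sf2[4], sf[3] / sf[4], tolerance = 1e-12,
               ignore_attr = TRUE)

  norm <- apply_size_factors(mat, sf)
  expect_identical(norm$unit, "normalized_counts")
  # fixed point up to the overall geometric mean of the first-round factors:
  # re-estimated factors are all equal (to geomean(sf)) and close to 1
  renorm <- size_factors(expression_matrix(norm$values, "counts"))
  expect_equal(unname(renorm), rep(exp(mean(log(sf))), 4), tolerance = 1e-12)
  expect_equal(unname(renorm), rep(1, 4), tolerance = 0.05)

  expect_equal(apply_size_factors(mat, setNames(rep(1, 4),
                                                colnames(mat$values)))$values,
               mat$values)
  expect_error(apply_size_factors(mat, c(s01 = 1)), "no size factor")
  allzero <- expression_matrix(
    matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("s1", "s2"))),
    "counts")
  expect_error(size_factors(allzero), "filter")
})

test_that("to_tpm satisfies its symmetry, invariance and hand-computed contracts", {
  eq <- expression_matrix(matrix(5, 4, 3,
                                 dimnames = list(paste0("g", 1:4),
                                                 paste0("s", 1:3))), "counts")
  len <- setNames(rep(2, 4), paste0("g", 1:4))
  tpm <- to_tpm(eq, len)
  expect_true(all(abs(tpm$values - 1e6 / 4) < 1e-9))
  expect_equal(colSums(tpm$values), rep(1e6, 3), ignore_attr = TRUE)

  mat <- rand_expr(6, 4, "counts", seed = 3)
  len <- setNames(runif(6, 0.5, 5), rownames(mat$values))
  expect_equal(to_tpm(mat, len)$values, to_tpm(mat, len * 2)$values)

  # 3-gene hand case: counts (10, 20, 30), lengths (1, 2, 5) kb
  h <- expression_matrix(matrix(c(10, 20, 30), 3,
                                dimnames = list(c("a", "b", "c"), "s")),
                         "counts")
  rate <- c(10, 10, 6)
  expect_equal(to_tpm(h, c(a = 1, b = 2, c = 5))$values[, "s"],
               rate / sum(rate) * 1e6, ignore_attr = TRUE)

  zero <- expression_matrix(matrix(c(1, 1, 0, 0), 2,
                                   dimnames = list(c("a", "b"),
                                                   c("s1", "s2"))), "counts")
  expect_error(to_tpm(zero, c(a = 1, b = 1)), "zero-depth.*s2")
})

test_that("log2_transform and zscore_per_gene behave per contract", {
  m <- expression_matrix(matrix(c(0, 3, 1, 7), 2,
                                dimnames = list(c("a", "b"),
                                                c("s1", "s2"))), "counts")
  lt <- log2_transform(m)
  expect_equal(lt$values["a", "s1"], 0)
  expect_equal(lt$values["b", "s1"], 2)
  expect_identical(lt$unit, "log2")
  expect_error(log2_transform(m, pseudocount = 0), "pseudocount")

  # monotone on random input
  mat <- rand_expr(5, 6, "counts", seed = 9)
  o1 <- order(mat$values[2, ]); o2 <- order(log2_transform(mat)$values[2, ])
  expect_identical(o1, o2)

  z <- zscore_per_gene(expression_matrix(
    matrix(c(1, 2, 3), 1, dimnames = list("g", paste0("s", 1:3))), "tpm",
    gene_subset = TRUE))
  expect_equal(z$values[1, ], c(s1 = -1, s2 = 0, s3 = 1))

  const <- expression_matrix(matrix(5, 2, 3,
                                    dimnames = list(c("a", "b"),
                                                    paste0("s", 1:3))), "tpm",
                             gene_subset = TRUE)
  expect_warning(zc <- zscore_per_gene(const), "constant")
  expect_true(all(zc$values == 0))

  zz <- zscore_per_gene(rand_expr(8, 10, "tpm", seed = 12))
  expect_equal(unname(rowMeans(zz$values)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(zz$values, 1, sd)), rep(1, 8), tolerance = 1e-12)
  # idempotence on non-constant rows
  expect_equal(zscore_per_gene(zz)$values, zz$values, tolerance = 1e-12)
})

test_that("mean_normalized_scores divides by the cross-type mean exactly", {
  v <- matrix(c(10, 30, 5, 5), 2,
              dimnames = list(c("A", "B"), c("g1", "g2")))
  g <- grouped_stat_matrix(v, "mean")
  ns <- mean_normalized_scores(g)
  expect_equal(ns$values[, "g1"], c(A = 0.5, B = 1.5))
  expect_equal(ns$values[, "g2"], c(A = 1, B = 1))

  # invariant: per-gene cross-type mean is exactly 1; zero-mean genes dropped
  set.seed(20)
  v2 <- matrix(rexp(40), 5, 8,
               dimnames = list(paste0("T", 1:5), paste0("g", 1:8)))
  v2[, 3] <- 0
  g2 <- grouped_stat_matrix(v2, "mean")
  expect_warning(ns2 <- mean_normalized_scores(g2), "g3")
  expect_equal(unname(colMeans(ns2$values)), rep(1, 7), tolerance = 1e-12)
  expect_error(mean_normalized_scores(group_statistic(
    rand_expr(3, 4, "tpm", seed = 2), rand_ann(sprintf("s%02d", 1:4), 2),
    "median")), "per-type means")
})
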