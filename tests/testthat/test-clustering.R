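test_that("absolute cosine similarity has its defining geometry", {
  expect_equal(abs_cos(c(1, 0), c(0, 1)), 0)
  expect_equal(abs_cos(c(1, -1, 0), c(-1, 1, 0)), 1)
  expect_equal(abs_cos(c(1, 1), c(1, 0)), 0.70711, tolerance = 1e-5)
  expect_equal(abs_cos(c(0, 0), c(1, 2)), 0)
  expect_error(abs_cos(c(1, 2), c(1, 2, 3)), "dimension")
  # symmetry, antipodal identity, scaling invariance over random vectors
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    k <- runif(1, 0.1, 10) * sample(c(-1, 1), 1)
    expect_equal(abs_cos(a, b), abs_cos(b, a))
    expect_equal(abs_cos(a, -a), 1)
    expect_equal(abs_cos(k * a, b), abs_cos(a, b))
  }
})

test_that("set similarity is the mean over cross pairs", {
  v <- c(2, 1, 0)
  expect_equal(set_similarity(v, v), 1)
  expect_equal(set_similarity(rbind(c(1, 0), c(0, 1)), c(1, 0)), 0.5)
  a <- c(1, 3, -2)
  b <- c(0, 1, 1)
  expect_equal(set_similarity(a, b), abs_cos(a, b))
  expect_error(set_similarity(matrix(numeric(0), 0, 2), c(1, 1)), "empty")
})

test_that("batching follows coverage rank with the quantile fallback", {
  cov <- stats::setNames(runif(10000), sprintf("u%05d", 1:10000))
  b <- make_batches(cov, batch_size = 1000, min_batches = 5)
  expect_length(b, 10)
  expect_true(all(lengths(b) == 1000))
  means <- vapply(b, function(ids) mean(cov[ids]), numeric(1))
  expect_true(all(diff(means) < 0))

  cov2 <- stats::setNames(runif(2500), sprintf("u%04d", 1:2500))
  b2 <- make_batches(cov2, batch_size = 1000, min_batches = 5)
  expect_length(b2, 5)
  expect_true(all(lengths(b2) == 500))

  cov3 <- stats::setNames(c(4, 3, 2, 1), c("a", "b", "c", "d"))
  b3 <- make_batches(cov3)
  expect_length(b3, 4)
  expect_true(all(lengths(b3) == 1))
  expect_equal(unlist(b3), c("a", "b", "c", "d"), ignore_attr = TRUE)
})

test_that("batched clustering recovers a separable toy instance", {
  # 6 unitigs, 3 chromosomes, ideal SSF vectors over 6 libraries
  V <- rbind(
    a1 = c(1, -1, 0, 0, 1, 0), a2 = c(-1, 1, 0, 0, -1, 0),  # chrom A (flipped)
    b1 = c(0, 1, 1, -1, 0, 0), b2 = c(0, 1, 1, -1, 0, 0),   # chrom B
    c1 = c(1, 0, -1, 0, 0, 1), c2 = c(1, 0, -1, 0, 0, 1)    # chrom C
  )
  comp <- stats::setNames(rep(1L, 6), rownames(V))
  cov <- stats::setNames(rep(1, 6), rownames(V))
  params <- clustering_params(grow_thresh = 0.9, create_thresh = 0.9,
                              merge_thresh = 0.8)
  a <- cluster_batched(V, comp, cov, params)
  expect_equal(length(unique(a)), 3)
  expect_equal(a[["a1"]], a[["a2"]])
  expect_equal(a[["b1"]], a[["b2"]])
  expect_equal(a[["c1"]], a[["c2"]])
  expect_false(a[["a1"]] == a[["b1"]] || a[["b1"]] == a[["c1"]])
})

test_that("zero vectors stay unclustered; near-duplicates seed a pair", {
  V <- rbind(
    u1 = c(1, 2, 3), u2 = c(1, 2, 3), zz = c(0, 0, 0)
  )
  comp <- stats::setNames(rep(1L, 3), rownames(V))
  cov <- stats::setNames(rep(1, 3), rownames(V))
  a <- cluster_batched(V, comp, cov, clustering_params(create_thresh = 0.99))
  expect_true(is.na(a[["zz"]]))
  expect_equal(a[["u1"]], a[["u2"]])
  expect_false(is.na(a[["u1"]]))
})

test_that("refinement dissolves small and low-coverage clusters, absorbs strays", {
  ids <- c("a1", "a2", "a3", "weak", "s1", "s2")
  assignment <- stats::setNames(c(1L, 1L, 1L, 2L, NA, NA), ids)
  components <- stats::setNames(c(1L, 1L, 1L, 1L, 2L, 2L), ids)
  lengths <- stats::setNames(c(5e6, 5e6, 5e6, 1e5, 2e5, 2e5), ids)
  params <- clustering_params(min_cluster_size = 1,
                              component_cov_thresh = 0.02)
  # cluster 2 holds 1e5 / 15.1e6 < 2% of its component's clustered bp, so
  # it dissolves; the component then has one cluster left and re-absorbs
  # the dissolved unitig in the same pass
  r <- refine_clusters(assignment, components, lengths, params)
  expect_equal(unname(r$assignment[["weak"]]), unname(r$assignment[["a1"]]))
  expect_equal(unname(r$assignment[["weak"]]), 1L)

  # min_cluster_size dissolves singletons
  a2 <- stats::setNames(c(1L, 1L, 1L, 2L, NA, NA), ids)
  r2 <- refine_clusters(a2, components, lengths,
                        clustering_params(min_cluster_size = 3,
                                          component_cov_thresh = 0))
  expect_equal(unname(r2$assignment[["weak"]]), 1L)  # absorbed after dissolve

  # strays on a single-cluster component are absorbed
  a3 <- stats::setNames(c(1L, 1L, 1L, NA, NA, NA), ids)
  r3 <- refine_clusters(a3, components, lengths, params)
  expect_equal(unname(r3$assignment[["weak"]]), 1L)
  expect_true(all(is.na(r3$assignment[c("s1", "s2")])))
})

test_that("refinement is idempotent", {
  set.seed(9)
  for (rep in 1:5) {
    n <- 30
    ids <- sprintf("u%02d", 1:n)
    assignment <- stats::setNames(
      sample(c(NA, 1:5), n, replace = TRUE), ids
    )
    components <- stats::setNames(sample(1:3, n, replace = TRUE), ids)
    lengths <- stats::setNames(runif(n, 5e4, 5e6), ids)
    params <- clustering_params()
    r1 <- refine_clusters(assignment, components, lengths, params)
    r2 <- refine_clusters(r1$assignment, components, lengths, params)
    expect_identical(r2$assignment, r1$assignment)
  }
})

test_that("uniform shrinkage of a unitig vector changes nothing", {
  # degenerate sequence shrinks every SSF dimension by the same factor;
  # similarities and cluster assignments must be unaffected
  b <- small_sim(seed = 11, n_chroms = 5, n_libraries = 30, segments = 5)
  ssf <- bundle_ssf(b)
  V <- unitigphaser:::ssf_matrix(ssf)
  S0 <- unitigphaser:::abs_cos_matrix(V)
  set.seed(2)
  shrunk <- sample(rownames(V), 10)
  V2 <- V
  V2[shrunk, ] <- V2[shrunk, ] * runif(10, 0.05, 1)
  expect_equal(unitigphaser:::abs_cos_matrix(V2), S0, tolerance = 1e-12)

  comp <- stats::setNames(
    component_labels(b$graph)$component, component_labels(b$graph)$unitig
  )
  cov <- stats::setNames(rep(1, nrow(V)), rownames(V))
  a1 <- cluster_batched(V, comp, cov, clustering_params())
  a2 <- cluster_batched(V2, comp, cov, clustering_params())
  expect_identical(a1, a2)
})

test_that("clustering is invariant to library order permutation", {
  b <- small_sim(seed = 13, n_chroms = 4, n_libraries = 24, segments = 5)
  ssf <- bundle_ssf(b)
  cl1 <- cluster_unitigs(ssf, b$graph)
  perm <- sample(attr(ssf, "library_levels"))
  ssf_p <- ssf
  attr(ssf_p, "library_levels") <- perm
  cl2 <- cluster_unitigs(ssf_p, b$graph)
  expect_identical(cl1$assignment, cl2$assignment)
})

test_that("full clustering recovers the simulated karyotype", {
  skip_if_not_installed("mclust")
  b <- small_sim(seed = 17, n_chroms = 6, n_libraries = 40, segments = 6,
                 misorientation_rate = 0.2, degenerate_rate = 0.1,
                 degenerate_intensity = 2)
  cl <- cluster_unitigs(bundle_ssf(b), b$graph)
  a <- cl$assignment
  truth <- truth_chrom(b)[a$unitig]
  expect_true(all(!is.na(a$cluster)))
  ari <- mclust::adjustedRandIndex(a$cluster, truth)
  expect_equal(ari, 1.0)
  # degenerate unitigs co-cluster with their chromosome
  deg <- b$truth_unitigs$unitig[b$truth_unitigs$degenerate]
  expect_true(all(!is.na(a$cluster[a$unitig %in% deg])))
})

test_that("empty input yields an empty clustering", {
  g <- assembly_graph(tibble::tibble(unitig = "u1", length = 1e5))
  empty_ssf <- strand_state_frequency(
    strand_counts(tibble::tibble(unitig = character(), library = character(),
                                 w = numeric(), c = numeric()))
  )
  cl <- cluster_unitigs(empty_ssf, g)
  expect_equal(nrow(cl$assignment), 0)
})
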