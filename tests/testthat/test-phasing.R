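# unit basis helpers for plane-geometry tests
e_ <- function(i, n = 5) {
  v <- numeric(n)
  v[i] <- 1
  v
}

test_that("cluster vector is the length-weighted mean", {
  X1 <- rbind(u1 = c(0.2, -0.4, 1))
  expect_equal(cluster_vector(X1, c(u1 = 7e6)), c(0.2, -0.4, 1))
  X2 <- rbind(u1 = c(1, 0), u2 = c(0, 1))
  expect_equal(cluster_vector(X2, c(u1 = 2e6, u2 = 2e6)), c(0.5, 0.5))
  expect_equal(cluster_vector(X2, c(u1 = 3e6, u2 = 1e6)), c(0.75, 0.25))
  expect_error(cluster_vector(X2[0, , drop = FALSE], c(u1 = 1)), "empty")
})

test_that("chromosome plane recovers an exact 2-D subspace", {
  set.seed(3)
  mix <- matrix(rnorm(12), 6, 2)
  X <- mix %*% rbind(e_(1), e_(2))  # vectors in span(e1, e2) of 5-dim space
  rownames(X) <- sprintf("u%d", 1:6)
  pl <- chromosome_plane(X)
  expect_false(pl$rank1)
  expect_equal(sum(pl$ev), 1, tolerance = 1e-12)
  # basis spans {e1, e2}: projecting X onto the basis loses nothing
  proj <- X %*% pl$basis %*% t(pl$basis)
  expect_equal(proj, X, tolerance = 1e-10)
  expect_equal(t(pl$basis) %*% pl$basis, diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("rank-1 clusters are flagged and completed deterministically", {
  a <- c(1, -1, 2, 0, 1)
  X <- rbind(u1 = a, u2 = -a)
  pl <- chromosome_plane(X)
  expect_true(pl$rank1)
  expect_equal(abs(sum(pl$basis[, 1] * a / sqrt(sum(a^2)))), 1,
               tolerance = 1e-12)
  expect_equal(sum(pl$basis[, 1] * pl$basis[, 2]), 0, tolerance = 1e-12)
  expect_error(chromosome_plane(X[1, , drop = FALSE]), "at least 2")
})

test_that("phase vector is the in-plane 90-degree rotation of v_clust", {
  basis <- cbind(e_(1), e_(2))
  vp <- phase_vector(e_(1), basis)
  expect_equal(abs(vp), e_(2))
  # orthogonal to the projected cluster vector, always
  set.seed(6)
  for (i in 1:10) {
    vc <- rnorm(5)
    vp <- phase_vector(vc, basis)
    proj <- basis %*% t(basis) %*% vc
    expect_equal(sum(vp * proj), 0, tolerance = 1e-10)
    expect_equal(max(abs(vp)), 1)
    # in-plane v_clust projects at full length
    vc_in <- basis %*% c(rnorm(2))
    expect_equal(
      sqrt(sum((t(basis) %*% vc_in)^2)), sqrt(sum(vc_in^2)),
      tolerance = 1e-12
    )
  }
  expect_error(phase_vector(e_(3), basis), "orthogonal to the chromosome plane")
})

test_that("haploid correction bisects the representative directions", {
  basis <- cbind(e_(1), e_(2))
  deg <- function(th) c(cos(th * pi / 180), sin(th * pi / 180))
  in_plane <- function(th) as.vector(basis %*% deg(th))
  # representatives at +40 and -20 degrees from v_clust = e1
  X <- rbind(u1 = in_plane(40), u2 = in_plane(-20))
  vc <- e_(1)
  vp <- phase_vector(vc, basis)
  corr <- haploid_correction(vc, vp, X, basis)
  ang <- atan2(sum(corr$v_clust * e_(2)), sum(corr$v_clust * e_(1))) * 180 / pi
  expect_equal(ang, 10, tolerance = 1e-8)
  expect_equal(sum(corr$v_clust * corr$v_phase), 0, tolerance = 1e-10)

  # symmetric representatives leave v_clust's direction unchanged
  X2 <- rbind(u1 = in_plane(35), u2 = in_plane(-35))
  corr2 <- haploid_correction(vc, vp, X2, basis)
  expect_equal(abs_cos(corr2$v_clust, vc), 1, tolerance = 1e-10)

  # a single direction: nothing to bisect
  X3 <- rbind(u1 = in_plane(10), u2 = 2 * in_plane(10))
  expect_warning(haploid_correction(vc, vp, X3, basis), "skipped")
})

manual_fit <- function(v_phase, libs = names(v_phase)) {
  structure(
    list(
      models = list(c01 = list(cluster = "c01",
                               v_phase = stats::setNames(v_phase, libs))),
      libraries = libs
    ),
    class = "phase_fit"
  )
}

test_that("marker pooling swaps negative-component libraries then dots |v_phase|", {
  counts <- counts_tbl("u1", "l1", 5, 0, "u1", "l2", 0, 5)
  cl <- tibble::tibble(unitig = "u1", cluster = "c01")
  mk <- pool_markers(counts, manual_fit(c(l1 = 1, l2 = -1)), cl)
  expect_equal(mk$hap1, 10)
  expect_equal(mk$hap2, 0)
  # zero phase vector -> zero markers
  mk0 <- pool_markers(counts, manual_fit(c(l1 = 0, l2 = 0)), cl)
  expect_equal(mk0$hap1 + mk0$hap2, 0)
  # negating v_phase swaps the haplotype labels
  mk_neg <- pool_markers(counts, manual_fit(c(l1 = -1, l2 = 1)), cl)
  expect_equal(mk_neg$hap1, mk$hap2)
  expect_equal(mk_neg$hap2, mk$hap1)
})

test_that("haplotype calls follow the ratio thresholds", {
  mk <- tibble::tibble(
    unitig = c("a", "b", "c", "d"), cluster = "c01",
    hap1 = c(100, 50, 0, 4), hap2 = c(2, 50, 0, 3)
  )
  calls <- call_haplotypes(mk, min_total = 10, ratio = 0.8)
  expect_equal(calls$call, c("HAP1", "HOM", "NONE", "NONE"))
})

test_that("haploid clusters are detected by explained variance and merged", {
  # rank-1 data with tiny jitter: haploid
  set.seed(21)
  a <- rnorm(12)
  X <- outer(runif(6, 0.5, 1.5), a) + matrix(rnorm(72, sd = 0.01), 6)
  rownames(X) <- sprintf("u%d", 1:6)
  ssf <- tibble::tibble(
    unitig = rep(rownames(X), each = 12),
    library = rep(sprintf("l%02d", 1:12), times = 6),
    ssf = as.vector(t(X)), w = 0, c = 0, defined = TRUE
  )
  attr(ssf, "unitig_levels") <- rownames(X)
  attr(ssf, "library_levels") <- sprintf("l%02d", 1:12)
  cl <- tibble::tibble(unitig = rownames(X), cluster = "c01")
  det <- detect_haploid(ssf, cl)
  expect_true(det$flags$haploid[det$flags$cluster == "c01"])
  expect_gt(det$flags$ev1[1], 0.99)

  # simulated genome with X/Y: only their clusters flag haploid, then merge
  b <- small_sim(seed = 29, n_chroms = 4, n_libraries = 40, segments = 6,
                 haploid_lengths_mb = c(X = 155, Y = 57))
  clusters <- cluster_unitigs(bundle_ssf(b), b$graph)
  det2 <- detect_haploid(bundle_ssf(b, "hap"), clusters)
  truth <- b$truth_unitigs
  hap_ids <- truth$unitig[truth$chromosome %in% c("chrX", "chrY")]
  a2 <- clusters$assignment
  hap_clusters <- unique(a2$cluster[a2$unitig %in% hap_ids])
  f <- det2$flags
  expect_true(all(f$haploid[f$cluster %in% hap_clusters]))
  expect_false(any(f$haploid[!f$cluster %in% hap_clusters], na.rm = TRUE))
  merged <- det2$assignment
  expect_length(unique(merged$cluster[merged$unitig %in% hap_ids]), 1)
})

test_that("phase models phase a simulated diploid genome faithfully", {
  b <- small_sim(seed = 31, n_chroms = 5, n_libraries = 48, segments = 7,
                 haploid_lengths_mb = c(X = 155, Y = 57),
                 misorientation_rate = 0.15)
  res <- phase_assembly(b$graph, b$counts_all, b$counts_hap)

  # conservation: hap1 + hap2 == sum_l |v_phase_l| (w + c), exactly
  vp_by_cluster <- lapply(res$fit$models, function(m) m$v_phase)
  counts <- res$counts_hap_oriented
  a <- res$calls
  for (i in seq_len(nrow(res$markers))) {
    u <- res$markers$unitig[i]
    clu <- res$markers$cluster[i]
    vp <- vp_by_cluster[[clu]]
    rows <- counts[counts$unitig == u, ]
    expected <- sum(abs(vp[rows$library]) * (rows$w + rows$c))
    expect_equal(res$markers$hap1[i] + res$markers$hap2[i], expected,
                 tolerance = 1e-10)
  }

  # noise-free recovery: 100% bp-weighted agreement up to label swaps
  ev <- evaluate_against_truth(res$calls, b$truth_unitigs)
  expect_equal(ev$agreement_pct[ev$scope == "overall"], 100)

  # v_phase concentrates on unmatched-state libraries
  pv <- tidy(res$fit)
  truth <- b$truth_unitigs
  states <- b$truth_states
  a <- res$clusters$assignment
  for (m in res$fit$models) {
    if (m$haploid) next
    ids <- a$unitig[!is.na(a$cluster) & a$cluster == m$cluster]
    chrom <- unique(truth$chromosome[match(ids, truth$unitig)])
    st <- states[states$chromosome == chrom, ]
    matched <- st$library[st$state %in% c("WW", "CC")]
    unmatched <- st$library[st$state %in% c("WC", "CW")]
    expect_lt(
      mean(abs(m$v_phase[matched])),
      0.1 * mean(abs(m$v_phase[unmatched]))
    )
  }
})
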