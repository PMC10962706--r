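test_that("read_gfa parses segments, links, lengths and coverage tags", {
  path <- write_gfa_fixture(c(
    "H\tVN:Z:1.0",
    "S\tu1\tACGTACGT",
    "S\tu2\t*\tLN:i:60000\trd:f:12.5",
    "S\tu3\t*\tLN:i:40000\tRC:i:80000",
    "L\tu1\t+\tu2\t-\t0M",
    "L\tu2\t+\tu3\t+\t0M"
  ))
  g <- read_gfa(path)
  expect_equal(nrow(g$segments), 3)
  expect_equal(nrow(g$links), 2)
  seg <- g$segments
  expect_equal(seg$length[seg$unitig == "u1"], 8)
  expect_equal(seg$length[seg$unitig == "u2"], 60000)
  expect_equal(seg$coverage[seg$unitig == "u2"], 12.5)
  expect_equal(seg$coverage[seg$unitig == "u3"], 80000 / 40000)
  expect_equal(seg$coverage[seg$unitig == "u1"], 0)
})

test_that("read_gfa rejects malformed graphs with informative errors", {
  expect_error(
    read_gfa(write_gfa_fixture(c("S\tu1\tACGT", "L\tu1\t+\tu9\t+\t0M"))),
    "unknown segment"
  )
  expect_error(
    read_gfa(write_gfa_fixture(c("S\tu1\tACGT", "S\tu1\tACGT"))),
    "duplicate segment id"
  )
  expect_error(
    read_gfa(write_gfa_fixture(c("S\tu1\t*"))),
    "no LN:i tag"
  )
})

test_that("GFA records round-trip through write_gfa and read_gfa", {
  g <- toy_tangle_graph()
  path <- withr::local_tempfile(fileext = ".gfa")
  write_gfa(g, path)
  g2 <- read_gfa(path)
  expect_equal(
    dplyr::arrange(g2$segments[, c("unitig", "length")], unitig),
    dplyr::arrange(g$segments[, c("unitig", "length")], unitig)
  )
  expect_equal(nrow(g2$links), nrow(g$links))
})

test_that("excision removes the short-node tangle of the largest component", {
  g <- toy_tangle_graph()
  pruned <- excise_rdna_tangle(g, short_len = 50000)
  expect_setequal(pruned$excised, c("t1", "t2"))
  expect_false(any(c("t1", "t2") %in% pruned$segments$unitig))
  # A and B are now in distinct components; partition only splits
  post <- component_labels(pruned)
  expect_false(
    post$component[post$unitig == "A"] == post$component[post$unitig == "B"]
  )
  pre <- component_labels(g)
  shared_pre <- merge(pre, pre, by = "component")
  for (cc in unique(post$component)) {
    members <- post$unitig[post$component == cc]
    expect_length(unique(pre$component[pre$unitig %in% members]), 1)
  }
})

test_that("excision never touches long nodes and picks the largest tangle", {
  # all nodes >= short_len: unchanged
  g_long <- assembly_graph(
    tibble::tibble(unitig = c("A", "B"), length = c(1e6, 2e6)),
    tibble::tibble(from = "A", from_orient = "+", to = "B", to_orient = "+")
  )
  expect_identical(excise_rdna_tangle(g_long)$segments, g_long$segments)

  # two tangles on the big component: 30kb total vs 80kb total
  g2 <- assembly_graph(
    tibble::tibble(
      unitig = c("A", "B", "s1", "s2", "b1", "b2"),
      length = c(10e6, 9e6, 10e3, 20e3, 40e3, 40e3)
    ),
    tibble::tibble(
      from = c("A", "s1", "A", "b1", "b2"), from_orient = "+",
      to = c("s1", "s2", "b1", "b2", "B"), to_orient = "+"
    )
  )
  pruned <- excise_rdna_tangle(g2, short_len = 50000)
  expect_setequal(pruned$excised, c("b1", "b2"))
  expect_true(all(c("s1", "s2") %in% pruned$segments$unitig))
  expect_true(all(pruned$segments$length[
    !pruned$segments$unitig %in% c("s1", "s2")
  ] >= 50000 | pruned$segments$unitig %in% c("s1", "s2")))
})

test_that("component labels are deterministic and orientation-blind", {
  g <- assembly_graph(
    tibble::tibble(unitig = c("A", "B", "C"), length = rep(1e5, 3)),
    tibble::tibble(from = "A", from_orient = "-", to = "B", to_orient = "-")
  )
  labs <- component_labels(g)
  expect_equal(labs$component[labs$unitig == "A"],
               labs$component[labs$unitig == "B"])
  expect_equal(labs$component[match(c("A", "C"), labs$unitig)], c(1L, 2L))

  g_iso <- assembly_graph(
    tibble::tibble(unitig = c("x", "y", "z"), length = rep(1e5, 3))
  )
  expect_equal(sort(component_labels(g_iso)$component), 1:3)
})

test_that("length filter keeps the >= boundary and supports identity", {
  g <- assembly_graph(
    tibble::tibble(unitig = c("a", "b", "c"),
                   length = c(40e3, 50e3, 60e3))
  )
  expect_setequal(filter_by_length(g, 50000), c("b", "c"))
  expect_setequal(filter_by_length(g, 0), c("a", "b", "c"))
})

test_that("simulated rDNA tangle fuses acrocentrics and excision separates them", {
  b <- simulate_strandseq(sim_config(
    n_diploid_chroms = 6,
    diploid_lengths_mb = c(120, 110, 100, 90, 80, 70),
    haploid_lengths_mb = NULL, segments_per_chrom = 4, n_libraries = 4,
    acrocentric = c(4, 5, 6), tangle_nodes = 5, seed = 3
  ))
  pre <- component_labels(b$graph)
  truth <- b$truth_unitigs
  acro_ids <- truth$unitig[truth$acrocentric & truth$chromosome != "rDNA"]
  expect_length(unique(pre$component[pre$unitig %in% acro_ids]), 1)
  pruned <- excise_rdna_tangle(b$graph)
  expect_setequal(pruned$excised,
                  truth$unitig[truth$chromosome == "rDNA"])
  post <- component_labels(pruned)
  by_chrom <- split(acro_ids, truth$chromosome[match(acro_ids, truth$unitig)])
  comps <- vapply(by_chrom, function(ids) {
    unique(post$component[post$unitig %in% ids])[1]
  }, integer(1))
  expect_length(unique(comps), 3)
})
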