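# Fixtures built in code: tiny GFA graphs, toy count tables, and small
# simulated genomes shared across test files.

write_gfa_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gfa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# toy graph used by the excision tests:
# big component A(10Mb) - t1(10kb) - t2(12kb) - B(9Mb); isolated C(1Mb)
toy_tangle_graph <- function() {
  assembly_graph(
    tibble::tibble(
      unitig = c("A", "B", "C", "t1", "t2"),
      length = c(10e6, 9e6, 1e6, 10e3, 12e3)
    ),
    tibble::tibble(
      from = c("A", "t1", "t2"), from_orient = "+",
      to = c("t1", "t2", "B"), to_orient = "+"
    )
  )
}

# long count table from explicit cells
counts_tbl <- function(...) {
  strand_counts(tibble::tribble(~unitig, ~library, ~w, ~c, ...))
}

# small, fast simulated genome; overrides merge into sim_config()
small_sim <- function(seed = 1, n_chroms = 6, n_libraries = 40,
                      segments = 5, ...) {
  args <- list(
    n_diploid_chroms = n_chroms,
    diploid_lengths_mb = seq(200, 80, length.out = n_chroms),
    haploid_lengths_mb = NULL,
    segments_per_chrom = segments,
    n_libraries = n_libraries,
    acrocentric = integer(),
    tangle_nodes = 0,
    background_noise_rate = 0,
    misorientation_rate = 0,
    degenerate_rate = 0,
    seed = seed
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  simulate_strandseq(do.call(sim_config, args))
}

# all-reads SSF over all libraries for a bundle
bundle_ssf <- function(bundle, which = c("all", "hap")) {
  which <- match.arg(which)
  counts <- if (which == "all") bundle$counts_all else bundle$counts_hap
  strand_state_frequency(counts)
}

# map unitig -> truth chromosome for a bundle
truth_chrom <- function(bundle) {
  stats::setNames(bundle$truth_unitigs$chromosome, bundle$truth_unitigs$unitig)
}
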