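# Synthetic Strand-seq simulator.
#
# Emulates the OUTPUT of the upstream alignment steps: per-unitig,
# per-library Watson/Crick first-mate alignment counts under WW/CC/WC/CW
# strand-state inheritance, for a diploid genome with optional haploid
# sex chromosomes, bubble-structured unitig graph, misoriented and
# degenerate unitigs, and uniform background noise. Full ground truth is
# returned for evaluation.

#' Simulator configuration
#'
#' Defaults describe a human-like genome observed through a typical
#' single Strand-seq preparation run: 22 diploid chromosomes with
#' human-scale lengths, X/Y haploid chromosomes, 96 libraries, and
#' sparse per-library coverage (about 100 reads per Mbp per haplotype,
#' i.e. roughly 0.1 reads/kbp).
#'
#' @param n_diploid_chroms number of diploid chromosomes (default 22).
#' @param diploid_lengths_mb lengths in Mbp; default is the human
#'   autosome lengths (first `n_diploid_chroms` entries).
#' @param haploid_lengths_mb named lengths of haploid chromosomes in
#'   Mbp; default `c(X = 155, Y = 57)`. Use `NULL` for none.
#' @param segments_per_chrom segments per chromosome; heterozygous
#'   segments yield two haplotype-specific unitigs, homozygous segments
#'   one collapsed unitig (default 12).
#' @param het_fraction probability that a diploid segment is
#'   heterozygous (default 0.5).
#' @param n_libraries number of Strand-seq libraries (default 96).
#' @param reads_per_mb expected first-mate alignments per Mbp per
#'   haplotype per library (default 100).
#' @param het_informative_frac fraction of a haplotype's reads on a
#'   heterozygous segment that overlap haplotype-distinguishing variation
#'   and align uniquely to the correct bubble arm (default 0.25); the
#'   remainder land on either arm at random.
#' @param hom_informative_frac fraction of reads on a homozygous unitig
#'   retained as haplotype-informative (unique-sequence) alignments
#'   (default 0.2).
#' @param background_noise_rate fraction of a unitig's expected reads
#'   added as orientation-random cross-chromosome noise (default 0.05).
#' @param misorientation_rate probability a unitig is stored in flipped
#'   orientation (default 0.05).
#' @param degenerate_rate probability a unitig carries degenerate
#'   sequence attracting uniform alignments (default 0.05).
#' @param degenerate_intensity expected degenerate reads as a multiple
#'   of the unitig's expected signal reads (default 2).
#' @param acrocentric indices of diploid chromosomes joined by the short
#'   rDNA tangle (default 13, 14, 15, 21, 22, clipped to range).
#' @param tangle_nodes number of short tangle nodes (default 8).
#' @param tangle_len_range length range in bp for tangle nodes
#'   (default 10000-40000, all below the 50 kbp threshold).
#' @param seed RNG seed; every stochastic step derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_diploid_chroms = 22,
                       diploid_lengths_mb = NULL,
                       haploid_lengths_mb = c(X = 155, Y = 57),
                       segments_per_chrom = 12,
                       het_fraction = 0.5,
                       n_libraries = 96,
                       reads_per_mb = 100,
                       het_informative_frac = 0.25,
                       hom_informative_frac = 0.2,
                       background_noise_rate = 0.05,
                       misorientation_rate = 0.05,
                       degenerate_rate = 0.05,
                       degenerate_intensity = 2,
                       acrocentric = c(13, 14, 15, 21, 22),
                       tangle_nodes = 8,
                       tangle_len_range = c(10000, 40000),
                       seed = 1) {
  human_autosomes <- c(
    248, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135,
    133, 114, 107, 102, 90, 84, 80, 59, 64, 47, 51
  )
  if (is.null(diploid_lengths_mb)) {
    diploid_lengths_mb <- rep_len(human_autosomes, n_diploid_chroms)
  }
  cfg <- list(
    n_diploid_chroms = n_diploid_chroms,
    diploid_lengths_mb = diploid_lengths_mb,
    haploid_lengths_mb = haploid_lengths_mb,
    segments_per_chrom = segments_per_chrom,
    het_fraction = het_fraction,
    n_libraries = n_libraries,
    reads_per_mb = reads_per_mb,
    het_informative_frac = het_informative_frac,
    hom_informative_frac = hom_informative_frac,
    background_noise_rate = background_noise_rate,
    misorientation_rate = misorientation_rate,
    degenerate_rate = degenerate_rate,
    degenerate_intensity = degenerate_intensity,
    acrocentric = acrocentric[acrocentric <= n_diploid_chroms],
    tangle_nodes = tangle_nodes,
    tangle_len_range = tangle_len_range,
    seed = seed
  )
  check_field <- function(ok, field) {
    if (!isTRUE(ok)) up_abort(sprintf("invalid sim_config field: %s", field))
  }
  check_field(n_diploid_chroms >= 1, "n_diploid_chroms")
  check_field(length(diploid_lengths_mb) == n_diploid_chroms &&
                all(diploid_lengths_mb > 0), "diploid_lengths_mb")
  check_field(is.null(haploid_lengths_mb) || all(haploid_lengths_mb > 0),
              "haploid_lengths_mb")
  check_field(segments_per_chrom >= 1, "segments_per_chrom")
  check_field(het_fraction >= 0 && het_fraction <= 1, "het_fraction")
  check_field(n_libraries >= 0, "n_libraries")
  check_field(reads_per_mb > 0, "reads_per_mb")
  for (f in c("het_informative_frac", "hom_informative_frac")) {
    check_field(cfg[[f]] >= 0 && cfg[[f]] <= 1, f)
  }
  for (f in c("background_noise_rate", "misorientation_rate",
              "degenerate_rate")) {
    check_field(cfg[[f]] >= 0 && cfg[[f]] < 1, f)
  }
  check_field(degenerate_intensity >= 0, "degenerate_intensity")
  structure(cfg, class = "sim_config")
}

#' Simulate strand-state inheritance
#'
#' Each (chromosome, library) cell inherits one of the four template
#' strand states WW, CC, WC, CW independently and equiprobably: each
#' homolog passes Watson or Crick with probability 1/2, so matched
#' (WW/CC) and unmatched (WC/CW) states occur in a 50/50 ratio.
#'
#' @param n_chroms,n_libraries matrix dimensions.
#' @param chrom_names,library_names optional dimnames.
#' @return character matrix (chromosomes x libraries) of states. Uses
#'   the current RNG state.
#' @export
inherit_strand_states <- function(n_chroms, n_libraries,
                                  chrom_names = NULL, library_names = NULL) {
  states <- c("WW", "CC", "WC", "CW")
  m <- matrix(
    sample(states, n_chroms * n_libraries, replace = TRUE),
    nrow = n_chroms, ncol = n_libraries
  )
  rownames(m) <- chrom_names %||%
    sprintf("chr%02d", seq_len(n_chroms))
  colnames(m) <- library_names %||%
    sprintf("lib%03d", seq_len(n_libraries))
  m
}

# rbinom that tolerates size 0 and vector sizes.
rbinom_vec <- function(size, prob) {
  out <- integer(length(size))
  pos <- size > 0
  out[pos] <- stats::rbinom(sum(pos), size[pos], prob)
  out
}

# Draw total signal reads for one haplotype of a segment across
# libraries: binomial around length * depth.
draw_reads <- function(n_lib, lambda) {
  size <- max(1L, round(2 * lambda))
  stats::rbinom(n_lib, size, 0.5)
}

#' Simulate a Strand-seq phasing input bundle
#'
#' Generates ground truth (chromosomes, segments, unitigs with
#' haplotype/orientation/degeneracy labels, per-chromosome strand
#' states), an assembly graph with per-chromosome bubble chains plus a
#' short-node rDNA-style tangle joining the acrocentric chromosomes, and
#' the two Watson/Crick count tables (all-reads and
#' haplotype-informative). Reads from both haplotypes align across a
#' heterozygous bubble: only the informative share lands deterministically
#' on its own arm, the rest picks an arm at random, so the all-reads SSF
#' of every unitig of a chromosome follows the chromosome's strand
#' state, while hap-informative SSF separates the haplotypes.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, writes `graph.gfa`,
#'   `counts_all.tsv`, `counts_hap.tsv`, `truth_unitigs.tsv`,
#'   `truth_states.tsv` and `config.yaml`.
#' @return a list of class `sim_bundle` with elements `graph`
#'   ([assembly_graph]), `counts_all`, `counts_hap` (count tibbles),
#'   `truth_unitigs`, `truth_states` (tibbles), `config`, and `paths`
#'   (when written). Re-running with the same config is byte-identical.
#' @export
simulate_strandseq <- function(config = sim_config(), outdir = NULL) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  bundle <- withr::with_seed(config$seed, simulate_impl(config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      gfa = file.path(outdir, "graph.gfa"),
      counts_all = file.path(outdir, "counts_all.tsv"),
      counts_hap = file.path(outdir, "counts_hap.tsv"),
      truth_unitigs = file.path(outdir, "truth_unitigs.tsv"),
      truth_states = file.path(outdir, "truth_states.tsv"),
      config = file.path(outdir, "config.yaml")
    )
    write_gfa(bundle$graph, paths$gfa)
    readr::write_tsv(bundle$counts_all, paths$counts_all, progress = FALSE)
    readr::write_tsv(bundle$counts_hap, paths$counts_hap, progress = FALSE)
    readr::write_tsv(bundle$truth_unitigs, paths$truth_unitigs,
                     progress = FALSE)
    readr::write_tsv(bundle$truth_states, paths$truth_states,
                     progress = FALSE)
    yaml::write_yaml(unclass(config), paths$config)
    bundle$paths <- paths
  }
  bundle
}

simulate_impl <- function(config) {
  n_dip <- config$n_diploid_chroms
  hap_lens <- config$haploid_lengths_mb
  chroms <- tibble(
    chromosome = sprintf("chr%02d", seq_len(n_dip)),
    length_mb = config$diploid_lengths_mb,
    ploidy = 2L,
    haplotype = NA_character_,
    acrocentric = seq_len(n_dip) %in% config$acrocentric
  )
  if (!is.null(hap_lens) && length(hap_lens) > 0) {
    hap_names <- names(hap_lens) %||% sprintf("H%d", seq_along(hap_lens))
    chroms <- dplyr::bind_rows(chroms, tibble(
      chromosome = paste0("chr", hap_names),
      length_mb = as.numeric(hap_lens),
      ploidy = 1L,
      # alternate H1/H2 so the merged haploid cluster has two truth labels
      haplotype = c("H1", "H2")[(seq_along(hap_lens) - 1) %% 2 + 1],
      acrocentric = FALSE
    ))
  }
  n_lib <- config$n_libraries
  lib_names <- sprintf("lib%03d", seq_len(n_lib))
  states <- inherit_strand_states(
    nrow(chroms), n_lib,
    chrom_names = chroms$chromosome, library_names = lib_names
  )

  # --- segments and unitigs -------------------------------------------------
  seg_rows <- list()
  uid <- 0L
  new_id <- function() {
    uid <<- uid + 1L
    sprintf("utg%06d", uid)
  }
  unitig_rows <- list()
  for (ci in seq_len(nrow(chroms))) {
    ch <- chroms[ci, ]
    k <- config$segments_per_chrom
    raw <- stats::rgamma(k, shape = 5)
    seg_len <- round(raw / sum(raw) * ch$length_mb * 1e6)
    seg_len <- pmax(seg_len, 60000)  # every signal unitig passes the filter
    for (si in seq_len(k)) {
      if (ch$ploidy == 2L) {
        het <- stats::runif(1) < config$het_fraction
        if (het) {
          ids <- c(new_id(), new_id())
          haps <- c("H1", "H2")
        } else {
          ids <- new_id()
          haps <- "HOM"
        }
      } else {
        ids <- new_id()
        haps <- ch$haplotype
      }
      for (j in seq_along(ids)) {
        unitig_rows[[length(unitig_rows) + 1L]] <- tibble(
          unitig = ids[j],
          chromosome = ch$chromosome,
          segment = si,
          haplotype = haps[j],
          length = seg_len[si],
          orientation = if (stats::runif(1) < config$misorientation_rate) "-" else "+",
          degenerate = stats::runif(1) < config$degenerate_rate,
          acrocentric = ch$acrocentric
        )
      }
    }
  }
  truth <- dplyr::bind_rows(unitig_rows)

  # --- counts ---------------------------------------------------------------
  all_w <- list()
  all_c <- list()
  hap_w <- list()
  hap_c <- list()
  depth <- config$reads_per_mb
  for (key in split(seq_len(nrow(truth)),
                    paste(truth$chromosome, truth$segment))) {
    rows <- truth[key, ]
    ch <- rows$chromosome[1]
    lam <- rows$length[1] / 1e6 * depth
    st <- states[ch, ]
    s1 <- substr(st, 1, 1)
    s2 <- substr(st, 2, 2)
    ploidy <- chroms$ploidy[chroms$chromosome == ch]

    if (ploidy == 1L) {
      # haploid: one unitig, one strand; all reads are unique sequence
      t1 <- draw_reads(n_lib, lam)
      u <- rows$unitig[1]
      hap_strand <- if (rows$haplotype[1] == "H2") s2 else s1
      all_w[[u]] <- ifelse(hap_strand == "W", t1, 0L)
      all_c[[u]] <- ifelse(hap_strand == "C", t1, 0L)
      hap_w[[u]] <- all_w[[u]]
      hap_c[[u]] <- all_c[[u]]
    } else if (nrow(rows) == 1L) {
      # homozygous segment: collapsed unitig receives both haplotypes
      t1 <- draw_reads(n_lib, lam)
      t2 <- draw_reads(n_lib, lam)
      u <- rows$unitig[1]
      all_w[[u]] <- ifelse(s1 == "W", t1, 0L) + ifelse(s2 == "W", t2, 0L)
      all_c[[u]] <- ifelse(s1 == "C", t1, 0L) + ifelse(s2 == "C", t2, 0L)
      j1 <- rbinom_vec(t1, config$hom_informative_frac)
      j2 <- rbinom_vec(t2, config$hom_informative_frac)
      hap_w[[u]] <- ifelse(s1 == "W", j1, 0L) + ifelse(s2 == "W", j2, 0L)
      hap_c[[u]] <- ifelse(s1 == "C", j1, 0L) + ifelse(s2 == "C", j2, 0L)
    } else {
      # heterozygous bubble: informative reads hit their own arm, the
      # rest of both haplotypes' reads land on either arm at random
      u1 <- rows$unitig[rows$haplotype == "H1"]
      u2 <- rows$unitig[rows$haplotype == "H2"]
      t1 <- draw_reads(n_lib, lam)
      t2 <- draw_reads(n_lib, lam)
      i1 <- rbinom_vec(t1, config$het_informative_frac)
      i2 <- rbinom_vec(t2, config$het_informative_frac)
      u1a <- rbinom_vec(t1 - i1, 0.5)  # H1 leftovers landing on arm 1
      u2a <- rbinom_vec(t2 - i2, 0.5)  # H2 leftovers landing on arm 1
      arm1_h1 <- i1 + u1a
      arm1_h2 <- u2a
      arm2_h1 <- (t1 - i1) - u1a
      arm2_h2 <- i2 + ((t2 - i2) - u2a)
      all_w[[u1]] <- ifelse(s1 == "W", arm1_h1, 0L) + ifelse(s2 == "W", arm1_h2, 0L)
      all_c[[u1]] <- ifelse(s1 == "C", arm1_h1, 0L) + ifelse(s2 == "C", arm1_h2, 0L)
      all_w[[u2]] <- ifelse(s1 == "W", arm2_h1, 0L) + ifelse(s2 == "W", arm2_h2, 0L)
      all_c[[u2]] <- ifelse(s1 == "C", arm2_h1, 0L) + ifelse(s2 == "C", arm2_h2, 0L)
      hap_w[[u1]] <- ifelse(s1 == "W", i1, 0L)
      hap_c[[u1]] <- ifelse(s1 == "C", i1, 0L)
      hap_w[[u2]] <- ifelse(s2 == "W", i2, 0L)
      hap_c[[u2]] <- ifelse(s2 == "C", i2, 0L)
    }
  }

  # noise, degeneracy, misorientation, per unitig
  for (i in seq_len(nrow(truth))) {
    u <- truth$unitig[i]
    lam_u <- 2 * truth$length[i] / 1e6 * depth
    info_frac <- switch(
      truth$haplotype[i],
      HOM = config$hom_informative_frac,
      H1 = , H2 = if (truth$chromosome[i] %in%
                        chroms$chromosome[chroms$ploidy == 1L]) {
        1
      } else {
        config$het_informative_frac
      }
    )
    add_uniform <- function(lambda) {
      n <- stats::rbinom(n_lib, max(1L, round(2 * lambda)), 0.5)
      nw <- rbinom_vec(n, 0.5)
      list(w = nw, c = n - nw)
    }
    if (config$background_noise_rate > 0) {
      noise <- add_uniform(config$background_noise_rate * lam_u)
      all_w[[u]] <- all_w[[u]] + noise$w
      all_c[[u]] <- all_c[[u]] + noise$c
      hap_w[[u]] <- hap_w[[u]] + rbinom_vec(noise$w, info_frac)
      hap_c[[u]] <- hap_c[[u]] + rbinom_vec(noise$c, info_frac)
    }
    if (truth$degenerate[i] && config$degenerate_intensity > 0) {
      # degenerate sequence is present in many copies, so its reads have
      # multiple SMEMs and never reach the hap-informative table
      deg <- add_uniform(config$degenerate_intensity * lam_u)
      all_w[[u]] <- all_w[[u]] + deg$w
      all_c[[u]] <- all_c[[u]] + deg$c
    }
    if (truth$orientation[i] == "-") {
      tmp <- all_w[[u]]
      all_w[[u]] <- all_c[[u]]
      all_c[[u]] <- tmp
      tmp <- hap_w[[u]]
      hap_w[[u]] <- hap_c[[u]]
      hap_c[[u]] <- tmp
    }
  }

  as_count_tbl <- function(wl, cl) {
    df <- tibble(
      unitig = rep(truth$unitig, each = n_lib),
      library = rep(lib_names, times = nrow(truth)),
      w = unlist(wl[truth$unitig], use.names = FALSE),
      c = unlist(cl[truth$unitig], use.names = FALSE)
    )
    df <- df[df$w + df$c > 0, ]
    attr(df, "unitig_levels") <- truth$unitig
    attr(df, "library_levels") <- lib_names
    df
  }
  counts_all <- as_count_tbl(all_w, all_c)
  counts_hap <- as_count_tbl(hap_w, hap_c)

  # --- graph ----------------------------------------------------------------
  links <- list()
  add_links <- function(from, to) {
    if (length(from) == 0 || length(to) == 0) return()
    links[[length(links) + 1L]] <<- tidyr::expand_grid(from = from, to = to)
  }
  for (ch in chroms$chromosome) {
    tr <- truth[truth$chromosome == ch, ]
    segs <- split(tr$unitig, tr$segment)
    segs <- segs[order(as.integer(names(segs)))]
    for (si in seq_len(length(segs) - 1)) {
      add_links(segs[[si]], segs[[si + 1]])
    }
  }
  seg_tbl <- tibble(
    unitig = truth$unitig, length = truth$length, coverage = 0
  )
  if (config$tangle_nodes > 0 && length(config$acrocentric) > 0) {
    tgl_ids <- sprintf("tgl%04d", seq_len(config$tangle_nodes))
    tgl_len <- round(stats::runif(
      config$tangle_nodes, config$tangle_len_range[1], config$tangle_len_range[2]
    ))
    seg_tbl <- dplyr::bind_rows(seg_tbl, tibble(
      unitig = tgl_ids, length = tgl_len, coverage = 0
    ))
    if (length(tgl_ids) > 1) {
      links[[length(links) + 1L]] <- tibble(
        from = tgl_ids[-length(tgl_ids)], to = tgl_ids[-1]
      )
    }
    acro_chroms <- chroms$chromosome[chroms$acrocentric]
    for (j in seq_along(acro_chroms)) {
      tr <- truth[truth$chromosome == acro_chroms[j], ]
      first_seg <- tr$unitig[tr$segment == 1]
      add_links(first_seg, tgl_ids[(j - 1) %% length(tgl_ids) + 1])
    }
    truth <- dplyr::bind_rows(truth, tibble(
      unitig = tgl_ids, chromosome = "rDNA", segment = NA_integer_,
      haplotype = NA_character_, length = tgl_len,
      orientation = "+", degenerate = TRUE, acrocentric = TRUE
    ))
  }
  links <- dplyr::bind_rows(links)
  links$from_orient <- "+"
  links$to_orient <- "+"
  graph <- assembly_graph(seg_tbl, links[, c("from", "from_orient",
                                             "to", "to_orient")])

  states_long <- tibble(
    chromosome = rep(rownames(states), times = ncol(states)),
    library = rep(colnames(states), each = nrow(states)),
    state = as.vector(states)
  )
  structure(
    list(
      graph = graph, counts_all = counts_all, counts_hap = counts_hap,
      truth_unitigs = truth, truth_states = states_long, config = config
    ),
    class = "sim_bundle"
  )
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf(
    "<sim_bundle> %d unitigs, %d libraries, %d chromosomes\n",
    nrow(x$truth_unitigs), x$config$n_libraries,
    length(unique(x$truth_unitigs$chromosome))
  ))
  invisible(x)
}
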