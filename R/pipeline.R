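#' Pipeline parameters
#'
#' All tunable parameters of the phasing pipeline with their defaults.
#'
#' @param min_unitig_len length filter in bp (default 50000).
#' @param rdna_short_len tangle node length threshold in bp
#'   (default 50000).
#' @param matched_abs_ssf,min_reads strand-state discretization, see
#'   [call_strand_states()].
#' @param max_unmatched_frac,min_informative_unitigs library QC, see
#'   [library_qc()].
#' @param grow_thresh,create_thresh,merge_thresh,batch_size,min_batches,min_cluster_size,component_cov_thresh
#'   clustering, see [clustering_params()].
#' @param linkage orientation-correction linkage, see
#'   [correct_orientation()].
#' @param ev1_min,ev2_max haploid detection, see [detect_haploid()].
#' @param min_total,ratio haplotype calling, see [call_haplotypes()].
#' @param discretize_phase round phase-vector components to -1/0/+1,
#'   see [fit_phase_models()].
#' @return a named list of class `phase_params`.
#' @export
phase_params <- function(min_unitig_len = 50000, rdna_short_len = 50000,
                         matched_abs_ssf = 0.6, min_reads = 10,
                         max_unmatched_frac = 0.8,
                         min_informative_unitigs = 20,
                         grow_thresh = 0.6, create_thresh = 0.7,
                         merge_thresh = 0.5, batch_size = 1000,
                         min_batches = 5, min_cluster_size = 3,
                         component_cov_thresh = 0.02,
                         linkage = "average",
                         ev1_min = 0.70, ev2_max = 0.20,
                         min_total = 10, ratio = 0.8,
                         discretize_phase = FALSE) {
  structure(
    list(
      min_unitig_len = min_unitig_len, rdna_short_len = rdna_short_len,
      matched_abs_ssf = matched_abs_ssf, min_reads = min_reads,
      max_unmatched_frac = max_unmatched_frac,
      min_informative_unitigs = min_informative_unitigs,
      grow_thresh = grow_thresh, create_thresh = create_thresh,
      merge_thresh = merge_thresh, batch_size = batch_size,
      min_batches = min_batches, min_cluster_size = min_cluster_size,
      component_cov_thresh = component_cov_thresh, linkage = linkage,
      ev1_min = ev1_min, ev2_max = ev2_max,
      min_total = min_total, ratio = ratio,
      discretize_phase = discretize_phase
    ),
    class = "phase_params"
  )
}

#' Phase an assembly graph with Strand-seq counts
#'
#' Runs the full pipeline: GFA reading, rDNA tangle excision, connected
#' components, length filtering, SSF computation and library QC,
#' chromosome clustering, haploid detection and merging, orientation
#' correction, phase-model fitting, marker pooling and haplotype
#' calling. When `outdir` is given, writes `markers.tsv` (tab-separated
#' `node  hap1  hap2`, integer-rounded, consumable by graph threading
#' tools), `calls.tsv`, a run log, and under `annotations/`:
#' `rdna_tangle.txt`, `library_qc.tsv`, `clusters.tsv`,
#' `orientations.tsv` and `phase_vectors.tsv`.
#'
#' @param gfa path to a GFA1 file, or an [assembly_graph].
#' @param counts_all,counts_hap paths to count TSVs, or count tibbles
#'   (all-reads and haplotype-informative).
#' @param outdir optional output directory.
#' @param params a [phase_params()] list.
#' @return a list with elements `graph`, `components`, `qc`, `clusters`,
#'   `haploid`, `orientation`, `fit`, `markers`, `calls`, `log`
#'   (invisible when `outdir` is given).
#' @export
phase_assembly <- function(gfa, counts_all, counts_hap, outdir = NULL,
                           params = phase_params()) {
  log_lines <- character()
  note <- function(stage, ...) {
    line <- sprintf("stage=%s %s", stage, paste(sprintf(...), collapse = ""))
    log_lines <<- c(log_lines, line)
  }

  graph <- if (inherits(gfa, "assembly_graph")) gfa else read_gfa(gfa)
  note("read_graph", "unitigs=%d links=%d",
       nrow(graph$segments), nrow(graph$links))
  graph <- excise_rdna_tangle(graph, short_len = params$rdna_short_len)
  note("excise_rdna_tangle", "removed=%d", length(graph$excised))
  components <- component_labels(graph)
  note("components", "n=%d", length(unique(components$component)))

  counts_all <- if (is.character(counts_all)) {
    read_strand_counts(counts_all)
  } else {
    strand_counts(counts_all)
  }
  counts_hap <- if (is.character(counts_hap)) {
    read_strand_counts(counts_hap)
  } else {
    strand_counts(counts_hap)
  }

  retained <- filter_by_length(graph, params$min_unitig_len)
  retained <- intersect(attr(counts_all, "unitig_levels") %||%
                          unique(counts_all$unitig), retained)
  note("length_filter", "retained=%d of %d",
       length(retained), nrow(graph$segments))

  sub_all <- counts_all[counts_all$unitig %in% retained, ]
  attr(sub_all, "unitig_levels") <- retained
  attr(sub_all, "library_levels") <- attr(counts_all, "library_levels")
  ssf_all <- strand_state_frequency(sub_all)
  states <- call_strand_states(ssf_all, params$matched_abs_ssf,
                               params$min_reads)
  qc <- library_qc(states, params$max_unmatched_frac,
                   params$min_informative_unitigs)
  note("library_qc", "retained=%d of %d", length(qc$libraries),
       nrow(qc$report))

  keep_lib <- function(df) {
    out <- df[df$library %in% qc$libraries, ]
    attr(out, "unitig_levels") <- attr(df, "unitig_levels")
    attr(out, "library_levels") <- intersect(
      attr(df, "library_levels") %||% unique(df$library), qc$libraries
    )
    out
  }
  ssf_all <- keep_lib(ssf_all)
  n_signal <- length(unique(ssf_all$unitig[ssf_all$defined]))
  note("unitig_qc", "with_signal=%d of %d", n_signal, length(retained))

  cl_params <- clustering_params(
    grow_thresh = params$grow_thresh, create_thresh = params$create_thresh,
    merge_thresh = params$merge_thresh, batch_size = params$batch_size,
    min_batches = params$min_batches,
    min_cluster_size = params$min_cluster_size,
    component_cov_thresh = params$component_cov_thresh
  )
  clusters <- cluster_unitigs(ssf_all, graph, cl_params)
  n_cl <- length(unique(stats::na.omit(clusters$assignment$cluster)))
  note("clustering", "clusters=%d clustered=%d unclustered=%d", n_cl,
       sum(!is.na(clusters$assignment$cluster)),
       sum(is.na(clusters$assignment$cluster)))

  sub_hap <- counts_hap[counts_hap$unitig %in% retained, ]
  attr(sub_hap, "unitig_levels") <- retained
  attr(sub_hap, "library_levels") <- attr(counts_hap, "library_levels")
  ssf_hap <- keep_lib(strand_state_frequency(sub_hap))

  haploid <- detect_haploid(ssf_hap, clusters, params$ev1_min,
                            params$ev2_max)
  n_hap <- sum(haploid$flags$haploid, na.rm = TRUE)
  note("haploid_detection", "haploid_clusters=%d", n_hap)
  merged_assignment <- haploid$assignment
  flagged <- haploid$flags$cluster[!is.na(haploid$flags$haploid) &
                                     haploid$flags$haploid]
  hap_labels <- if (length(flagged) > 0) min(flagged) else character()

  orientation <- correct_orientation(ssf_all, merged_assignment,
                                     linkage = params$linkage)
  note("orientation", "flipped=%d ambiguous=%d",
       sum(orientation$orientation == "FLIPPED"), sum(orientation$ambiguous))

  counts_hap_or <- apply_orientation(keep_lib(sub_hap), orientation)
  ssf_hap_or <- keep_lib(strand_state_frequency(counts_hap_or))
  fit <- fit_phase_models(ssf_hap_or, merged_assignment, graph,
                          haploid = hap_labels,
                          discretize = params$discretize_phase)
  note("phase_models", "fitted=%d", length(fit$models))

  markers <- pool_markers(counts_hap_or, fit, merged_assignment)
  calls <- call_haplotypes(markers, params$min_total, params$ratio)
  unclustered <- setdiff(retained, calls$unitig)
  calls <- dplyr::bind_rows(
    calls,
    tibble(unitig = unclustered, cluster = NA_character_,
           hap1 = 0, hap2 = 0, call = "NONE")
  ) |>
    dplyr::arrange(.data$unitig)
  note("calls", "hap1=%d hap2=%d hom=%d none=%d",
       sum(calls$call == "HAP1"), sum(calls$call == "HAP2"),
       sum(calls$call == "HOM"), sum(calls$call == "NONE"))

  result <- list(
    graph = graph, components = components, qc = qc, clusters = clusters,
    haploid = haploid, orientation = orientation, fit = fit,
    markers = markers, calls = calls, counts_hap_oriented = counts_hap_or,
    log = log_lines, params = params
  )
  if (!is.null(outdir)) {
    write_phase_outputs(result, outdir)
    return(invisible(result))
  }
  result
}

# Write all pipeline outputs under outdir.
write_phase_outputs <- function(result, outdir) {
  ann <- file.path(outdir, "annotations")
  dir.create(ann, recursive = TRUE, showWarnings = FALSE)

  writeLines(result$graph$excised, file.path(ann, "rdna_tangle.txt"))
  readr::write_tsv(result$qc$report, file.path(ann, "library_qc.tsv"),
                   progress = FALSE)
  comp <- result$components
  readr::write_tsv(
    dplyr::left_join(result$clusters$assignment, comp, by = "unitig"),
    file.path(ann, "clusters.tsv"), progress = FALSE
  )
  readr::write_tsv(result$orientation, file.path(ann, "orientations.tsv"),
                   progress = FALSE)
  pv <- tidy(result$fit)
  readr::write_tsv(pv, file.path(ann, "phase_vectors.tsv"), progress = FALSE)

  markers_out <- tibble(
    node = result$markers$unitig,
    hap1 = round(result$markers$hap1),
    hap2 = round(result$markers$hap2)
  )
  readr::write_tsv(markers_out, file.path(outdir, "markers.tsv"),
                   progress = FALSE)
  readr::write_tsv(
    dplyr::select(result$calls, node = "unitig", "cluster", "call"),
    file.path(outdir, "calls.tsv"), progress = FALSE
  )
  writeLines(result$log, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
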