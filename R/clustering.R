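#' Clustering parameters
#'
#' Parameters of the batched agglomerative chromosome clustering and its
#' refinement. The three similarity thresholds act on mean pairwise
#' absolute cosine similarity and so live in (0, 1].
#'
#' @param grow_thresh minimum unitig-to-cluster similarity to attach an
#'   unclustered unitig to an existing cluster (default 0.6).
#' @param create_thresh minimum unitig-to-unitig similarity to seed a new
#'   cluster from the best unclustered pair (default 0.7).
#' @param merge_thresh minimum cluster-to-cluster similarity to merge two
#'   clusters (default 0.5).
#' @param batch_size unitigs per coverage-ranked batch (default 1000).
#' @param min_batches if chunking by `batch_size` yields fewer batches
#'   than this, split into this many near-equal quantile batches instead
#'   (default 5).
#' @param min_cluster_size clusters smaller than this are dissolved
#'   during refinement (default 3).
#' @param component_cov_thresh clusters holding less than this fraction
#'   of a connected component's clustered base pairs are dissolved during
#'   refinement (default 0.02).
#' @return a named list of class `clustering_params`.
#' @export
clustering_params <- function(grow_thresh = 0.6, create_thresh = 0.7,
                              merge_thresh = 0.5, batch_size = 1000,
                              min_batches = 5, min_cluster_size = 3,
                              component_cov_thresh = 0.02) {
  stopifnot(
    grow_thresh > 0, grow_thresh <= 1,
    create_thresh > 0, create_thresh <= 1,
    merge_thresh > 0, merge_thresh <= 1,
    component_cov_thresh >= 0, component_cov_thresh < 1
  )
  structure(
    list(
      grow_thresh = grow_thresh, create_thresh = create_thresh,
      merge_thresh = merge_thresh, batch_size = batch_size,
      min_batches = min_batches, min_cluster_size = min_cluster_size,
      component_cov_thresh = component_cov_thresh
    ),
    class = "clustering_params"
  )
}

#' Batch unitigs by coverage quantile
#'
#' Unitigs are ranked by descending coverage (ties by id) and chunked
#' into batches of `batch_size`; if that yields fewer than `min_batches`
#' batches they are instead split into `min_batches` near-equal quantile
#' batches (empty batches dropped). Batches are returned in descending
#' mean-coverage order so high-signal unitigs seed the clustering.
#'
#' @param coverage named numeric vector, one value per unitig.
#' @param batch_size,min_batches see [clustering_params()].
#' @return list of character vectors of unitig ids.
#' @export
make_batches <- function(coverage, batch_size = 1000, min_batches = 5) {
  n <- length(coverage)
  if (n == 0) return(list())
  ids <- names(coverage)[order(-coverage, names(coverage))]
  n_batches <- ceiling(n / batch_size)
  if (n_batches < min_batches) {
    sizes <- rep(n %/% min_batches, min_batches)
    extra <- n %% min_batches
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
    sizes <- sizes[sizes > 0]
    grp <- rep(seq_along(sizes), sizes)
  } else {
    grp <- rep(seq_len(n_batches), each = batch_size, length.out = n)
  }
  unname(split(ids, grp))
}

# -- internal clustering engine ---------------------------------------------

# State: assignment is an integer vector aligned with rownames(S) (NA =
# unclustered); clusters are integer labels in creation order, merged
# clusters keep the smaller label. Ties always resolve to the
# lexicographically smallest (unitig id, cluster id) pair; rows are
# pre-sorted by id so the first index wins.

# Mean similarity of each cluster to each unclustered unitig.
cluster_unc_sims <- function(S, assignment, unc_idx) {
  cl_idx <- which(!is.na(assignment))
  g <- assignment[cl_idx]
  sums <- rowsum(S[cl_idx, unc_idx, drop = FALSE], group = g)
  sizes <- as.vector(table(g))
  sums / sizes
}

# Mean pairwise similarity between every pair of clusters.
cluster_pair_sims <- function(S, assignment) {
  cl_idx <- which(!is.na(assignment))
  g <- assignment[cl_idx]
  sums <- rowsum(t(rowsum(S[cl_idx, cl_idx, drop = FALSE], group = g)),
                 group = g)
  sizes <- as.vector(table(g))
  sums / outer(sizes, sizes)
}

# One grow/create/merge cycle over the currently active rows. Returns
# the updated assignment plus whether any action fired.
run_cluster_pass <- function(S, assignment, active, components, params,
                             next_label) {
  any_action <- FALSE
  repeat {
    fired <- FALSE
    # GROW: repeatedly attach the best unclustered unitig.
    repeat {
      unc_idx <- which(active & is.na(assignment))
      if (length(unc_idx) == 0 || !any(!is.na(assignment))) break
      sims <- cluster_unc_sims(S, assignment, unc_idx)
      best <- max(sims)
      if (best <= params$grow_thresh) break
      hit <- which(sims == best, arr.ind = TRUE)
      # smallest unitig id first, then smallest cluster label
      labels <- as.integer(rownames(sims))
      hit <- hit[order(hit[, 2], labels[hit[, 1]]), , drop = FALSE]
      u <- unc_idx[hit[1, 2]]
      assignment[u] <- labels[hit[1, 1]]
      fired <- TRUE
      any_action <- TRUE
    }
    # CREATE: seed a new cluster from the best unclustered pair.
    unc_idx <- which(active & is.na(assignment))
    if (length(unc_idx) >= 2) {
      Su <- S[unc_idx, unc_idx, drop = FALSE]
      diag(Su) <- -Inf
      best <- max(Su)
      if (best > params$create_thresh) {
        hit <- which(Su == best, arr.ind = TRUE)
        hit <- cbind(pmin(hit[, 1], hit[, 2]), pmax(hit[, 1], hit[, 2]))
        hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
        assignment[unc_idx[hit[1, ]]] <- next_label
        next_label <- next_label + 1L
        any_action <- TRUE
        next  # back to GROW
      }
    }
    if (!fired) break else break
  }
  # MERGE: component-restricted first, then global.
  for (restricted in c(TRUE, FALSE)) {
    repeat {
      labels <- sort(unique(assignment[!is.na(assignment)]))
      if (length(labels) < 2) break
      sims <- cluster_pair_sims(S, assignment)
      lab <- as.integer(rownames(sims))
      allowed <- upper.tri(sims)
      if (restricted) {
        comps <- lapply(lab, function(k) {
          unique(components[which(assignment == k)])
        })
        share <- outer(seq_along(lab), seq_along(lab), Vectorize(function(i, j) {
          length(intersect(comps[[i]], comps[[j]])) > 0
        }))
        allowed <- allowed & share
      }
      if (!any(allowed)) break
      vals <- sims
      vals[!allowed] <- -Inf
      best <- max(vals)
      if (best <= params$merge_thresh) break
      hit <- which(vals == best, arr.ind = TRUE)
      hit <- hit[order(lab[hit[, 1]], lab[hit[, 2]]), , drop = FALSE]
      a <- lab[hit[1, 1]]
      b <- lab[hit[1, 2]]
      keep <- min(a, b)
      assignment[assignment %in% c(a, b)] <- keep
      any_action <- TRUE
    }
  }
  list(assignment = assignment, next_label = next_label,
       any_action = any_action)
}

#' Batched agglomerative clustering on absolute cosine similarity
#'
#' Implements the initial clustering loop: batches are admitted in
#' descending coverage order; within the active set the algorithm
#' alternates cluster growing (attach the unclustered unitig with the
#' highest mean similarity to any cluster while it exceeds
#' `grow_thresh`), cluster creation (seed a new cluster from the best
#' unclustered pair above `create_thresh`, then return to growing) and,
#' once neither fires, cluster merging above `merge_thresh` (first
#' restricted to cluster pairs sharing a connected component, then
#' globally). Earlier unclustered unitigs stay eligible as later batches
#' arrive; after the last batch, passes repeat until no action fires.
#' All ties break to the lexicographically smallest (unitig id, cluster
#' id) pair, so results are reproducible.
#'
#' @param V numeric matrix of SSF vectors, one row per unitig (rownames
#'   = unitig ids), one column per retained library.
#' @param components named vector mapping unitig id to connected
#'   component (used by the restricted merge step).
#' @param coverage named numeric vector used for batching.
#' @param params a [clustering_params()] list.
#' @param initial optional named integer vector of existing cluster
#'   labels (NA = unclustered); existing clusters are retained and can
#'   grow. Batches are formed over the unclustered unitigs only.
#' @return a named integer vector of cluster labels (NA = unclustered).
#' @export
cluster_batched <- function(V, components, coverage,
                            params = clustering_params(), initial = NULL) {
  if (nrow(V) == 0) return(stats::setNames(integer(0), character(0)))
  ord <- order(rownames(V))
  V <- V[ord, , drop = FALSE]
  ids <- rownames(V)
  S <- abs_cos_matrix(V)
  assignment <- rep(NA_integer_, length(ids))
  names(assignment) <- ids
  if (!is.null(initial)) {
    assignment[names(initial)] <- initial
  }
  next_label <- if (all(is.na(assignment))) 1L else max(assignment, na.rm = TRUE) + 1L
  comp_vec <- components[ids]

  to_batch <- ids[is.na(assignment)]
  batches <- make_batches(coverage[to_batch], params$batch_size,
                          params$min_batches)
  active <- !is.na(assignment)  # seeded members are always active
  names(active) <- ids
  for (b in batches) {
    active[b] <- TRUE
    res <- run_cluster_pass(S, assignment, active, comp_vec, params,
                            next_label)
    assignment <- res$assignment
    next_label <- res$next_label
  }
  # final passes until quiescent
  repeat {
    res <- run_cluster_pass(S, assignment, active, comp_vec, params,
                            next_label)
    assignment <- res$assignment
    next_label <- res$next_label
    if (!res$any_action) break
  }
  assignment
}

#' Refine a clustering
#'
#' Three cleanup rules: (1) clusters smaller than `min_cluster_size`
#' are dissolved; (2) per connected component, clusters holding less
#' than `component_cov_thresh` of the component's clustered base pairs
#' are dissolved on that component; (3) components containing exactly
#' one cluster absorb their unclustered unitigs into it.
#'
#' @param assignment named integer vector (NA = unclustered).
#' @param components named vector of component labels.
#' @param lengths named numeric vector of unitig lengths (bp).
#' @param params a [clustering_params()] list.
#' @return list with `assignment` (refined labels) and `absorbed`
#'   (ids assigned by rule 3).
#' @export
refine_clusters <- function(assignment, components, lengths,
                            params = clustering_params()) {
  ids <- names(assignment)
  comp <- components[ids]
  len <- lengths[ids]

  # (1) dissolve small clusters
  sizes <- table(assignment)
  small <- as.integer(names(sizes)[sizes < params$min_cluster_size])
  assignment[assignment %in% small] <- NA_integer_

  # (2) dissolve clusters covering too little of a component
  cl <- !is.na(assignment)
  if (any(cl)) {
    df <- tibble(
      id = ids[cl], cluster = assignment[cl],
      component = comp[cl], length = len[cl]
    )
    frac <- df |>
      dplyr::group_by(.data$component, .data$cluster) |>
      dplyr::summarise(bp = sum(.data$length), .groups = "drop_last") |>
      dplyr::mutate(frac = .data$bp / sum(.data$bp)) |>
      dplyr::ungroup()
    weak <- frac[frac$frac < params$component_cov_thresh, ]
    if (nrow(weak) > 0) {
      drop <- paste(comp[ids], assignment[ids]) %in%
        paste(weak$component, weak$cluster)
      assignment[drop] <- NA_integer_
    }
  }

  # (3) single-cluster components absorb their unclustered unitigs
  absorbed <- character()
  for (cc in unique(comp)) {
    in_cc <- which(comp == cc)
    labs <- unique(assignment[in_cc])
    labs <- labs[!is.na(labs)]
    if (length(labs) == 1) {
      stray <- in_cc[is.na(assignment[in_cc])]
      if (length(stray) > 0) {
        assignment[stray] <- labs
        absorbed <- c(absorbed, ids[stray])
      }
    }
  }
  list(assignment = assignment, absorbed = absorbed)
}

#' Cluster unitigs by homologous chromosome pair
#'
#' Full chromosome clustering: batched agglomerative clustering on
#' absolute cosine similarity of all-reads SSF vectors, refinement, a
#' second clustering round over the remaining unclustered unitigs (with
#' existing clusters retained and growable), and a second refinement.
#'
#' @param ssf all-reads SSF tibble from [strand_state_frequency()],
#'   restricted to retained libraries and length-filtered unitigs.
#' @param graph an [assembly_graph] (provides components and lengths).
#' @param params a [clustering_params()] list.
#' @param coverage optional named coverage vector for batching; by
#'   default computed as total aligned reads / length from the count
#'   columns of `ssf`, falling back to length rank when all zero.
#' @return an object of class `strand_clusters`: list with `assignment`
#'   (tibble `unitig`, `cluster`, `provenance`), `audit` (per-stage
#'   counts) and `params`. Cluster labels are `c01`, `c02`, ... ordered
#'   by each cluster's smallest member id.
#' @export
cluster_unitigs <- function(ssf, graph, params = clustering_params(),
                            coverage = NULL) {
  V <- ssf_matrix(ssf)
  if (nrow(V) == 0) {
    return(structure(
      list(
        assignment = tibble(
          unitig = character(), cluster = character(), provenance = character()
        ),
        audit = tibble(stage = character(), n_clustered = integer(),
                       n_clusters = integer()),
        params = params
      ),
      class = "strand_clusters"
    ))
  }
  comp_tbl <- component_labels(graph)
  components <- stats::setNames(comp_tbl$component, comp_tbl$unitig)
  lengths <- stats::setNames(graph$segments$length, graph$segments$unitig)
  missing <- setdiff(rownames(V), names(components))
  if (length(missing) > 0) {
    up_abort(sprintf(
      "unitigs absent from graph: %s", paste(head(missing, 5), collapse = ", ")
    ))
  }
  if (is.null(coverage)) {
    totals <- tapply(ssf$w + ssf$c, ssf$unitig, sum)[rownames(V)]
    coverage <- as.vector(totals) / lengths[rownames(V)]
    if (all(coverage == 0, na.rm = TRUE)) {
      coverage <- lengths[rownames(V)]
    }
    names(coverage) <- rownames(V)
  }

  audit <- list()
  note <- function(stage, a) {
    tibble(stage = stage, n_clustered = sum(!is.na(a)),
           n_clusters = length(unique(a[!is.na(a)])))
  }

  a1 <- cluster_batched(V, components, coverage, params)
  audit$initial <- note("initial_clustering", a1)
  r1 <- refine_clusters(a1, components, lengths, params)
  audit$refine1 <- note("refinement_1", r1$assignment)

  unc <- names(r1$assignment)[is.na(r1$assignment)]
  a2 <- r1$assignment
  if (length(unc) > 0) {
    a2 <- cluster_batched(
      V, components, coverage[unc], params,
      initial = r1$assignment[!is.na(r1$assignment)]
    )
  }
  audit$second <- note("second_clustering", a2)
  r2 <- refine_clusters(a2, components, lengths, params)
  audit$refine2 <- note("refinement_2", r2$assignment)
  final <- r2$assignment

  provenance <- rep(NA_character_, length(final))
  names(provenance) <- names(final)
  provenance[!is.na(final)] <- "refined"
  round1 <- names(r1$assignment)[!is.na(r1$assignment)]
  provenance[intersect(round1, names(final)[!is.na(final)])] <- "initial"
  provenance[intersect(c(r1$absorbed, r2$absorbed),
                       names(final)[!is.na(final)])] <- "absorbed"

  # deterministic public labels, ordered by smallest member id
  labs <- sort(unique(final[!is.na(final)]))
  first_member <- vapply(labs, function(k) min(names(final)[which(final == k)]),
                         character(1))
  ord <- labs[order(first_member)]
  width <- max(2, nchar(length(ord)))
  public <- stats::setNames(sprintf(paste0("c%0", width, "d"),
                                    seq_along(ord)), ord)
  assignment <- tibble(
    unitig = names(final),
    cluster = ifelse(is.na(final), NA_character_,
                     public[as.character(final)]),
    provenance = provenance
  ) |>
    dplyr::arrange(.data$unitig)

  structure(
    list(assignment = assignment, audit = dplyr::bind_rows(audit),
         params = params),
    class = "strand_clusters"
  )
}

#' @export
print.strand_clusters <- function(x, ...) {
  n <- nrow(x$assignment)
  k <- length(unique(stats::na.omit(x$assignment$cluster)))
  cat(sprintf(
    "<strand_clusters> %d unitigs in %d clusters (%d unclustered)\n",
    n, k, sum(is.na(x$assignment$cluster))
  ))
  invisible(x)
}
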