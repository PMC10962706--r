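# Phase-vector inference and haplotype-informative library pooling.
#
# In hap-informative SSF space the unitig vectors of a diploid cluster
# fall on three ideal directions -- maternal, paternal, homozygous --
# all lying in the 2-D "chromosome plane" spanned by the cluster vector
# v_clust and an orthogonal phase vector v_phase (the difference of the
# two haplotype directions). v_phase's non-zero components mark the
# unmatched-strand-state (phase-informative) libraries and their signs
# say which orientation maps to which haplotype.

# Orthonormal completion: a deterministic unit vector orthogonal to v.
orthogonal_complement <- function(v) {
  e <- numeric(length(v))
  e[which.min(abs(v))] <- 1
  u <- e - sum(e * v) * v
  u / sqrt(sum(u^2))
}

# Fix basis vector signs: largest-|.| component positive.
fix_sign <- function(v) {
  s <- sign(v[which.max(abs(v))])
  if (s < 0) -v else v
}

#' Infer the chromosome plane of a cluster
#'
#' Uncentered SVD of the cluster's hap-informative SSF vectors; the top
#' two right singular vectors span the chromosome plane (a subspace
#' through the origin, as required for projecting and rotating
#' `v_clust`), and squared singular values give the explained-variance
#' proportions used for haploid detection.
#'
#' @param X numeric matrix, one hap-informative SSF vector per row
#'   (>= 2 rows).
#' @return list with `basis` (libraries x 2, orthonormal columns), `ev`
#'   (proportions for components 1 and 2) and `rank1` (TRUE when the
#'   vectors span only a line, in which case the second basis vector is
#'   an arbitrary deterministic completion).
#' @export
chromosome_plane <- function(X) {
  if (nrow(X) < 2) up_abort("chromosome_plane needs at least 2 vectors")
  s <- svd(X)
  tot <- sum(s$d^2)
  if (tot == 0) up_abort("chromosome_plane: all vectors are zero")
  ev <- (s$d^2 / tot)
  ev <- c(ev, 0, 0)[1:2]
  b1 <- fix_sign(s$v[, 1])
  rank1 <- length(s$d) < 2 || s$d[2] <= s$d[1] * 1e-8
  b2 <- if (rank1) orthogonal_complement(b1) else fix_sign(s$v[, 2])
  list(basis = cbind(b1, b2, deparse.level = 0), ev = ev, rank1 = rank1)
}

#' Size-weighted cluster vector
#'
#' `v_clust` is the length-weighted average of the orientation-corrected
#' unitig SSF vectors of a cluster; length weighting ensures that
#' unequal fragmentation of the two haplotypes does not skew it.
#'
#' @param X numeric matrix, one vector per row (rownames = unitig ids).
#' @param lengths named numeric vector of unitig lengths (bp).
#' @return numeric vector over libraries.
#' @export
cluster_vector <- function(X, lengths) {
  if (nrow(X) == 0) up_abort("cluster_vector: empty cluster")
  wts <- lengths[rownames(X)]
  if (any(is.na(wts))) up_abort("cluster_vector: missing unitig lengths")
  as.vector(wts %*% X) / sum(wts)
}

#' Phase vector from cluster vector and plane
#'
#' Projects `v_clust` into the chromosome plane and rotates the
#' projection 90 degrees within the plane; the result is orthogonal to
#' the projected cluster vector and identifies the phase-informative
#' libraries. Haplotype labels are parentage-unknown, so either rotation
#' sign is valid; the result is rescaled so its largest-|.| component
#' equals +1, which both fixes the sign deterministically and puts the
#' components on the scale of the ideal -1/0/+1 pattern.
#'
#' @param v_clust cluster vector over libraries.
#' @param basis orthonormal plane basis from [chromosome_plane()].
#' @return numeric `v_phase` vector over libraries.
#' @export
phase_vector <- function(v_clust, basis) {
  xy <- as.vector(t(basis) %*% v_clust)
  if (sqrt(sum(xy^2)) < 1e-8 * sqrt(sum(v_clust^2))) {
    up_abort("cluster vector is orthogonal to the chromosome plane")
  }
  vp <- as.vector(basis %*% c(-xy[2], xy[1]))
  vp / vp[which.max(abs(vp))]
}

#' Haploid phase-vector correction
#'
#' For a merged haploid cluster (e.g. X + Y), the size-weighted
#' `v_clust` is biased toward the larger chromosome, rotating it off the
#' bisector of the two chromosome directions and biasing `v_phase`. The
#' correction projects each unitig vector into the plane, expresses it
#' in (v_clust, v_phase) coordinates, and uses the product of the two
#' coordinates to find the extreme "representative" unitigs of either
#' chromosome; `v_clust` is then rotated to bisect the two
#' representative directions and `v_phase` re-derived as its in-plane
#' 90-degree rotation.
#'
#' @param v_clust,v_phase current vectors over libraries.
#' @param X matrix of the cluster's unitig SSF vectors (rows).
#' @param basis orthonormal plane basis from [chromosome_plane()].
#' @return list with corrected `v_clust` and `v_phase`. When all
#'   dimension products coincide (a single haploid chromosome: nothing
#'   to bisect) the inputs are returned unchanged with a warning.
#' @export
haploid_correction <- function(v_clust, v_phase, X, basis) {
  P <- X %*% basis                       # unitig plane coordinates
  P <- normalize_rows(P)                 # directions only; magnitude-free
  vc <- as.vector(t(basis) %*% v_clust)  # v_clust in plane coordinates
  u1 <- vc / sqrt(sum(vc^2))
  u2 <- c(-u1[2], u1[1])                 # in-plane 90-degree rotation
  a <- as.vector(P %*% u1)
  b <- as.vector(P %*% u2)
  prod <- a * b
  if (max(prod) - min(prod) < 1e-12) {
    rlang::warn("haploid correction skipped: all dimension products equal")
    return(list(v_clust = v_clust, v_phase = v_phase))
  }
  r_plus <- P[which.max(prod), ]
  r_minus <- P[which.min(prod), ]
  bis <- r_plus + r_minus
  nb <- sqrt(sum(bis^2))
  if (nb < 1e-8) {
    rlang::warn("haploid correction skipped: antipodal representatives")
    return(list(v_clust = v_clust, v_phase = v_phase))
  }
  bis <- bis / nb
  scale <- sqrt(sum(vc^2))
  new_vc <- as.vector(basis %*% (bis * scale))
  vp <- as.vector(basis %*% c(-bis[2], bis[1]))
  vp <- vp / vp[which.max(abs(vp))]
  list(v_clust = new_vc, v_phase = vp)
}

#' Detect and merge haploid chromosome clusters
#'
#' Diploid clusters spread across the full chromosome plane in
#' hap-informative SSF space, while the unitigs of a haploid chromosome
#' stay on a single line, so the uncentered PCA explained-variance split
#' separates the two cases: clusters with component-1 proportion above
#' `ev1_min` and component-2 proportion below `ev2_max` are flagged
#' haploid. All haploid clusters are merged into a single cluster so
#' that shared sequence such as the pseudoautosomal region phases
#' together. The flags are invariant to unitig orientation (negating
#' rows leaves the uncentered covariance unchanged), so detection may
#' run before or after orientation correction.
#'
#' @param ssf_hap hap-informative SSF tibble over retained libraries.
#' @param clusters a `strand_clusters` object or assignment tibble.
#' @param ev1_min,ev2_max explained-variance thresholds (defaults 0.70
#'   and 0.20).
#' @return list with `flags` (tibble: `cluster`, `n`, `ev1`, `ev2`,
#'   `haploid`; `haploid` is NA for clusters of size < 2, which are not
#'   evaluated) and `assignment` (tibble with haploid clusters merged;
#'   the merged cluster keeps the smallest participating label).
#' @export
detect_haploid <- function(ssf_hap, clusters, ev1_min = 0.70,
                           ev2_max = 0.20) {
  assignment <- if (inherits(clusters, "strand_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  check_columns(assignment, c("unitig", "cluster"), "cluster assignment")
  V <- ssf_matrix(ssf_hap)
  clustered <- assignment[!is.na(assignment$cluster), ]
  flags <- lapply(split(clustered$unitig, clustered$cluster), function(ids) {
    if (length(ids) < 2) {
      return(tibble(n = length(ids), ev1 = NA_real_, ev2 = NA_real_,
                    haploid = NA))
    }
    pl <- chromosome_plane(V[ids, , drop = FALSE])
    tibble(n = length(ids), ev1 = pl$ev[1], ev2 = pl$ev[2],
           haploid = pl$ev[1] > ev1_min & pl$ev[2] < ev2_max)
  })
  flags <- dplyr::bind_rows(flags, .id = "cluster")
  hap_labels <- flags$cluster[!is.na(flags$haploid) & flags$haploid]
  merged <- assignment
  if (length(hap_labels) >= 2) {
    keep <- min(hap_labels)
    merged$cluster[merged$cluster %in% hap_labels] <- keep
  }
  list(flags = flags, assignment = merged)
}

#' Fit per-cluster phase models
#'
#' For each cluster: infer the chromosome plane (uncentered PCA of
#' hap-informative SSF vectors), compute the size-weighted cluster
#' vector, derive the phase vector by in-plane 90-degree rotation, and,
#' for haploid clusters, apply the representative-bisection correction.
#'
#' @param ssf_hap orientation-corrected hap-informative SSF tibble.
#' @param clusters assignment tibble (`unitig`, `cluster`), typically
#'   the merged assignment from [detect_haploid()].
#' @param graph an [assembly_graph] (unitig lengths for size weighting).
#' @param haploid optional character vector of haploid cluster labels
#'   (after merging, usually at most one).
#' @param discretize if TRUE, round phase-vector components to the
#'   ideal -1/0/+1 pattern (sign where |component| >= 0.5, else 0)
#'   before pooling.
#' @return an object of class `phase_fit`: per-cluster models with
#'   `v_clust`, `v_phase`, `basis`, `ev`, `haploid`, `rank1` and the
#'   unitig plane coordinates. Clusters with a single member are skipped
#'   with a warning (no plane can be inferred).
#' @export
fit_phase_models <- function(ssf_hap, clusters, graph, haploid = character(),
                             discretize = FALSE) {
  assignment <- if (inherits(clusters, "strand_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  check_columns(assignment, c("unitig", "cluster"), "cluster assignment")
  V <- ssf_matrix(ssf_hap)
  lengths <- stats::setNames(graph$segments$length, graph$segments$unitig)
  clustered <- assignment[!is.na(assignment$cluster), ]
  groups <- split(clustered$unitig, clustered$cluster)

  models <- list()
  for (lab in names(groups)) {
    ids <- sort(groups[[lab]])
    if (length(ids) < 2) {
      rlang::warn(sprintf(
        "cluster %s has a single member; no phase model fitted", lab
      ))
      next
    }
    X <- V[ids, , drop = FALSE]
    pl <- chromosome_plane(X)
    vc <- cluster_vector(X, lengths)
    vp <- phase_vector(vc, pl$basis)
    is_hap <- lab %in% haploid
    if (is_hap) {
      corr <- haploid_correction(vc, vp, X, pl$basis)
      vc <- corr$v_clust
      vp <- corr$v_phase
    }
    if (discretize) {
      vp <- ifelse(abs(vp) >= 0.5, sign(vp), 0)
    }
    coords <- X %*% pl$basis
    models[[lab]] <- list(
      cluster = lab,
      v_clust = stats::setNames(vc, colnames(V)),
      v_phase = stats::setNames(vp, colnames(V)),
      basis = pl$basis, ev = pl$ev, rank1 = pl$rank1, haploid = is_hap,
      coords = tibble(
        unitig = ids, pc1 = coords[, 1], pc2 = coords[, 2]
      )
    )
  }
  structure(
    list(models = models, libraries = colnames(V)),
    class = "phase_fit"
  )
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf(
    "<phase_fit> %d cluster(s) over %d libraries (%d haploid)\n",
    length(x$models), length(x$libraries),
    sum(vapply(x$models, function(m) m$haploid, logical(1)))
  ))
  invisible(x)
}

#' Pool haplotype-informative counts into marker counts
#'
#' For each library, Watson and Crick counts are swapped where the phase
#' vector component is negative (so that one haplotype's template strand
#' is consistently labeled across libraries), and then the Watson and
#' Crick count columns are each dotted with `|v_phase|`, yielding a pair
#' of haplotype marker counts per unitig. Components act as continuous
#' weights, so matched-state libraries (components near 0) contribute
#' almost nothing. By construction `hap1 + hap2` equals
#' `sum_l |v_phase_l| * (w_l + c_l)` exactly for every unitig.
#'
#' @param counts_hap orientation-corrected hap-informative count table.
#' @param fit a `phase_fit` from [fit_phase_models()].
#' @param clusters assignment tibble matching `fit` (merged labels).
#' @return tibble with columns `unitig`, `cluster`, `hap1`, `hap2`.
#' @export
pool_markers <- function(counts_hap, fit, clusters) {
  assignment <- if (inherits(clusters, "strand_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  mats <- count_matrices(counts_hap,
                         unitigs = unique(counts_hap$unitig),
                         libraries = fit$libraries)
  out <- lapply(fit$models, function(m) {
    ids <- assignment$unitig[!is.na(assignment$cluster) &
                               assignment$cluster == m$cluster]
    ids <- sort(intersect(ids, rownames(mats$W)))
    if (length(ids) == 0) return(NULL)
    W <- mats$W[ids, , drop = FALSE]
    C <- mats$C[ids, , drop = FALSE]
    neg <- m$v_phase < 0
    Wp <- W
    Cp <- C
    Wp[, neg] <- C[, neg]
    Cp[, neg] <- W[, neg]
    wts <- abs(m$v_phase)
    tibble(
      unitig = ids,
      cluster = m$cluster,
      hap1 = as.vector(Wp %*% wts),
      hap2 = as.vector(Cp %*% wts)
    )
  })
  dplyr::bind_rows(out) |> dplyr::arrange(.data$unitig)
}

#' Call unitig haplotypes from marker counts
#'
#' A simple threshold caller on the pooled marker counts: `NONE` below
#' `min_total` total markers, `HAP1`/`HAP2` when one haplotype holds at
#' least `ratio` of the markers, `HOM` otherwise (homozygous unitigs
#' receive balanced markers from both haplotypes). Downstream graph
#' threading tools consume the marker counts themselves; this caller
#' provides a self-contained per-unitig assignment.
#'
#' @param markers tibble from [pool_markers()].
#' @param min_total minimum `hap1 + hap2` to call (default 10).
#' @param ratio majority fraction for a haplotype call (default 0.8).
#' @return the input tibble with an added `call` column.
#' @export
call_haplotypes <- function(markers, min_total = 10, ratio = 0.8) {
  check_columns(markers, c("unitig", "hap1", "hap2"), "marker counts")
  dplyr::mutate(
    markers,
    total = .data$hap1 + .data$hap2,
    call = dplyr::case_when(
      .data$total < min_total ~ "NONE",
      .data$hap1 / .data$total >= ratio ~ "HAP1",
      .data$hap2 / .data$total >= ratio ~ "HAP2",
      TRUE ~ "HOM"
    )
  ) |>
    dplyr::select(-"total")
}
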