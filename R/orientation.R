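#' Detect and correct misoriented unitigs
#'
#' Within a chromosome cluster, unitigs in opposite orientation have
#' all-reads SSF vectors pointing in opposite directions along the same
#' cluster axis, so signed cosine similarity bisects the cluster by
#' orientation. Because a cluster may already be fully consistently
#' oriented (so no bisected structure exists), clustering is performed
#' on the unitig vectors together with a negated ("flipped") copy of
#' each: the augmented set always contains both orientations, a
#' two-group cut of a hierarchical clustering on 1 - cos distance splits
#' them, and only the original vectors are then retained. The group
#' containing the lexicographically smallest unitig id is labeled
#' `FORWARD`; the other group is `FLIPPED` and has Watson/Crick counts
#' swapped downstream (see [apply_orientation()]). A unitig landing in
#' the same group as its own flipped copy has near-orthogonal geometry;
#' it is flagged ambiguous, treated as `FORWARD`, and a warning is
#' emitted.
#'
#' @param ssf all-reads SSF tibble over retained libraries (see
#'   [strand_state_frequency()]).
#' @param clusters a `strand_clusters` object from [cluster_unitigs()],
#'   or its assignment tibble (`unitig`, `cluster`).
#' @param linkage hierarchical clustering linkage: `"average"`
#'   (default), `"single"` or `"complete"`.
#' @return a tibble with columns `unitig`, `cluster`, `orientation`
#'   (`FORWARD`/`FLIPPED`) and `ambiguous` (logical), one row per
#'   clustered unitig.
#' @export
correct_orientation <- function(ssf, clusters, linkage = c("average",
                                                           "single",
                                                           "complete")) {
  linkage <- match.arg(linkage)
  assignment <- if (inherits(clusters, "strand_clusters")) {
    clusters$assignment
  } else {
    clusters
  }
  check_columns(assignment, c("unitig", "cluster"), "cluster assignment")
  assignment <- assignment[!is.na(assignment$cluster), ]
  V <- ssf_matrix(ssf)

  out <- lapply(split(assignment$unitig, assignment$cluster), function(ids) {
    ids <- sort(ids)
    X <- V[ids, , drop = FALSE]
    n <- nrow(X)
    if (n == 1) {
      return(tibble(unitig = ids, orientation = "FORWARD", ambiguous = FALSE))
    }
    Y <- rbind(X, -X)
    Yn <- normalize_rows(Y)
    C <- Yn %*% t(Yn)
    C[abs(C) > 1] <- sign(C[abs(C) > 1])
    zero <- rowSums(Y^2) == 0
    C[zero, ] <- 0
    C[, zero] <- 0
    D <- 1 - C
    hc <- hclust(as.dist(D), method = linkage)
    grp <- cutree(hc, k = 2)
    orig <- grp[seq_len(n)]
    flip <- grp[n + seq_len(n)]
    ambiguous <- orig == flip
    if (any(ambiguous)) {
      rlang::warn(sprintf(
        "%d unitig(s) with ambiguous orientation geometry treated as FORWARD",
        sum(ambiguous)
      ))
    }
    fwd_group <- orig[1]  # ids sorted: group of the smallest id stays FORWARD
    orientation <- ifelse(orig == fwd_group, "FORWARD", "FLIPPED")
    orientation[ambiguous] <- "FORWARD"
    tibble(unitig = ids, orientation = unname(orientation),
           ambiguous = unname(ambiguous))
  })
  dplyr::bind_rows(out, .id = "cluster") |>
    dplyr::select("unitig", "cluster", "orientation", "ambiguous") |>
    dplyr::arrange(.data$unitig)
}
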