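# broom-style tidiers for the package's fitted objects.

#' Tidy a chromosome clustering
#'
#' @param x a `strand_clusters` object.
#' @param ... unused.
#' @return the assignment tibble (`unitig`, `cluster`, `provenance`).
#' @method tidy strand_clusters
#' @export
tidy.strand_clusters <- function(x, ...) {
  x$assignment
}

#' Summarize a chromosome clustering
#'
#' @param x a `strand_clusters` object.
#' @param ... unused.
#' @return a one-row tibble with `n_unitigs`, `n_clusters`,
#'   `n_unclustered`, `largest_cluster`.
#' @method glance strand_clusters
#' @export
glance.strand_clusters <- function(x, ...) {
  a <- x$assignment
  sizes <- table(a$cluster)
  tibble(
    n_unitigs = nrow(a),
    n_clusters = length(sizes),
    n_unclustered = sum(is.na(a$cluster)),
    largest_cluster = if (length(sizes) > 0) max(sizes) else 0L
  )
}

#' Tidy a phase fit
#'
#' @param x a `phase_fit` object.
#' @param ... unused.
#' @return a long tibble with one row per (cluster, library):
#'   `cluster`, `library`, `v_clust`, `v_phase`. Libraries with
#'   `v_phase` components away from 0 are the phase-informative ones.
#' @method tidy phase_fit
#' @export
tidy.phase_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    tibble(
      cluster = m$cluster, library = x$libraries,
      v_clust = unname(m$v_clust), v_phase = unname(m$v_phase)
    )
  }))
}

#' Summarize a phase fit
#'
#' @param x a `phase_fit` object.
#' @param ... unused.
#' @return a tibble with one row per cluster: `cluster`, `n_unitigs`,
#'   `ev1`, `ev2`, `haploid`, `rank1`.
#' @method glance phase_fit
#' @export
glance.phase_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(x$models, function(m) {
    tibble(
      cluster = m$cluster, n_unitigs = nrow(m$coords),
      ev1 = m$ev[1], ev2 = m$ev[2], haploid = m$haploid, rank1 = m$rank1
    )
  }))
}
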