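#' Read a Watson/Crick count table
#'
#' Reads a long-format TSV with header `unitig  library  w  c`, one row
#' per observed (unitig, library) pair, giving the number of first-mate
#' read alignments in Watson (`w`) and Crick (`c`) orientation. Duplicate
#' pairs are summed; absent pairs are implicitly zero. Unitig and library
#' order is the order of first appearance in the file, and is preserved
#' through downstream matrix construction.
#'
#' @param path path to a TSV file.
#' @return a tibble with columns `unitig`, `library`, `w`, `c`, carrying
#'   the first-appearance ordering as factor-level attributes
#'   `unitig_levels` and `library_levels`.
#' @export
read_strand_counts <- function(path) {
  if (!file.exists(path)) up_abort(sprintf("count table not found: %s", path))
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      unitig = readr::col_character(),
      library = readr::col_character(),
      w = readr::col_double(),
      c = readr::col_double()
    ),
    progress = FALSE
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    up_abort(sprintf(
      "malformed count table row at line %d of %s", probs$row[1] + 1, path
    ))
  }
  check_columns(df, c("unitig", "library", "w", "c"), "count table")
  bad <- which(df$w < 0 | df$c < 0 | is.na(df$w) | is.na(df$c))
  if (length(bad) > 0) {
    up_abort(sprintf("negative or missing count at line %d", bad[1] + 1))
  }
  strand_counts(df)
}

#' Construct a strand count table
#'
#' Normalizes a long-format count table: aggregates duplicate
#' (unitig, library) rows by summing and records first-appearance
#' ordering of unitigs and libraries.
#'
#' @param df data frame with columns `unitig`, `library`, `w`, `c`.
#' @return a tibble with ordering attributes (see [read_strand_counts()]).
#' @export
strand_counts <- function(df) {
  check_columns(df, c("unitig", "library", "w", "c"), "count table")
  u_lev <- unique(df$unitig)
  l_lev <- unique(df$library)
  out <- df |>
    dplyr::group_by(.data$unitig, .data$library) |>
    dplyr::summarise(w = sum(.data$w), c = sum(.data$c), .groups = "drop") |>
    dplyr::arrange(
      match(.data$unitig, u_lev), match(.data$library, l_lev)
    )
  attr(out, "unitig_levels") <- u_lev
  attr(out, "library_levels") <- l_lev
  out
}

# Dense W and C matrices (unitig x library) from a long count table.
# Absent pairs are 0. Row/column order is first-appearance order unless
# explicit orderings are given.
count_matrices <- function(counts, unitigs = NULL, libraries = NULL) {
  u_lev <- unitigs %||% attr(counts, "unitig_levels") %||% unique(counts$unitig)
  l_lev <- libraries %||% attr(counts, "library_levels") %||% unique(counts$library)
  counts <- counts[counts$unitig %in% u_lev & counts$library %in% l_lev, ]
  W <- matrix(0, length(u_lev), length(l_lev), dimnames = list(u_lev, l_lev))
  C <- W
  i <- cbind(match(counts$unitig, u_lev), match(counts$library, l_lev))
  W[i] <- counts$w
  C[i] <- counts$c
  list(W = W, C = C)
}

#' Strand state frequency
#'
#' The strand state frequency (SSF) of a unitig in a library is
#' `(w - c) / (w + c)` for Watson count `w` and Crick count `c`. It is 0
#' for balanced alignments, and +1 / -1 when all alignments are Watson /
#' Crick; a matched (WW/CC) inherited strand state therefore yields |SSF|
#' near 1 and an unmatched (WC/CW) state an SSF near 0. Cells with
#' `w + c = 0` have no evidence: their SSF is set to 0 and flagged
#' `defined = FALSE`, so they contribute nothing to similarity vectors.
#'
#' @param counts a count table from [read_strand_counts()] or
#'   [strand_counts()]; rows absent from the table are zero-count cells.
#' @return a tibble with columns `unitig`, `library`, `w`, `c`, `ssf`,
#'   `defined`, covering the full unitig x library grid, with ordering
#'   attributes preserved.
#' @export
strand_state_frequency <- function(counts) {
  check_columns(counts, c("unitig", "library", "w", "c"), "count table")
  u_lev <- attr(counts, "unitig_levels") %||% unique(counts$unitig)
  l_lev <- attr(counts, "library_levels") %||% unique(counts$library)
  full <- tidyr::expand_grid(unitig = u_lev, library = l_lev) |>
    dplyr::left_join(
      counts[, c("unitig", "library", "w", "c")],
      by = c("unitig", "library")
    ) |>
    dplyr::mutate(
      w = dplyr::coalesce(.data$w, 0),
      c = dplyr::coalesce(.data$c, 0),
      total = .data$w + .data$c,
      ssf = dplyr::if_else(.data$total > 0, (.data$w - .data$c) / .data$total, 0),
      defined = .data$total > 0
    ) |>
    dplyr::select(-"total")
  attr(full, "unitig_levels") <- u_lev
  attr(full, "library_levels") <- l_lev
  full
}

# SSF values as a dense unitig x library matrix; undefined cells are 0.
ssf_matrix <- function(ssf, unitigs = NULL, libraries = NULL) {
  u_lev <- unitigs %||% attr(ssf, "unitig_levels") %||% unique(ssf$unitig)
  l_lev <- libraries %||% attr(ssf, "library_levels") %||% unique(ssf$library)
  ssf <- ssf[ssf$unitig %in% u_lev & ssf$library %in% l_lev, ]
  m <- matrix(0, length(u_lev), length(l_lev), dimnames = list(u_lev, l_lev))
  m[cbind(match(ssf$unitig, u_lev), match(ssf$library, l_lev))] <- ssf$ssf
  m
}

#' Discretize strand states
#'
#' Calls a strand state per (unitig, library) cell: `LOW_COVERAGE` when
#' fewer than `min_reads` alignments support the cell, otherwise
#' `MATCHED` when |SSF| >= `matched_abs_ssf` and `UNMATCHED` below it.
#'
#' @param ssf output of [strand_state_frequency()] (carries `w`, `c`).
#' @param matched_abs_ssf |SSF| threshold for a matched call
#'   (default 0.6).
#' @param min_reads minimum `w + c` to call a state (default 10).
#' @return the input tibble with an added `state` column.
#' @export
call_strand_states <- function(ssf, matched_abs_ssf = 0.6, min_reads = 10) {
  check_columns(ssf, c("unitig", "library", "w", "c", "ssf"), "ssf table")
  out <- dplyr::mutate(
    ssf,
    state = dplyr::case_when(
      .data$w + .data$c < min_reads ~ "LOW_COVERAGE",
      abs(.data$ssf) >= matched_abs_ssf ~ "MATCHED",
      TRUE ~ "UNMATCHED"
    )
  )
  attr(out, "unitig_levels") <- attr(ssf, "unitig_levels")
  attr(out, "library_levels") <- attr(ssf, "library_levels")
  out
}

#' Library quality control
#'
#' Each chromosome inherits matched and unmatched strand states in an
#' expected 50/50 ratio across libraries, so a library whose callable
#' cells are overwhelmingly unmatched indicates failed Strand-seq
#' chemistry (no BrdU strand removal) and is discarded. Libraries with
#' too few callable unitigs to judge are also discarded.
#'
#' @param states output of [call_strand_states()].
#' @param max_unmatched_frac drop a library when
#'   `UNMATCHED / (MATCHED + UNMATCHED)` exceeds this (default 0.8).
#' @param min_informative_unitigs drop a library with fewer callable
#'   (non-LOW_COVERAGE) unitigs than this (default 20).
#' @return a list with `libraries` (retained ids, in input order) and
#'   `report` (tibble: `library`, `n_matched`, `n_unmatched`, `n_low`,
#'   `retained`). All libraries failing is a fatal error.
#' @export
library_qc <- function(states, max_unmatched_frac = 0.8,
                       min_informative_unitigs = 20) {
  check_columns(states, c("library", "state"), "state table")
  l_lev <- attr(states, "library_levels") %||% unique(states$library)
  report <- states |>
    dplyr::group_by(.data$library) |>
    dplyr::summarise(
      n_matched = sum(.data$state == "MATCHED"),
      n_unmatched = sum(.data$state == "UNMATCHED"),
      n_low = sum(.data$state == "LOW_COVERAGE"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_callable = .data$n_matched + .data$n_unmatched,
      unmatched_frac = dplyr::if_else(
        .data$n_callable > 0,
        .data$n_unmatched / .data$n_callable,
        1
      ),
      retained = .data$n_callable >= min_informative_unitigs &
        .data$unmatched_frac <= max_unmatched_frac
    ) |>
    dplyr::arrange(match(.data$library, l_lev))
  if (!any(report$retained)) {
    up_abort(paste0(
      "library QC discarded every library; summary:\n",
      paste(utils::capture.output(print(report)), collapse = "\n")
    ))
  }
  list(
    libraries = report$library[report$retained],
    report = dplyr::select(
      report, "library", "n_matched", "n_unmatched", "n_low", "retained"
    )
  )
}

#' Apply orientation corrections to a count table
#'
#' Flipping a unitig swaps its Watson and Crick counts in every library,
#' which negates its SSF row. Used to propagate the orientation map to
#' both the all-reads and the haplotype-informative count tables.
#'
#' @param counts a count table.
#' @param orientation tibble with columns `unitig`, `orientation`
#'   (values `FORWARD` / `FLIPPED`), e.g. from [correct_orientation()].
#' @return the count table with `w`/`c` swapped on flipped unitigs.
#' @export
apply_orientation <- function(counts, orientation) {
  check_columns(orientation, c("unitig", "orientation"), "orientation map")
  flipped <- orientation$unitig[orientation$orientation == "FLIPPED"]
  i <- counts$unitig %in% flipped
  tmp <- counts$w[i]
  counts$w[i] <- counts$c[i]
  counts$c[i] <- tmp
  counts
}
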