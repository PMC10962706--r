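#' Evaluate haplotype calls against a truth table
#'
#' Computes the base-pair-weighted disagreement between per-unitig
#' haplotype calls and a reference assignment, restricted to unitigs at
#' least `min_len` bp long. Phased haplotypes are parentage-unknown, so
#' per cluster the HAP1/HAP2 labels are mapped onto the truth labels in
#' whichever way minimizes disagreement (a global mapping across all
#' clusters is available instead via `per_cluster = FALSE`). `HOM` must
#' match `HOM` under either mapping and `NONE` never matches.
#' Disagreement is reported overall and restricted to acrocentric
#' chromosomes when the truth table carries an `acrocentric` column.
#'
#' @param calls tibble with columns `unitig`, `cluster`, `call`
#'   (e.g. the `calls` element of [phase_assembly()]).
#' @param truth tibble with columns `unitig`, `haplotype` (H1/H2/HOM),
#'   `length`, and optionally `chromosome` and `acrocentric` (e.g.
#'   `truth_unitigs` from [simulate_strandseq()]).
#' @param min_len minimum unitig length included (default 50000).
#' @param per_cluster map haplotype labels per cluster (default TRUE,
#'   mirroring parentage-unknown semantics) or once globally.
#' @return a tibble with columns `scope` (`overall`, `acrocentric`),
#'   `total_bp`, `mismatch_bp`, `disagreement_pct`, `agreement_pct`.
#' @export
evaluate_against_truth <- function(calls, truth, min_len = 50000,
                                   per_cluster = TRUE) {
  check_columns(calls, c("unitig", "cluster", "call"), "calls")
  check_columns(truth, c("unitig", "haplotype", "length"), "truth")
  truth <- truth[!is.na(truth$haplotype) & truth$length >= min_len, ]
  unknown <- setdiff(truth$unitig, calls$unitig)
  if (length(unknown) > 0) {
    up_abort(sprintf(
      "truth unitigs missing from calls, e.g.: %s",
      paste(head(unknown, 5), collapse = ", ")
    ))
  }
  df <- dplyr::inner_join(
    calls, truth,
    by = "unitig", suffix = c("", ".truth")
  )

  # mismatch bp under a fixed HAP1 -> H1 / HAP2 -> H2 mapping (or swapped)
  mismatch_bp <- function(d, swap) {
    mapped <- dplyr::case_when(
      d$call == "HAP1" ~ if (swap) "H2" else "H1",
      d$call == "HAP2" ~ if (swap) "H1" else "H2",
      d$call == "HOM" ~ "HOM",
      TRUE ~ "NONE"
    )
    sum(d$length[mapped != d$haplotype])
  }
  best <- function(d) min(mismatch_bp(d, FALSE), mismatch_bp(d, TRUE))

  total_mismatch <- if (per_cluster) {
    key <- dplyr::coalesce(df$cluster, "unclustered")
    sum(vapply(split(seq_len(nrow(df)), key),
               function(i) best(df[i, ]), numeric(1)))
  } else {
    best(df)
  }

  scope_row <- function(scope, d, mm) {
    total <- sum(d$length)
    pct <- if (total > 0) 100 * mm / total else 0
    tibble(
      scope = scope, total_bp = total, mismatch_bp = mm,
      disagreement_pct = pct, agreement_pct = 100 - pct
    )
  }
  out <- scope_row("overall", df, total_mismatch)
  if ("acrocentric" %in% names(df)) {
    acro <- df[df$acrocentric %in% TRUE, ]
    if (nrow(acro) > 0) {
      mm_acro <- if (per_cluster) {
        key <- dplyr::coalesce(acro$cluster, "unclustered")
        sum(vapply(split(seq_len(nrow(acro)), key),
                   function(i) best(acro[i, ]), numeric(1)))
      } else {
        best(acro)
      }
      out <- dplyr::bind_rows(out, scope_row("acrocentric", acro, mm_acro))
    }
  }
  out
}
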