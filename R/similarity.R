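#' Absolute cosine similarity
#'
#' `|a . b| / (||a|| ||b||)`, i.e. |cos(theta)| of the angle between two
#' vectors. Absolute value makes the measure orientation-blind: a
#' misoriented unitig's SSF vector is the negation of its correctly
#' oriented counterpart, and still scores 1 against it. Zero vectors
#' carry no strand signal and have similarity 0 to everything.
#'
#' @param a,b numeric vectors of equal length.
#' @return a number in \[0, 1\].
#' @export
abs_cos <- function(a, b) {
  if (length(a) != length(b)) {
    up_abort("abs_cos: vectors have different dimension")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  min(1, abs(sum(a * b)) / (na * nb))
}

#' Mean pairwise absolute cosine similarity between two vector sets
#'
#' The similarity between a unitig and a cluster, or between two
#' clusters, is the mean over all cross pairs of [abs_cos()]. Singleton
#' sets reduce to `abs_cos` itself.
#'
#' @param A,B numeric matrices with one vector per row (a plain vector is
#'   treated as a single row).
#' @return mean pairwise similarity in \[0, 1\].
#' @export
set_similarity <- function(A, B) {
  if (is.vector(A)) A <- matrix(A, nrow = 1)
  if (is.vector(B)) B <- matrix(B, nrow = 1)
  if (nrow(A) == 0 || nrow(B) == 0) up_abort("set_similarity: empty set")
  if (ncol(A) != ncol(B)) {
    up_abort("set_similarity: vectors have different dimension")
  }
  An <- normalize_rows(A)
  Bn <- normalize_rows(B)
  mean(pmin(1, abs(An %*% t(Bn))))
}

# Full pairwise |cos| matrix over the rows of V (zero rows give 0).
abs_cos_matrix <- function(V) {
  Vn <- normalize_rows(V)
  S <- abs(Vn %*% t(Vn))
  S[S > 1] <- 1
  S
}
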