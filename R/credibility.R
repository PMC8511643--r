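#' Recode an association matrix into a credibility matrix
#'
#' Verified associations are more trustworthy than undetermined pairs, so the
#' binary matrix is recoded entry-wise: `1 -> delta` (`delta > 1`),
#' `0 -> base_code`.
#'
#' @param A Binary association matrix.
#' @param delta Credibility of a verified association, `> 1`.
#' @param base_code Credibility of an undetermined pair (default `-1`).
#' @return Numeric matrix with the same dimnames as `A`.
#' @export
build_credibility <- function(A, delta = 2, base_code = -1) {
  .check_association(A)
  if (!(is.numeric(delta) && length(delta) == 1L && delta > 1)) {
    stop("`delta` must be > 1")
  }
  C <- ifelse(A == 1, delta, base_code)
  dimnames(C) <- dimnames(A)
  C
}

#' Raw credibility similarity (inner products of credibility profiles)
#'
#' `CM1[i, j]` is the inner product of rows `i` and `j` of the credibility
#' matrix for `i != j`; the diagonal is set to 0 (self-similarity of the raw
#' product is large and would distort the subsequent row-wise rescaling, and
#' the voting model fixes the similarity diagonal to 1 separately).
#'
#' @param C Credibility matrix; rows are the profiles being compared (pass
#'   `t(C)` for the disease side).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
raw_credibility_similarity <- function(C) {
  stopifnot(is.matrix(C))
  if (nrow(C) < 2L) stop("need at least 2 profiles to compare")
  CM1 <- tcrossprod(C)
  diag(CM1) <- 0
  CM1
}

#' Rescale a raw credibility similarity into \[0, 1\]
#'
#' Each entry is rescaled by the extrema of both of its rows (which include
#' the zeroed diagonal):
#' `CM[i, j] = (CM1[i, j] - min_i) * (CM1[i, j] - min_j) /
#'  ((max_i - min_i) * (max_j - min_j))`.
#' A constant row carries no information; its factor is defined as 0.  The
#' diagonal stays 0.  The result is invariant to multiplying `CM1` by any
#' positive constant.
#'
#' @param CM1 Symmetric matrix with zero diagonal from
#'   [raw_credibility_similarity()].
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
scale_credibility <- function(CM1) {
  stopifnot(is.matrix(CM1), nrow(CM1) == ncol(CM1))
  if (any(diag(CM1) != 0)) stop("diagonal of the raw similarity must be zeroed first")
  rmin <- apply(CM1, 1L, min)
  rmax <- apply(CM1, 1L, max)
  span <- rmax - rmin
  G <- (CM1 - rmin) / ifelse(span == 0, Inf, span)  # row factor in [0, 1]
  CM <- G * t(G)
  diag(CM) <- 0
  dimnames(CM) <- dimnames(CM1)
  CM
}

#' Credibility similarity of miRNAs or diseases
#'
#' Convenience wrapper: recode `A`, form the profile inner products along the
#' requested axis, and rescale to `[0, 1]`.
#'
#' @inheritParams build_credibility
#' @param side `"mirna"` (compare rows of `A`) or `"disease"` (columns).
#' @return Symmetric similarity matrix in `[0, 1]` with zero diagonal.
#' @export
credibility_similarity <- function(A, delta = 2, base_code = -1,
                                   side = c("mirna", "disease")) {
  side <- match.arg(side)
  C <- build_credibility(A, delta, base_code)
  if (side == "disease") C <- t(C)
  scale_credibility(raw_credibility_similarity(C))
}

#' Integrate two similarity matrices
#'
#' Entry-wise mean of an external similarity (functional or semantic) and the
#' credibility similarity, with the diagonal forced to 1 afterwards: voters
#' must keep their absolute status (self-similarity 1) even though the
#' credibility similarity has a zero diagonal by construction.
#'
#' @param sim_a,sim_b Square similarity matrices with identical dimnames.
#' @return Their entry-wise mean with unit diagonal.
#' @export
integrate_similarity <- function(sim_a, sim_b) {
  stopifnot(is.matrix(sim_a), is.matrix(sim_b))
  if (!identical(dim(sim_a), dim(sim_b)) ||
      !identical(dimnames(sim_a), dimnames(sim_b))) {
    stop("similarity matrices must share axis labels and order")
  }
  M <- (sim_a + sim_b) / 2
  diag(M) <- 1
  M
}
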