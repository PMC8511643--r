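#' Per-group voter counts
#'
#' `N_m[i]` is the number of verified associations in miRNA `i`'s row,
#' `N_d[s]` the number in disease `s`'s column; both sums equal the total
#' number of voters.
#'
#' @param A Binary association matrix.
#' @return List with numeric vectors `N_m` (per miRNA) and `N_d`
#'   (per disease).
#' @export
voter_counts <- function(A) {
  .check_association(A)
  list(N_m = rowSums(A), N_d = colSums(A))
}

#' Basic voting weight of a candidate pair
#'
#' The fairness normalisation `1 / (N_m[i] + N_d[s] - A[i, s])`: every vote
#' cast to candidate `(i, s)` carries this weight, so the candidate's total
#' incoming vote mass is exactly 1 (slightly above 1 for a voter, whose
#' self-vote is counted in both its row and its column group).  A candidate
#' connected to no voter has denominator 0 and receives weight 0 by
#' convention (it gets no votes anyway).
#'
#' @param counts Voter counts from [voter_counts()].
#' @param A Binary association matrix.
#' @param i miRNA index of the candidate.
#' @param s Disease index of the candidate.
#' @return A single number.
#' @export
basic_weight <- function(counts, A, i, s) {
  den <- counts$N_m[[i]] + counts$N_d[[s]] - A[i, s]
  if (den <= 0) 0 else 1 / den
}

#' Group weight
#'
#' `group_size ^ e`, amplifying the voice of groups with many voters;
#' `0 ^ e` is defined as 0 for every `e` (an empty group has no voice, even
#' at `e = 0` where group influence is otherwise disabled).
#'
#' @param group_size Non-negative integer(s): number of voters in the group.
#' @param e Exponent `>= 0`.
#' @return Numeric of the same length as `group_size`.
#' @export
group_weight <- function(group_size, e = 1 / 3) {
  stopifnot(all(group_size >= 0), e >= 0)
  ifelse(group_size == 0, 0, group_size^e)
}

#' Weighted-voting association scores
#'
#' Every verified association `(mi, ds)` votes for all pairs in its row and
#' column.  The vote it casts to candidate `(mi, dj)` is weighted by the
#' row-group influence `N_m[i]^e`, the disease similarity `D[s, j]` between
#' voter and candidate, and the candidate's basic weight
#' `1 / (N_m[i] + N_d[j] - A[i, j])`; column-group votes are symmetric with
#' `M` and `N_d[j]^e`.  Accumulated in closed form:
#'
#' `F[i, j] = (N_m[i]^e * (A %*% D)[i, j] + N_d[j]^e * (t(M) %*% A)[i, j]) /
#'            (N_m[i] + N_d[j] - A[i, j])`
#'
#' with terms of zero denominator (a pair connected to no voter) set to 0.
#' A voter's self-vote is counted once in its row sum and once in its column
#' sum.  Similarity rows index the voter side: `M[t, i]` is read as "voter
#' miRNA t's (possibly filtered) similarity row evaluated at candidate i".
#'
#' @param A Binary association matrix.
#' @param M Integrated (and typically filtered) miRNA similarity, unit
#'   diagonal.
#' @param D Integrated (and typically filtered) disease similarity, unit
#'   diagonal.
#' @param e Group-weight exponent.
#' @return Numeric score matrix sharing axes with `A`.
#' @export
score_matrix <- function(A, M, D, e = 1 / 3) {
  .check_association(A)
  n <- nrow(A); m <- ncol(A)
  if (!identical(dim(M), c(n, n))) stop("miRNA similarity must be ", n, "x", n)
  if (!identical(dim(D), c(m, m))) stop("disease similarity must be ", m, "x", m)
  if (!is.null(rownames(M)) && !identical(rownames(M), rownames(A))) {
    stop("miRNA similarity labels do not match the association matrix")
  }
  if (!is.null(rownames(D)) && !identical(rownames(D), colnames(A))) {
    stop("disease similarity labels do not match the association matrix")
  }
  counts <- voter_counts(A)
  gw_m <- group_weight(counts$N_m, e)
  gw_d <- group_weight(counts$N_d, e)
  num <- gw_m * (A %*% D) +                      # row-group votes
    crossprod(M, A) * rep(gw_d, each = n)        # column-group votes
  den <- outer(counts$N_m, counts$N_d, "+") - A
  F <- ifelse(den > 0, num / ifelse(den > 0, den, 1), 0)
  dimnames(F) <- dimnames(A)
  F
}
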