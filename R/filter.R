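#' Adaptively filter one similarity row
#'
#' Keeps the reliable head of the row's descending value distribution and
#' zeroes the rest.  Procedure (positions are 1-based in the descending sort
#' of the off-diagonal values, ties by smaller matrix position first):
#' 1. hypothetical position `p_h = round(r * k)` (half-up), clamped to
#'    `[1, k - 1]`, where `k` is the row length;
#' 2. the value `v` at `p_h` selects its level bin `[lo, lo + 0.1)` with
#'    `lo = floor(10 v) / 10`;
#' 3. the leading point `p_l` is the position of the value closest to
#'    `lo + 0.1`, the following point `p_f` the position of the value closest
#'    to `lo` (ties: smallest position);
#' 4. the cut is `p = p_f` if `p_f < 2 p_h`, else `p = p_l` if
#'    `p_l > p_h / 2`, else `p = 2 p_h`, clamped to `[1, k - 1]`;
#' 5. the top `p` values keep their matrix positions, all other off-diagonal
#'    entries become 0.  The own (diagonal) entry is never touched.
#'
#' @param row Numeric vector of similarity values (one matrix row).
#' @param own_index Position of the diagonal element, excluded from the sort
#'   and preserved at its value.
#' @param r Hypothetical-position ratio in `(0, 1]`.
#' @return The filtered row, with the chosen cut position in attribute `"p"`.
#' @export
filter_row <- function(row, own_index, r = 0.1) {
  k <- length(row)
  if (k == 0L) stop("empty similarity row")
  if (k < 2L) stop("similarity row needs at least 2 entries")
  stopifnot(own_index >= 1L, own_index <= k, r > 0, r <= 1)
  idx <- setdiff(seq_len(k), own_index)
  vals <- row[idx]
  ord <- order(-vals, seq_along(vals))        # descending, stable in position
  sorted <- vals[ord]
  ph <- min(max(floor(r * k + 0.5), 1), k - 1)
  v <- sorted[ph]
  lo <- floor(v * 10 + 1e-9) / 10             # half-open level bin [lo, lo+0.1)
  hi <- lo + 0.1
  pl <- which.min(abs(sorted - hi))           # first minimum = smallest position
  pf <- which.min(abs(sorted - lo))
  p <- if (pf < 2 * ph) pf else if (pl > ph / 2) pl else 2 * ph
  p <- min(max(p, 1), k - 1)
  out <- numeric(k)
  keep <- idx[ord[seq_len(p)]]
  out[keep] <- row[keep]
  out[own_index] <- row[own_index]
  names(out) <- names(row)
  attr(out, "p") <- as.integer(p)
  out
}

#' Adaptively filter every row of a similarity matrix
#'
#' Applies [filter_row()] to each row independently; the diagonal is
#' preserved.  Because each row chooses its own cut, the result is generally
#' asymmetric; `symmetrize = "max"` restores symmetry by the element-wise
#' maximum with the transpose (keeping an entry if either endpoint retained
#' it).
#'
#' @param S Square similarity matrix.
#' @inheritParams filter_row
#' @param symmetrize `"none"` (default) or `"max"`.
#' @return Filtered matrix with integer attribute `"p"` (per-row cut
#'   positions).
#' @export
filter_matrix <- function(S, r = 0.1, symmetrize = c("none", "max")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  k <- nrow(S)
  out <- S
  p <- integer(k)
  for (i in seq_len(k)) {
    fr <- filter_row(S[i, ], i, r)
    p[i] <- attr(fr, "p")
    out[i, ] <- fr
  }
  if (symmetrize == "max") out <- pmax(out, t(out))
  attr(out, "p") <- p
  out
}
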