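#' Model parameters
#'
#' Bundles and validates every tunable of the prediction pipeline.
#'
#' @param delta Credibility of a verified association, `> 1`.  The association
#'   matrix is recoded to `delta` where an association is known and to
#'   `base_code` elsewhere before the credibility similarity is formed.
#' @param base_code Credibility code of an undetermined pair.  Default `-1`;
#'   `+1` is accepted for the alternative convention.
#' @param omega Semantic contribution factor in `(0, 1]`: per-level decay of
#'   an ancestor term's contribution to a disease's semantic value.
#' @param r Hypothetical-position ratio of the similarity filter, in `(0, 1]`:
#'   the assumed cut position is `round(r * k)` in a row of length `k`.
#' @param e Group-weight exponent, `>= 0`.  `e = 0` disables group influence.
#' @param filter Logical; apply the adaptive row filter to the integrated
#'   similarities before voting.
#' @param symmetrize Filter post-processing: `"none"` keeps the (generally
#'   asymmetric) row-filtered matrix, `"max"` restores symmetry by the
#'   element-wise maximum with the transpose.
#'
#' @return A list of class `"mdv_params"`.
#' @examples
#' mdv_params(delta = 2, r = 0.1, e = 1/3)
#' @export
mdv_params <- function(delta = 2, base_code = -1, omega = 0.5, r = 0.1,
                       e = 1 / 3, filter = TRUE,
                       symmetrize = c("none", "max")) {
  symmetrize <- match.arg(symmetrize)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  if (delta <= 1) {
    stop("`delta` must be > 1: known associations must outweigh undetermined ones")
  }
  stopifnot(is.numeric(base_code), length(base_code) == 1L, is.finite(base_code))
  if (!(is.numeric(omega) && length(omega) == 1L && omega > 0 && omega <= 1)) {
    stop("`omega` must lie in (0, 1]")
  }
  if (!(is.numeric(r) && length(r) == 1L && r > 0 && r <= 1)) {
    stop("`r` must lie in (0, 1]")
  }
  if (!(is.numeric(e) && length(e) == 1L && e >= 0)) {
    stop("`e` must be >= 0")
  }
  structure(
    list(delta = delta, base_code = base_code, omega = omega, r = r, e = e,
         filter = isTRUE(filter), symmetrize = symmetrize),
    class = "mdv_params"
  )
}

#' @export
print.mdv_params <- function(x, ...) {
  cat("mdvote parameters:\n")
  cat(sprintf("  delta (credibility)      %.4g\n", x$delta))
  cat(sprintf("  base_code                %.4g\n", x$base_code))
  cat(sprintf("  omega (semantic decay)   %.4g\n", x$omega))
  cat(sprintf("  r (filter ratio)         %.4g\n", x$r))
  cat(sprintf("  e (group exponent)       %.4g\n", x$e))
  cat(sprintf("  filter                   %s (symmetrize: %s)\n",
              x$filter, x$symmetrize))
  invisible(x)
}
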