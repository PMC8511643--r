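#' Rank-based AUC
#'
#' `P(score_pos > score_neg) + 0.5 * P(tie)`, computed from midranks; equal to
#' the trapezoidal area under the threshold-swept ROC curve.
#'
#' @param scores_pos Scores of the positive pairs.
#' @param scores_neg Scores of the negative pairs.
#' @return A number in `[0, 1]`.
#' @export
auc_rank <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve points
#'
#' Threshold-swept (FPR, TPR) pairs, from (0, 0) to (1, 1), with
#' `TPR = TP / (TP + FN)` and `FPR = FP / (FP + TN)`.
#'
#' @inheritParams auc_rank
#' @return A `data.frame` with columns `FPR` and `TPR`, monotone
#'   non-decreasing in both.
#' @export
roc_points <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0L || nn == 0L) stop("both score sets must be non-empty")
  thr <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores_pos >= t) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores_neg >= t) / nn, numeric(1))
  data.frame(FPR = c(0, fpr), TPR = c(0, tpr))
}

# Fit on training associations, score, and return AUC of held-out positives
# against all full-matrix negatives. test_pos: linear indices into A.
.cv_trial <- function(A, FM, SD, params, test_pos, neg_idx) {
  A_tr <- A
  A_tr[test_pos] <- 0L
  F <- predict_associations(A_tr, FM, SD, params)
  auc_rank(F[test_pos], F[neg_idx])
}

#' Five-fold cross-validation
#'
#' The verified associations are split at random into five folds.  For each
#' fold, everything downstream of the association matrix (credibility
#' similarity, integration, filtering, voter counts, scores) is rebuilt from
#' the training associations only; the held-out positives are then ranked
#' against all negative pairs of the full matrix.  The external similarities
#' `FM` and `SD` derive from independent data and are not recomputed.
#'
#' @param A Binary association matrix with at least 5 positives.
#' @param FM miRNA functional similarity.
#' @param SD Disease semantic similarity.
#' @param params Model parameters from [mdv_params()].
#' @param seed Integer seed fixing the fold assignments.
#' @param repeats Number of independent five-fold splits to average over.
#' @param folds Number of folds (5 by convention).
#' @return List of class `"mdv_cv"`: `fold_aucs` (repeats x folds matrix),
#'   `mean_auc`, and `roc` (pooled ROC points of the last repeat).
#' @export
five_fold_cv <- function(A, FM, SD, params = mdv_params(), seed = 1L,
                         repeats = 5L, folds = 5L) {
  .check_association(A)
  pos <- which(A == 1)
  if (length(pos) < folds) stop("need at least ", folds, " positive associations")
  neg <- which(A == 0)
  set.seed(seed)
  fold_aucs <- matrix(NA_real_, repeats, folds)
  roc <- NULL
  for (rep_i in seq_len(repeats)) {
    assign <- sample(rep_len(seq_len(folds), length(pos)))
    pooled_pos <- numeric(0); pooled_neg <- numeric(0)
    for (f in seq_len(folds)) {
      test_pos <- pos[assign == f]
      A_tr <- A
      A_tr[test_pos] <- 0L
      F <- predict_associations(A_tr, FM, SD, params)
      fold_aucs[rep_i, f] <- auc_rank(F[test_pos], F[neg])
      if (rep_i == repeats) {
        pooled_pos <- c(pooled_pos, F[test_pos])
        pooled_neg <- c(pooled_neg, F[neg])
      }
    }
    if (rep_i == repeats) roc <- roc_points(pooled_pos, pooled_neg)
  }
  structure(list(fold_aucs = fold_aucs,
                 mean_auc = mean(fold_aucs),
                 roc = roc),
            class = "mdv_cv")
}

#' @export
print.mdv_cv <- function(x, ...) {
  cat(sprintf("five-fold CV: mean AUC %.4f over %d repeat(s) x %d folds\n",
              x$mean_auc, nrow(x$fold_aucs), ncol(x$fold_aucs)))
  invisible(x)
}

#' Global leave-one-out cross-validation
#'
#' Each verified association is masked in turn, the model is rebuilt on the
#' remaining positives, and the left-out pair's score is ranked against all
#' unknown pairs of the whole matrix (the global candidate set).  The
#' returned AUC averages the per-trial rank placements.
#'
#' @inheritParams five_fold_cv
#' @return The LOOCV AUC (single number) with attribute `"per_trial"`.
#' @export
global_loocv <- function(A, FM, SD, params = mdv_params()) {
  .check_association(A)
  pos <- which(A == 1)
  if (length(pos) < 2L) stop("need at least 2 positive associations")
  neg <- which(A == 0)
  per <- vapply(pos, function(p) .cv_trial(A, FM, SD, params, p, neg),
                numeric(1))
  structure(mean(per), per_trial = per)
}

#' Hyperparameter sweep over credibility and filter ratio
#'
#' Mean five-fold CV AUC for every (`delta`, `r`) grid cell at fixed `e`,
#' using the same seed (hence the same fold splits) in every cell.
#'
#' @inheritParams five_fold_cv
#' @param delta_grid,r_grid Numeric vectors of values to sweep.
#' @param e Group-weight exponent held fixed.
#' @return A `data.frame` with columns `delta`, `r`, `mean_auc`.
#' @export
hyperparameter_sweep <- function(A, FM, SD, delta_grid, r_grid, e = 1 / 3,
                                 params = mdv_params(), seed = 1L,
                                 repeats = 1L) {
  grid <- expand.grid(delta = delta_grid, r = r_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    p <- mdv_params(delta = grid$delta[i], base_code = params$base_code,
                    omega = params$omega, r = grid$r[i], e = e,
                    filter = params$filter, symmetrize = params$symmetrize)
    five_fold_cv(A, FM, SD, p, seed = seed, repeats = repeats)$mean_auc
  }, numeric(1))
  grid
}
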