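test_that("rank-based AUC matches direct reasoning and the pairwise oracle", {
  expect_equal(auc_rank(c(3, 4), c(1, 2)), 1)
  expect_equal(auc_rank(c(1, 2), c(3, 4)), 0)
  expect_equal(auc_rank(c(1, 3), c(2, 4)), 0.25)
  expect_equal(auc_rank(c(1, 1), c(1, 1)), 0.5)   # all ties: midrank credit
  expect_error(auc_rank(numeric(0), 1), "non-empty")

  set.seed(14)
  for (rep_i in 1:30) {
    pos <- sample(0:10, sample(1:50, 1), replace = TRUE) / 2  # heavy ties
    neg <- sample(0:10, sample(1:50, 1), replace = TRUE) / 2
    expect_equal(auc_rank(pos, neg), pairwise_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("rank-based AUC agrees with pROC on continuous scores", {
  set.seed(15)
  pos <- rnorm(40, 1); neg <- rnorm(60)
  ours <- auc_rank(pos, neg)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 60)), predictor = c(pos, neg),
    quiet = TRUE, direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("ROC points run monotonically from (0,0) to (1,1) and integrate to the AUC", {
  set.seed(16)
  pos <- rnorm(25, 0.8); neg <- rnorm(40)
  rp <- roc_points(pos, neg)
  expect_equal(rp$FPR[1], 0); expect_equal(rp$TPR[1], 0)
  expect_equal(rp$FPR[nrow(rp)], 1); expect_equal(rp$TPR[nrow(rp)], 1)
  expect_true(all(diff(rp$FPR) >= 0))
  expect_true(all(diff(rp$TPR) >= 0))
  trapz <- sum(diff(rp$FPR) * (utils::head(rp$TPR, -1) + utils::tail(rp$TPR, -1)) / 2)
  expect_equal(trapz, auc_rank(pos, neg), tolerance = 1e-12)
})

test_that("five-fold CV is seeded, deterministic, and rebuilt from masked associations only", {
  net <- make_network(fixture_spec(n_mirna = 24, n_disease = 16, seed = 5))
  SD <- semantic_similarity_matrix(net$dags)
  p <- mdv_params()
  cv1 <- five_fold_cv(net$A, net$FM, SD, p, seed = 7, repeats = 2)
  cv2 <- five_fold_cv(net$A, net$FM, SD, p, seed = 7, repeats = 2)
  expect_identical(cv1$fold_aucs, cv2$fold_aucs)
  expect_true(all(cv1$fold_aucs >= 0 & cv1$fold_aucs <= 1))

  # replicate the documented fold assignment and recompute one repeat from
  # scratch through the public API: the fold model must see masked pairs as 0
  pos <- which(net$A == 1); neg <- which(net$A == 0)
  set.seed(7)
  assign <- sample(rep_len(1:5, length(pos)))
  for (f in 1:5) {
    test_pos <- pos[assign == f]
    A_tr <- net$A; A_tr[test_pos] <- 0L
    fit <- predict_associations(A_tr, net$FM, SD, p, detail = TRUE)
    expect_true(all(fit$C[test_pos] == p$base_code))      # no leak into credibility
    expect_equal(auc_rank(fit$scores[test_pos], fit$scores[neg]),
                 cv1$fold_aucs[1, f], tolerance = 1e-12)
  }

  A4 <- net$A * 0L
  A4[cbind(1:4, 1:4)] <- 1L
  expect_error(five_fold_cv(A4, net$FM, SD, p), "at least 5")
})

test_that("uninformative similarities with group influence off score near chance", {
  net <- make_network(fixture_spec(n_mirna = 24, n_disease = 16, seed = 6))
  ones_M <- matrix(1, 24, 24, dimnames = list(rownames(net$A), rownames(net$A)))
  ones_D <- matrix(1, 16, 16, dimnames = list(colnames(net$A), colnames(net$A)))
  cv <- five_fold_cv(net$A, ones_M, ones_D,
                     mdv_params(e = 0, filter = FALSE), seed = 2, repeats = 2)
  expect_gt(cv$mean_auc, 0.35)
  expect_lt(cv$mean_auc, 0.65)
})

test_that("global LOOCV works on the smallest legal instance and beats 5CV on planted signal", {
  ex <- make_worked_example()$scoring
  a1 <- global_loocv(ex$A, ex$M, ex$D, mdv_params(filter = FALSE))
  a2 <- global_loocv(ex$A, ex$M, ex$D, mdv_params(filter = FALSE))
  expect_identical(as.numeric(a1), as.numeric(a2))
  expect_true(as.numeric(a1) >= 0 && as.numeric(a1) <= 1)
  expect_length(attr(a1, "per_trial"), 2L)

  net <- make_network(fixture_spec(n_mirna = 30, n_disease = 20,
                                   density = 0.06, seed = 8))
  SD <- semantic_similarity_matrix(net$dags)
  cv <- five_fold_cv(net$A, net$FM, SD, mdv_params(), seed = 3, repeats = 2)
  lo <- global_loocv(net$A, net$FM, SD, mdv_params())
  # each LOOCV trial trains on strictly more positives than a CV fold
  expect_gte(as.numeric(lo), cv$mean_auc - 0.05)
})

test_that("the hyperparameter sweep covers the grid deterministically", {
  net <- make_network(fixture_spec(n_mirna = 20, n_disease = 14,
                                   density = 0.08, seed = 9))
  SD <- semantic_similarity_matrix(net$dags)
  tab <- hyperparameter_sweep(net$A, net$FM, SD,
                              delta_grid = c(1.5, 3), r_grid = c(0.1, 0.3),
                              seed = 4)
  expect_identical(nrow(tab), 4L)
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))

  dup <- hyperparameter_sweep(net$A, net$FM, SD,
                              delta_grid = c(2, 2), r_grid = 0.2, seed = 4)
  expect_equal(dup$mean_auc[1], dup$mean_auc[2])

  low <- hyperparameter_sweep(net$A, net$FM, SD,
                              delta_grid = 1.0001, r_grid = 0.1, seed = 4)
  expect_true(is.finite(low$mean_auc))
})
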