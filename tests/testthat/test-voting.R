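test_that("voter counts are the row and column sums of the association matrix", {
  A <- matrix(c(1L, 1L, 0L,
                1L, 0L, 0L), 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("d1", "d2", "d3")))
  cnt <- voter_counts(A)
  expect_equal(unname(cnt$N_m), c(2, 1))
  expect_equal(unname(cnt$N_d), c(2, 1, 0))
  expect_equal(sum(cnt$N_m), sum(cnt$N_d))
  expect_true(all(voter_counts(A * 0L)$N_m == 0))
})

test_that("basic weight normalises by the voters connected to the candidate", {
  A <- matrix(c(1L, 1L, 0L,
                1L, 0L, 0L), 2, byrow = TRUE,
              dimnames = list(c("m1", "m2"), c("d1", "d2", "d3")))
  cnt <- voter_counts(A)
  expect_equal(basic_weight(cnt, A, 1, 3), 1 / 2)   # N_m1=2, N_d3=0, A=0
  expect_equal(basic_weight(cnt, A, 1, 1), 1 / 3)   # voter: 2 + 2 - 1
  # single voter in the row, empty column: weight 1
  B <- matrix(c(1L, 0L), 1, 2, dimnames = list("m1", c("d1", "d2")))
  expect_equal(basic_weight(voter_counts(B), B, 1, 2), 1)
  # isolated candidate: denominator 0 contributes nothing
  Z <- matrix(c(1L, 0L, 0L, 0L), 2, dimnames = list(c("m1", "m2"), c("d1", "d2")))
  expect_equal(basic_weight(voter_counts(Z), Z, 2, 2), 0)
})

test_that("group weight is size^e with empty groups silenced", {
  expect_equal(group_weight(8, 1 / 3), 2)
  expect_equal(group_weight(1, 0.77), 1)
  expect_equal(group_weight(5, 0), 1)
  expect_equal(group_weight(0, 0), 0)
  expect_equal(group_weight(0, 1 / 3), 0)
  expect_equal(group_weight(c(0, 1, 27), 1 / 3), c(0, 1, 3))
})

test_that("the worked 2x2 instance scores as the vote-casting oracle dictates", {
  ex <- make_worked_example()$scoring
  F <- score_matrix(ex$A, ex$M, ex$D, ex$e)
  # frozen from the literal vote-accumulation oracle: each identity voter
  # casts a similarity-weighted vote into the other's row/column
  expect_equal(F["m1", "d1"], 2)
  expect_equal(F["m2", "d2"], 2)
  expect_equal(F["m1", "d2"], 0.35)
  expect_equal(F["m2", "d1"], 0.35)
  expect_equal(F, loop_score(ex$A, ex$M, ex$D, ex$e))
  # no voters, no votes
  expect_true(all(score_matrix(ex$A * 0L, ex$M, ex$D, ex$e) == 0))
})

test_that("vectorised scoring equals the literal vote-casting loop", {
  set.seed(606)
  for (rep_i in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:8, 1)
    A <- rand_A(n, m, runif(1, 0.1, 0.7))
    M <- rand_sim(rownames(A)); D <- rand_sim(colnames(A))
    e <- sample(c(0, 1 / 3, 1, 2.5), 1)
    expect_equal(score_matrix(A, M, D, e), loop_score(A, M, D, e),
                 tolerance = 1e-10)
  }
})

test_that("every candidate's incoming vote mass is conserved", {
  # with group influence off and all similarities 1, a non-voter connected to
  # at least one voter receives exactly 1; a voter receives N/(N-1) > 1
  set.seed(99)
  for (rep_i in 1:30) {
    n <- sample(2:12, 1); m <- sample(2:10, 1)
    A <- rand_A(n, m, runif(1, 0.05, 0.6))
    ones_M <- matrix(1, n, n, dimnames = list(rownames(A), rownames(A)))
    ones_D <- matrix(1, m, m, dimnames = list(colnames(A), colnames(A)))
    F <- score_matrix(A, ones_M, ones_D, e = 0)
    N <- outer(rowSums(A), colSums(A), "+")
    nonvoter <- A == 0 & N >= 1
    if (any(nonvoter)) expect_lt(max(abs(F[nonvoter] - 1)), 1e-12)
    voter <- A == 1
    if (any(voter)) {
      expect_lt(max(abs(F[voter] - (N / (N - 1))[voter])), 1e-12)
      expect_true(all(F[voter] > 1))
    }
    isolated <- A == 0 & N == 0
    if (any(isolated)) expect_true(all(F[isolated] == 0))
  }
})

test_that("raising a voter-candidate similarity never lowers the candidate's score", {
  set.seed(17)
  for (rep_i in 1:20) {
    A <- rand_A(5, 6, 0.4)
    M <- rand_sim(rownames(A)); D <- rand_sim(colnames(A))
    F0 <- score_matrix(A, M, D, 1 / 3)
    voters <- which(A == 1, arr.ind = TRUE)
    if (nrow(voters) == 0) next
    v <- voters[sample(nrow(voters), 1), ]
    j <- sample(ncol(A), 1)
    D2 <- D
    D2[v["col"], j] <- min(1, D[v["col"], j] + 0.3)  # voter's row, candidate's disease
    F1 <- score_matrix(A, M, D2, 1 / 3)
    expect_gte(F1[v["row"], j], F0[v["row"], j] - 1e-12)
  }
})

test_that("a verified association outscores each of its own self-vote terms", {
  set.seed(41)
  for (rep_i in 1:20) {
    A <- rand_A(6, 5, 0.3)
    M <- rand_sim(rownames(A)); D <- rand_sim(colnames(A))
    F <- score_matrix(A, M, D, 1 / 3)
    cnt <- voter_counts(A)
    voters <- which(A == 1, arr.ind = TRUE)
    for (k in seq_len(nrow(voters))) {
      i <- voters[k, 1]; j <- voters[k, 2]
      den <- cnt$N_m[i] + cnt$N_d[j] - 1
      self_row <- group_weight(cnt$N_m[i], 1 / 3) * D[j, j] / den
      self_col <- group_weight(cnt$N_d[j], 1 / 3) * M[i, i] / den
      expect_gte(F[i, j], max(self_row, self_col) - 1e-12)
    }
  }
})

test_that("axis mismatches are rejected", {
  ex <- make_worked_example()$scoring
  M_bad <- ex$M; rownames(M_bad) <- c("m1", "mX")
  expect_error(score_matrix(ex$A, M_bad, ex$D), "miRNA similarity labels")
  D_bad <- ex$D; rownames(D_bad) <- c("d1", "dX")
  expect_error(score_matrix(ex$A, ex$M, D_bad), "disease similarity labels")
  expect_error(score_matrix(ex$A, ex$M[1, 1, drop = FALSE], ex$D), "2x2")
})
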