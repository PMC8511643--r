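# Independent oracles used across tests.  These deliberately avoid the
# package's vectorised code paths.

# Literal vote-casting loop: every verified association votes for all pairs
# in its row and column; each vote = group weight x voter-candidate
# similarity x basic weight of the receiving candidate.
loop_score <- function(A, M, D, e) {
  n <- nrow(A); m <- ncol(A)
  Nm <- rowSums(A); Nd <- colSums(A)
  gw <- function(x) if (x == 0) 0 else x^e
  F <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) if (A[i, j] == 1) {
    for (s in seq_len(m)) {
      den <- Nm[i] + Nd[s] - A[i, s]
      if (den > 0) F[i, s] <- F[i, s] + gw(Nm[i]) * D[j, s] / den
    }
    for (t in seq_len(n)) {
      den <- Nm[t] + Nd[j] - A[t, j]
      if (den > 0) F[t, j] <- F[t, j] + gw(Nd[j]) * M[i, t] / den
    }
  }
  dimnames(F) <- dimnames(A)
  F
}

# Exhaustive pairwise AUC: P(pos > neg) + 0.5 P(tie) over all pairs.
pairwise_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random binary association matrix with dimnames.
rand_A <- function(n, m, p = 0.3) {
  matrix(rbinom(n * m, 1L, p), n, m,
         dimnames = list(paste0("m", seq_len(n)), paste0("d", seq_len(m))))
}

# Random symmetric unit-diagonal similarity in [0, 1].
rand_sim <- function(labels) {
  k <- length(labels)
  S <- matrix(runif(k * k), k, k)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  S
}

# Random disease ancestor graph over a shared random ontology tree:
# nodes N1..Nk, each node's parent drawn from earlier nodes (N1 = root).
rand_ontology <- function(k) {
  stopifnot(k >= 2)
  parent <- c(NA, vapply(2:k, function(i) sample(i - 1L, 1L), integer(1)))
  data.frame(child = paste0("N", 2:k),
             parent = paste0("N", parent[-1]),
             stringsAsFactors = FALSE)
}
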