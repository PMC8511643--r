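#' Specification of a synthetic miRNA-disease network
#'
#' The generator plants latent groups shared by the association matrix and
#' both similarity sources, emulating the core modelling assumption that
#' functionally similar miRNAs associate with similar diseases.  Defaults
#' mirror the scale and sparsity of curated association databases (about 3%
#' of pairs verified).
#'
#' @param n_mirna,n_disease Network dimensions.
#' @param n_groups Number of planted latent groups
#'   (`<= min(n_mirna, n_disease)`).
#' @param density Expected fraction of verified pairs, in `(0, 1)`.
#' @param within_group_boost Multiplier of the association probability when
#'   the miRNA and disease share a group; `1` removes all planted signal.
#' @param sim_noise Half-width of the uniform jitter added to the functional
#'   similarity.
#' @param seed Integer seed fixing all randomness of the generator.
#' @return A list of class `"mdv_fixture_spec"`.
#' @export
fixture_spec <- function(n_mirna = 60L, n_disease = 40L, n_groups = 4L,
                         density = 0.03, within_group_boost = 10,
                         sim_noise = 0.1, seed = 1L) {
  stopifnot(n_mirna >= 2L, n_disease >= 2L,
            n_groups >= 1L, n_groups <= min(n_mirna, n_disease),
            density > 0, density < 1,
            within_group_boost >= 0, sim_noise >= 0)
  structure(list(n_mirna = as.integer(n_mirna),
                 n_disease = as.integer(n_disease),
                 n_groups = as.integer(n_groups),
                 density = density,
                 within_group_boost = within_group_boost,
                 sim_noise = sim_noise,
                 seed = as.integer(seed)),
            class = "mdv_fixture_spec")
}

#' Generate a synthetic miRNA-disease network
#'
#' Each miRNA and disease is assigned a latent group.  A pair is verified
#' with probability `p_in = boost * p_out` when the groups match and `p_out`
#' otherwise, with `p_out` normalised so the expected density equals
#' `spec$density`.  The functional similarity is a group indicator (1 within,
#' 0.1 across) plus symmetric uniform jitter, clipped to `[0, 1]`, unit
#' diagonal.  Disease ancestor graphs hang each disease term under its group
#' term (sometimes via a private intermediate term) under a common root, so
#' same-group diseases share ancestors.
#'
#' @param spec A [fixture_spec()].
#' @return List with `A` (binary association matrix), `FM` (functional
#'   similarity), `dags` (list of disease ancestor graphs), `ontology`
#'   (edges + term mapping, as [read_ontology()] returns), and the group
#'   assignments `mirna_groups`, `disease_groups`.
#' @export
make_network <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "mdv_fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_mirna; m <- spec$n_disease; g <- spec$n_groups
  mirnas <- sprintf("mir-%03d", seq_len(n))
  diseases <- sprintf("disease-%03d", seq_len(m))
  gm <- sample(rep_len(seq_len(g), n))
  gd <- sample(rep_len(seq_len(g), m))
  match_mat <- outer(gm, gd, "==")
  f_match <- mean(match_mat)
  p_out <- spec$density / (f_match * spec$within_group_boost + (1 - f_match))
  p_in <- spec$within_group_boost * p_out
  if (p_in > 1) {
    stop(sprintf("infeasible density: within-group probability %.3f exceeds 1", p_in))
  }
  prob <- ifelse(match_mat, p_in, p_out)
  A <- matrix(as.integer(runif(n * m) < prob), n, m,
              dimnames = list(mirnas, diseases))
  # functional similarity: group indicator + symmetric jitter
  FM <- ifelse(outer(gm, gm, "=="), 1, 0.1)
  jit <- matrix(runif(n * n, -spec$sim_noise, spec$sim_noise), n, n)
  jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
  FM <- pmin(pmax(FM + jit, 0), 1)
  diag(FM) <- 1
  dimnames(FM) <- list(mirnas, mirnas)
  # ontology: root <- group terms <- (optional private intermediate) <- leaves
  root <- "T-root"
  gterm <- sprintf("T-grp%02d", seq_len(g))
  edges <- data.frame(child = gterm, parent = root, stringsAsFactors = FALSE)
  terms <- character(m)
  for (j in seq_len(m)) {
    leaf <- sprintf("T-d%03d", j)
    parent <- gterm[gd[j]]
    if (runif(1) < 0.3) {                       # occasional private depth
      mid <- sprintf("T-mid%03d", j)
      edges <- rbind(edges, data.frame(child = mid, parent = parent))
      parent <- mid
    }
    edges <- rbind(edges, data.frame(child = leaf, parent = parent))
    terms[j] <- leaf
  }
  ontology <- list(edges = edges, terms = setNames(terms, diseases))
  dags <- build_dags(ontology, diseases)
  list(A = A, FM = FM, dags = dags, ontology = ontology,
       mirna_groups = setNames(gm, mirnas),
       disease_groups = setNames(gd, diseases))
}

#' Destroy all association structure by permuting cells
#'
#' Randomly shuffles every entry of the association matrix across all
#' (miRNA, disease) positions, preserving the total number of verified pairs
#' but breaking any relation to the similarity structure and to the row and
#' column identities.  Used as the permutation null in calibration tests.
#'
#' @param A Binary association matrix.
#' @param seed Integer seed.
#' @return A matrix of the same shape, dimnames and total as `A`.
#' @export
permute_associations <- function(A, seed = 1L) {
  .check_association(A)
  set.seed(seed)
  out <- matrix(sample(as.vector(A)), nrow(A), ncol(A),
                dimnames = dimnames(A))
  out
}

#' Fixed worked examples
#'
#' Small hard-coded instances used throughout the documentation and golden
#' tests: a 3 x 2 association matrix exercising the credibility similarity,
#' and a 2 x 2 scoring instance with hand-checkable votes.
#'
#' @return List with `credibility` (fields `A`, `delta`, `base_code`) and
#'   `scoring` (fields `A`, `M`, `D`, `e`).
#' @export
make_worked_example <- function() {
  A3 <- matrix(c(1L, 0L,
                 0L, 1L,
                 1L, 1L), nrow = 3, byrow = TRUE,
               dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
  A2 <- matrix(c(1L, 0L,
                 0L, 1L), nrow = 2, byrow = TRUE,
               dimnames = list(c("m1", "m2"), c("d1", "d2")))
  M2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(rownames(A2), rownames(A2)))
  D2 <- matrix(c(1, 0.2, 0.2, 1), 2, dimnames = list(colnames(A2), colnames(A2)))
  list(
    credibility = list(A = A3, delta = 2, base_code = -1),
    scoring = list(A = A2, M = M2, D = D2, e = 0)
  )
}

#' Write a synthetic network to the standard input files
#'
#' Emits the association edge list, the functional-similarity matrix, the
#' ontology edge list and the disease-term mapping into a directory, in the
#' formats the pipeline reads.
#'
#' @param net A network from [make_network()].
#' @param dir Output directory (created if needed).
#' @param delim `"tab"` or `"comma"`.
#' @return Named character vector of the written paths.
#' @export
write_network <- function(net, dir, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    associations = file.path(dir, "associations.tsv"),
    mirna_sim = file.path(dir, "mirna_similarity.tsv"),
    ontology_edges = file.path(dir, "ontology_edges.tsv"),
    ontology_terms = file.path(dir, "disease_terms.tsv")
  )
  write_associations(net$A, paths[["associations"]], delim)
  write_similarity(net$FM, paths[["mirna_sim"]], delim)
  write.table(net$ontology$edges, paths[["ontology_edges"]], sep = sep,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(net$ontology$terms), unname(net$ontology$terms)),
              paths[["ontology_terms"]], sep = sep,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  paths
}
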