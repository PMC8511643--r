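#' Build a disease's ancestor graph
#'
#' Restricts the ontology to the disease's own term plus all of its ancestors
#' (the node set `T(D)`), with the child-to-parent edges induced among them.
#' A disease whose term does not occur in the ontology gets a singleton graph
#' with a warning: it can then match other diseases only through itself.
#'
#' @param disease Disease label.
#' @param term Ontology term id of the disease.
#' @param edges Data frame of (child, parent) term pairs (see
#'   [read_ontology()]).
#' @return A list of class `"mdv_dag"`: `disease`, `term`, `nodes`
#'   (character, term first), `edges` (induced child/parent data frame).
#' @export
disease_dag <- function(disease, term, edges) {
  stopifnot(is.character(term), length(term) == 1L)
  known <- unique(c(edges$child, edges$parent))
  if (!term %in% known) {
    if (nrow(edges) > 0L) {
      warning(sprintf("term '%s' (disease '%s') not in ontology; using singleton ancestor graph",
                      term, disease))
    }
    return(structure(list(disease = disease, term = term, nodes = term,
                          edges = edges[0, , drop = FALSE]),
                     class = "mdv_dag"))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology edge relation contains a cycle")
  # all terms reachable from `term` along child -> parent edges
  anc <- igraph::subcomponent(g, term, mode = "out")
  nodes <- names(anc)
  nodes <- c(term, setdiff(nodes, term))
  sub <- edges[edges$child %in% nodes & edges$parent %in% nodes, , drop = FALSE]
  rownames(sub) <- NULL
  structure(list(disease = disease, term = term, nodes = nodes, edges = sub),
            class = "mdv_dag")
}

#' Per-term semantic contributions within a disease's ancestor graph
#'
#' The disease's own term contributes 1; any ancestor `d` contributes
#' `max(omega * contribution(child))` over its children inside the graph, so
#' contributions decay geometrically with the distance from the disease.
#'
#' @param dag A `"mdv_dag"` from [disease_dag()].
#' @param omega Semantic contribution factor in `(0, 1]`.
#' @return Named numeric vector of contributions over `dag$nodes`.
#' @export
contribution <- function(dag, omega = 0.5) {
  stopifnot(inherits(dag, "mdv_dag"), omega > 0, omega <= 1)
  nodes <- dag$nodes
  val <- setNames(rep(NA_real_, length(nodes)), nodes)
  val[dag$term] <- 1
  children_of <- split(dag$edges$child, dag$edges$parent)
  visiting <- character(0)
  rec <- function(d) {
    if (!is.na(val[[d]])) return(val[[d]])
    if (d %in% visiting) stop("cycle detected in ancestor graph at term ", d)
    visiting <<- c(visiting, d)
    ch <- intersect(children_of[[d]], nodes)
    if (length(ch) == 0L) {
      stop(sprintf("term '%s' unreachable from disease term '%s'", d, dag$term))
    }
    v <- max(omega * vapply(ch, rec, numeric(1)))
    visiting <<- setdiff(visiting, d)
    val[[d]] <<- v
    v
  }
  for (d in nodes) rec(d)
  val
}

#' Semantic value of a disease
#'
#' Sum of the per-term contributions over the disease's ancestor graph;
#' always `>= 1` (the disease itself contributes 1).
#'
#' @inheritParams contribution
#' @return A single number.
#' @export
semantic_value <- function(dag, omega = 0.5) {
  sum(contribution(dag, omega))
}

#' Disease semantic similarity matrix
#'
#' For diseases `di`, `dj` with ancestor graphs `T(di)`, `T(dj)`, the
#' similarity is the summed contribution of the shared terms from both sides,
#' normalised by the two semantic values:
#' `SD(di, dj) = sum_t (D_di(t) + D_dj(t)) / (V(di) + V(dj))` over
#' `t` in `T(di) & T(dj)`.  Symmetric, unit diagonal, values in `[0, 1]`.
#'
#' @param dags List of `"mdv_dag"` objects, one per disease.
#' @inheritParams contribution
#' @return Named numeric similarity matrix over the diseases.
#' @export
semantic_similarity_matrix <- function(dags, omega = 0.5) {
  stopifnot(length(dags) >= 1L)
  diseases <- vapply(dags, `[[`, character(1), "disease")
  if (anyDuplicated(diseases)) stop("duplicate disease labels in DAG list")
  contribs <- lapply(dags, contribution, omega = omega)
  V <- vapply(contribs, sum, numeric(1))
  k <- length(dags)
  SD <- diag(1, k)
  dimnames(SD) <- list(diseases, diseases)
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      ci <- contribs[[i]]
      for (j in seq.int(i + 1L, k)) {
        cj <- contribs[[j]]
        shared <- intersect(names(ci), names(cj))
        s <- if (length(shared)) {
          sum(ci[shared] + cj[shared]) / (V[i] + V[j])
        } else 0
        SD[i, j] <- SD[j, i] <- s
      }
    }
  }
  attr(SD, "symmetric") <- TRUE
  SD
}

#' Ancestor graphs for all diseases of an ontology input
#'
#' @param ontology List with `edges` and `terms` (see [read_ontology()]).
#' @param diseases Diseases to build graphs for (default: all mapped).
#' @return Named list of `"mdv_dag"` objects.
#' @export
build_dags <- function(ontology, diseases = names(ontology$terms)) {
  missing <- setdiff(diseases, names(ontology$terms))
  if (length(missing)) {
    stop("no ontology term mapped for disease(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  dags <- lapply(diseases, function(d) {
    disease_dag(d, ontology$terms[[d]], ontology$edges)
  })
  names(dags) <- diseases
  dags
}
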