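#' End-to-end association scoring
#'
#' Runs the full model on an association matrix and external similarities:
#' credibility similarity on both axes, integration with the functional and
#' semantic similarities, adaptive row filtering, and weighted voting.
#'
#' @param A Binary association matrix (miRNAs x diseases, dimnames required).
#' @param FM miRNA functional similarity aligned to `rownames(A)`.
#' @param SD Disease semantic similarity aligned to `colnames(A)`.
#' @param params Model parameters from [mdv_params()].
#' @param detail If `TRUE`, also return the intermediate matrices.
#' @return The score matrix, or (with `detail = TRUE`) a list with `scores`,
#'   `C` (credibility matrix), `CM`, `CD`, `M`, `D` (integrated, post-filter
#'   when filtering is on).
#' @examples
#' net <- make_network(fixture_spec(n_mirna = 12, n_disease = 8, seed = 1))
#' SD <- semantic_similarity_matrix(net$dags)
#' F <- predict_associations(net$A, net$FM, SD)
#' head(write_rankings(F, net$A))
#' @export
predict_associations <- function(A, FM, SD, params = mdv_params(),
                                 detail = FALSE) {
  .check_association(A)
  stopifnot(inherits(params, "mdv_params"))
  FM <- align_similarity(FM, rownames(A))
  SD <- align_similarity(SD, colnames(A))
  C <- build_credibility(A, params$delta, params$base_code)
  CM <- scale_credibility(raw_credibility_similarity(C))
  CD <- scale_credibility(raw_credibility_similarity(t(C)))
  M <- integrate_similarity(FM, CM)
  D <- integrate_similarity(SD, CD)
  if (params$filter) {
    M <- filter_matrix(M, params$r, params$symmetrize)
    D <- filter_matrix(D, params$r, params$symmetrize)
  }
  F <- score_matrix(A, M, D, params$e)
  if (!detail) return(F)
  list(scores = F, C = C, CM = CM, CD = CD, M = M, D = D)
}

#' Run the file-based prediction pipeline
#'
#' Reads the association edge list and similarity inputs, computes disease
#' semantic similarity from an ontology when no precomputed matrix is given,
#' scores every pair, and writes the ranked prediction table.  Each stage is
#' logged via `message()`.
#'
#' @param associations Path to the 2-column association edge list.
#' @param mirna_sim Path to the miRNA functional-similarity matrix.
#' @param disease_sim Path to a precomputed disease semantic-similarity
#'   matrix, or `NULL` to derive it from the ontology.
#' @param ontology_edges,ontology_terms Paths to the ontology (child, parent)
#'   edge list and the (disease, term) mapping; used when `disease_sim` is
#'   `NULL`.
#' @param out Path for the ranked prediction table (`NULL`: don't write).
#' @param params Model parameters from [mdv_params()].
#' @param delim Field delimiter of all files, `"tab"` or `"comma"`.
#' @return List with `scores` and the ranking `data.frame` (`rankings`),
#'   invisibly.
#' @export
run_pipeline <- function(associations, mirna_sim, disease_sim = NULL,
                         ontology_edges = NULL, ontology_terms = NULL,
                         out = NULL, params = mdv_params(),
                         delim = c("tab", "comma")) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  A <- stage("read associations", read_associations(associations, delim))
  message(sprintf("associations: %d miRNAs x %d diseases, %d known pairs",
                  nrow(A), ncol(A), sum(A)))
  FM <- stage("read miRNA similarity", read_similarity(mirna_sim, delim))
  if (!is.null(disease_sim)) {
    SD <- stage("read disease similarity", read_similarity(disease_sim, delim))
  } else {
    if (is.null(ontology_edges) || is.null(ontology_terms)) {
      stop("[disease similarity] supply either a similarity matrix or an ontology")
    }
    ont <- stage("read ontology", read_ontology(ontology_edges, ontology_terms, delim))
    dags <- stage("build ancestor graphs", build_dags(ont, colnames(A)))
    SD <- stage("semantic similarity",
                semantic_similarity_matrix(dags, params$omega))
    message(sprintf("semantic similarity: %d diseases (omega = %.3g)",
                    ncol(SD), params$omega))
  }
  message(sprintf("scoring with delta = %.3g, base = %.3g, r = %.3g, e = %.4g",
                  params$delta, params$base_code, params$r, params$e))
  F <- stage("scoring", predict_associations(A, FM, SD, params))
  rk <- stage("rank predictions", write_rankings(F, A, out, delim))
  if (!is.null(out)) message("rankings written to ", out)
  invisible(list(scores = F, rankings = rk))
}
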