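#' Read a miRNA-disease association edge list
#'
#' Reads a two-column delimited file of (miRNA, disease) pairs and builds the
#' binary association matrix `A`: `A[i, j] = 1` if the pair is listed, `0`
#' otherwise.  Axis order is first-appearance order in the file, which is the
#' canonical order for every downstream matrix.  Duplicate pairs collapse to a
#' single 1.
#'
#' @param path Path to the edge-list file.
#' @param delim `"tab"` (default) or `"comma"`.
#' @return A binary integer matrix with miRNAs as named rows and diseases as
#'   named columns.
#' @examples
#' f <- tempfile()
#' writeLines(c("m1\td1", "m2\td2"), f)
#' read_associations(f)
#' @seealso [write_associations()], [read_similarity()]
#' @export
read_associations <- function(path, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  if (!file.exists(path)) stop("association file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  if (!any(keep)) stop("association file is empty: ", path)
  lineno <- which(keep)
  fields <- strsplit(raw[keep], sep, fixed = TRUE)
  ok <- lengths(fields) == 2L &
    vapply(fields, function(f) all(nzchar(trimws(f))), logical(1))
  if (!all(ok)) {
    stop(sprintf(
      "malformed association record (need exactly 2 non-empty fields) at line %d of %s",
      lineno[which(!ok)[1L]], path
    ))
  }
  mi <- trimws(vapply(fields, `[[`, character(1), 1L))
  ds <- trimws(vapply(fields, `[[`, character(1), 2L))
  mirnas <- unique(mi)
  diseases <- unique(ds)
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(mi, mirnas), match(ds, diseases))] <- 1L
  A
}

#' Write an association matrix as an edge list
#'
#' Emits the `A == 1` pairs in row-major order (all diseases of the first
#' miRNA, then the second, ...).  Rows or columns without any association
#' cannot be represented in an edge list and are silently absent on re-read.
#'
#' @param A Binary association matrix with dimnames.
#' @inheritParams read_associations
#' @return `path`, invisibly.
#' @export
write_associations <- function(A, path, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  .check_association(A)
  idx <- which(t(A) == 1)                       # row-major enumeration
  j <- (idx - 1L) %% ncol(A) + 1L
  i <- (idx - 1L) %/% ncol(A) + 1L
  writeLines(paste(rownames(A)[i], colnames(A)[j], sep = sep), path)
  invisible(path)
}

#' Read a square similarity matrix
#'
#' Expects a delimited file with a header row of labels and the same labels,
#' in the same order, in the first column.  Symmetry is checked to a tolerance
#' of `1e-8` and recorded in the `"symmetric"` attribute; an asymmetric
#' matrix loads fine (the row filter produces such matrices).
#'
#' @inheritParams read_associations
#' @return A numeric matrix with identical row and column names and a logical
#'   attribute `"symmetric"`.
#' @export
read_similarity <- function(path, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  if (!file.exists(path)) stop("similarity file not found: ", path)
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("similarity file needs a label column plus values: ", path)
  labels <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  if (nrow(vals) != ncol(vals)) {
    stop(sprintf("similarity matrix is not square: %d rows, %d columns",
                 nrow(vals), ncol(vals)))
  }
  if (!identical(labels, colnames(vals))) {
    stop("similarity row labels do not match header labels in the same order")
  }
  num <- vapply(vals, function(col) is.numeric(col) || all(!is.na(suppressWarnings(as.numeric(col)))), logical(1))
  if (!all(num)) {
    stop("non-numeric similarity value in column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  }
  S <- as.matrix(vals)
  storage.mode(S) <- "double"
  dimnames(S) <- list(labels, labels)
  attr(S, "symmetric") <- max(abs(S - t(S))) <= 1e-8
  S
}

#' Write a square similarity matrix
#'
#' Full precision (17 significant digits), so `read_similarity()` recovers
#' the values to within `1e-12`.
#'
#' @param S Square numeric matrix with dimnames.
#' @inheritParams read_associations
#' @return `path`, invisibly.
#' @export
write_similarity <- function(S, path, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  stopifnot(is.matrix(S), nrow(S) == ncol(S), !is.null(rownames(S)))
  out <- cbind(name = rownames(S),
               as.data.frame(format(S, digits = 17, trim = TRUE, scientific = TRUE)))
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ontology as flattened edge + mapping tables
#'
#' @param edges_path Two-column delimited file of (child term, parent term).
#' @param mapping_path Two-column delimited file of (disease label, term id).
#' @inheritParams read_associations
#' @return A list with `edges` (data.frame `child`, `parent`) and `terms`
#'   (named character vector, disease label -> term id).  The edge relation
#'   must be acyclic.
#' @export
read_ontology <- function(edges_path, mapping_path, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  ed <- read.delim(edges_path, sep = sep, header = FALSE,
                   stringsAsFactors = FALSE, col.names = c("child", "parent"))
  mp <- read.delim(mapping_path, sep = sep, header = FALSE,
                   stringsAsFactors = FALSE, col.names = c("disease", "term"))
  edges <- data.frame(child = as.character(ed$child),
                      parent = as.character(ed$parent),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (!igraph::is_dag(g)) stop("ontology edge relation contains a cycle")
  terms <- setNames(as.character(mp$term), as.character(mp$disease))
  known <- unique(c(edges$child, edges$parent))
  orphan <- setdiff(terms, known)
  if (length(orphan)) {
    # isolated roots are legal (singleton ancestor graphs)
    message(length(orphan), " mapped term(s) absent from the edge set; treated as isolated roots")
  }
  list(edges = edges, terms = terms)
}

#' Write ranked predictions
#'
#' Emits every (miRNA, disease) pair with its predicted score and whether the
#' association is already known, sorted by descending score; ties broken by
#' (miRNA index, disease index) ascending, i.e. the canonical axis order.
#'
#' @param scores Numeric score matrix sharing axes with `A`.
#' @param A Binary association matrix.
#' @param path Output path (`NULL` to return the table without writing).
#' @inheritParams read_associations
#' @return The ranked `data.frame` (invisibly when written).
#' @export
write_rankings <- function(scores, A, path = NULL, delim = c("tab", "comma")) {
  sep <- .mdv_sep(delim)
  if (length(scores) == 0L) stop("empty score matrix")
  if (!identical(dimnames(scores), dimnames(A)) ||
      !identical(dim(scores), dim(A))) {
    stop("score matrix and association matrix must share axes")
  }
  i <- rep(seq_len(nrow(A)), times = ncol(A))
  j <- rep(seq_len(ncol(A)), each = nrow(A))
  tab <- data.frame(
    miRNA = rownames(A)[i],
    disease = colnames(A)[j],
    score = as.vector(scores),
    known = as.integer(as.vector(A) == 1),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$score, i, j), , drop = FALSE]
  rownames(tab) <- NULL
  if (is.null(path)) return(tab)
  write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Align a similarity matrix to the canonical axis of an association matrix
#'
#' Labels present in `S` but absent from `labels` are dropped with a warning;
#' labels missing from `S` are an error (the method needs a similarity row
#' per entity).
#'
#' @param S Square named similarity matrix.
#' @param labels Character vector of required labels in canonical order.
#' @return `S` restricted and reordered to `labels`.
#' @export
align_similarity <- function(S, labels) {
  stopifnot(is.matrix(S), !is.null(rownames(S)))
  missing <- setdiff(labels, rownames(S))
  if (length(missing)) {
    stop("similarity matrix lacks required label(s): ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  extra <- setdiff(rownames(S), labels)
  if (length(extra)) {
    warning(length(extra), " similarity label(s) absent from the association matrix were dropped")
  }
  S[labels, labels, drop = FALSE]
}

.mdv_sep <- function(delim = c("tab", "comma")) {
  if (is.character(delim) && length(delim) > 0 && delim[1] %in% c("\t", ","))
    return(delim[1])
  switch(match.arg(delim), tab = "\t", comma = ",")
}

.check_association <- function(A) {
  stopifnot(is.matrix(A))
  if (is.null(rownames(A)) || is.null(colnames(A))) {
    stop("association matrix needs miRNA row names and disease column names")
  }
  if (anyDuplicated(rownames(A)) || anyDuplicated(colnames(A))) {
    stop("association matrix labels must be unique within each axis")
  }
  if (!all(A %in% c(0, 1))) stop("association matrix must be binary")
  invisible(TRUE)
}
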