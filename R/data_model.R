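#' Construct a binary miRNA-disease association dataset
#'
#' Bundles the binary association matrix `A` (miRNAs in rows, diseases in
#' columns) with its ordered identifier lists. Row `i` of `A` is the
#' interaction profile of miRNA `i`; column `j` is the interaction profile of
#' disease `j`.
#'
#' @param A numeric matrix with entries in \{0, 1\}.
#' @param mirna_ids character vector of unique miRNA identifiers (rows).
#' @param disease_ids character vector of unique disease identifiers (columns).
#' @return An object of class `association_dataset` with fields `mirna_ids`,
#'   `disease_ids` and `A` (dimnames set from the identifier lists).
#' @export
association_dataset <- function(A, mirna_ids = rownames(A),
                                disease_ids = colnames(A)) {
  A <- as.matrix(A)
  if (is.null(mirna_ids) || is.null(disease_ids)) {
    stop("mirna_ids and disease_ids are required (or set dimnames on A)")
  }
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (nrow(A) < 1L || ncol(A) < 1L) stop("A must be at least 1 x 1")
  if (length(mirna_ids) != nrow(A)) stop("length(mirna_ids) != nrow(A)")
  if (length(disease_ids) != ncol(A)) stop("length(disease_ids) != ncol(A)")
  if (anyDuplicated(mirna_ids)) stop("duplicate miRNA identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (!all(A %in% c(0, 1))) stop("A must be binary (entries 0 or 1)")
  storage.mode(A) <- "double"
  dimnames(A) <- list(mirna_ids, disease_ids)
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids, A = A),
            class = "association_dataset")
}

#' @export
print.association_dataset <- function(x, ...) {
  cat(sprintf("association_dataset: %d miRNAs x %d diseases, %d known associations\n",
              length(x$mirna_ids), length(x$disease_ids), sum(x$A)))
  invisible(x)
}

#' Read an association edge list
#'
#' Reads a two-column tab-separated file of (miRNA id, disease id) pairs.
#' Lines starting with `#` and blank lines are ignored. Identifiers are
#' sorted lexicographically so the matrix layout is deterministic, and
#' duplicate edges collapse to a single association.
#'
#' @param path path to a TSV edge list.
#' @return An [association_dataset()].
#' @export
load_association_edges <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("empty edge list: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 2L)) {
    bad <- idx[which(nfield != 2L)[1L]]
    stop(sprintf("malformed edge list line %d in %s: expected 2 tab-separated columns",
                 bad, path))
  }
  m <- trimws(vapply(parts, `[[`, "", 1L))
  d <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(m == "") || any(d == "")) stop("empty identifier in edge list: ", path)
  mirna_ids <- sort(unique(m))
  disease_ids <- sort(unique(d))
  A <- matrix(0, length(mirna_ids), length(disease_ids),
              dimnames = list(mirna_ids, disease_ids))
  A[cbind(match(m, mirna_ids), match(d, disease_ids))] <- 1
  association_dataset(A, mirna_ids, disease_ids)
}

#' Write an association dataset as an edge list
#'
#' @param dataset an [association_dataset()].
#' @param path output path (TSV, two columns, no header).
#' @export
save_association_edges <- function(dataset, path) {
  stopifnot(inherits(dataset, "association_dataset"))
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  pos <- pos[order(pos[, 1L], pos[, 2L]), , drop = FALSE]
  lines <- paste(dataset$mirna_ids[pos[, 1L]], dataset$disease_ids[pos[, 2L]],
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Construct a labeled similarity matrix
#'
#' A square non-negative similarity matrix over one entity class (miRNAs or
#' diseases). The matrix is symmetrized as `(S + t(S)) / 2` on construction.
#'
#' @param S square numeric matrix with finite non-negative entries.
#' @param ids character vector of unique identifiers, one per row/column.
#' @param symmetrize if `TRUE` (default) store `(S + t(S)) / 2`.
#' @return An object of class `similarity_matrix` with fields `ids` and `S`.
#' @export
similarity_matrix <- function(S, ids = rownames(S), symmetrize = TRUE) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) stop("similarity matrix must be square")
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(S)))
  ids <- as.character(ids)
  if (length(ids) != nrow(S)) stop("length(ids) != nrow(S)")
  if (anyDuplicated(ids)) stop("duplicate identifiers")
  if (!all(is.finite(S))) stop("similarity matrix has non-finite entries")
  if (any(S < 0)) stop("similarity matrix has negative entries")
  if (symmetrize) S <- (S + t(S)) / 2
  storage.mode(S) <- "double"
  dimnames(S) <- list(ids, ids)
  structure(list(ids = ids, S = S), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix: %d x %d, range [%.4g, %.4g]\n",
              nrow(x$S), ncol(x$S), min(x$S), max(x$S)))
  invisible(x)
}

#' Read a labeled square similarity matrix
#'
#' Expects a TSV file with a header row of identifiers and a first column of
#' identifiers; row and column labels must agree in the same order. The
#' matrix is symmetrized on load; negative entries are rejected.
#'
#' @param path path to a labeled TSV matrix.
#' @return A [similarity_matrix()].
#' @export
load_similarity_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (!is.numeric(M)) stop("non-numeric entry in similarity matrix: ", path)
  if (nrow(M) != ncol(M)) stop("similarity matrix not square: ", path)
  if (!identical(rownames(M), colnames(M))) {
    stop("row labels do not match column labels in ", path)
  }
  similarity_matrix(M, rownames(M))
}

#' Write a labeled similarity matrix
#'
#' @param sm a [similarity_matrix()].
#' @param path output TSV path.
#' @export
save_similarity_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "similarity_matrix"))
  .write_labeled_matrix(sm$S, path)
}

.write_labeled_matrix <- function(M, path) {
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a score matrix
#'
#' Real-valued miRNA-by-disease matrix holding either the denoised
#' association matrix or the final predicted association scores.
#'
#' @param scores numeric matrix (miRNAs in rows, diseases in columns), finite.
#' @param mirna_ids,disease_ids identifier vectors.
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(scores, mirna_ids = rownames(scores),
                         disease_ids = colnames(scores)) {
  scores <- as.matrix(scores)
  if (!all(is.finite(scores))) stop("scores must be finite")
  mirna_ids <- as.character(mirna_ids)
  disease_ids <- as.character(disease_ids)
  if (length(mirna_ids) != nrow(scores)) stop("length(mirna_ids) != nrow(scores)")
  if (length(disease_ids) != ncol(scores)) stop("length(disease_ids) != ncol(scores)")
  dimnames(scores) <- list(mirna_ids, disease_ids)
  structure(list(mirna_ids = mirna_ids, disease_ids = disease_ids,
                 scores = scores), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix: %d miRNAs x %d diseases, range [%.4g, %.4g]\n",
              nrow(x$scores), ncol(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Write a score matrix as labeled TSV
#'
#' @param scores a [score_matrix()].
#' @param path output TSV path.
#' @export
save_scores <- function(scores, path) {
  stopifnot(inherits(scores, "score_matrix"))
  .write_labeled_matrix(scores$scores, path)
}

#' Read a score matrix written by [save_scores()]
#'
#' @param path TSV path.
#' @return A [score_matrix()].
#' @export
load_scores <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          comment.char = "#", check.names = FALSE)
  M <- as.matrix(df)
  score_matrix(M, rownames(M), colnames(M))
}

#' Restrict dataset and similarity matrices to their common identifiers
#'
#' Intersects the dataset's miRNA ids with the miRNA similarity ids and its
#' disease ids with the disease similarity ids, reorders everything
#' consistently (dataset order), and drops entities missing from a
#' similarity matrix with a warning.
#'
#' @param dataset an [association_dataset()].
#' @param sm miRNA [similarity_matrix()].
#' @param sd disease [similarity_matrix()].
#' @return list with elements `dataset`, `sm`, `sd`.
#' @export
align_inputs <- function(dataset, sm, sd) {
  stopifnot(inherits(dataset, "association_dataset"),
            inherits(sm, "similarity_matrix"),
            inherits(sd, "similarity_matrix"))
  mk <- intersect(dataset$mirna_ids, sm$ids)
  dk <- intersect(dataset$disease_ids, sd$ids)
  if (length(mk) == 0L) stop("no miRNA identifiers shared with the miRNA similarity matrix")
  if (length(dk) == 0L) stop("no disease identifiers shared with the disease similarity matrix")
  nmiss <- length(dataset$mirna_ids) - length(mk)
  ndmiss <- length(dataset$disease_ids) - length(dk)
  if (nmiss > 0L) warning(sprintf("dropping %d miRNA(s) absent from the similarity matrix", nmiss))
  if (ndmiss > 0L) warning(sprintf("dropping %d disease(s) absent from the similarity matrix", ndmiss))
  ds <- association_dataset(dataset$A[mk, dk, drop = FALSE], mk, dk)
  list(dataset = ds,
       sm = similarity_matrix(sm$S[mk, mk, drop = FALSE], mk, symmetrize = FALSE),
       sd = similarity_matrix(sd$S[dk, dk, drop = FALSE], dk, symmetrize = FALSE))
}

#' Rank the top candidate miRNAs for one disease
#'
#' Sorts the score column of one disease in decreasing order (ties broken by
#' miRNA id, lexicographically) and returns the top `k`. With
#' `exclude_known = TRUE` known associations (`A == 1`) are removed before
#' ranking, which is the setting used for prospective candidate lists.
#'
#' @param scores a [score_matrix()].
#' @param disease_id disease identifier to rank.
#' @param k number of candidates to return (`>= 1`); truncated to the number
#'   of available candidates.
#' @param exclude_known drop pairs already present in `dataset`.
#' @param dataset required when `exclude_known = TRUE`.
#' @return data.frame with columns `rank`, `mirna`, `score`.
#' @export
top_k <- function(scores, disease_id, k, exclude_known = FALSE, dataset = NULL) {
  stopifnot(inherits(scores, "score_matrix"), k >= 1)
  j <- match(disease_id, scores$disease_ids)
  if (is.na(j)) stop("unknown disease id: ", disease_id)
  s <- scores$scores[, j]
  ids <- scores$mirna_ids
  if (exclude_known) {
    if (is.null(dataset)) stop("dataset required when exclude_known = TRUE")
    jj <- match(disease_id, dataset$disease_ids)
    if (is.na(jj)) stop("unknown disease id in dataset: ", disease_id)
    known <- dataset$mirna_ids[dataset$A[, jj] == 1]
    keep <- !(ids %in% known)
    s <- s[keep]
    ids <- ids[keep]
  }
  ord <- order(-s, ids)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(rank = seq_along(ord), mirna = ids[ord], score = s[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}
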