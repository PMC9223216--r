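#' Construct a disease DAG corpus
#'
#' Each disease is described by the directed acyclic graph of itself and its
#' ancestor terms (MeSH-style). A DAG is given as a node set together with a
#' parent map; edges point from child to parent. The corpus also fixes the
#' universe size used as the denominator of the term-frequency contribution
#' model.
#'
#' @param dags named list, one entry per disease. Each entry is a list with
#'   `nodes` (character vector of terms, containing the disease itself) and
#'   `parents` (named list mapping a term to the character vector of its
#'   parent terms inside the DAG; terms without an entry are roots).
#' @param universe_size number of diseases in the universe; defaults to the
#'   number of DAGs in the corpus.
#' @return An object of class `dag_corpus`.
#' @export
dag_corpus <- function(dags, universe_size = length(dags)) {
  if (is.null(names(dags)) || anyDuplicated(names(dags))) {
    stop("dags must be a uniquely named list (one entry per disease)")
  }
  if (universe_size < 1) stop("universe_size must be >= 1")
  for (d in names(dags)) {
    g <- dags[[d]]
    if (!all(c("nodes", "parents") %in% names(g))) {
      stop("DAG for ", d, " must have fields 'nodes' and 'parents'")
    }
    if (!(d %in% g$nodes)) stop("disease ", d, " is not a node of its own DAG")
    pn <- unlist(g$parents, use.names = FALSE)
    if (!all(pn %in% g$nodes)) stop("DAG for ", d, " names a parent that is not a node")
    if (!all(names(g$parents) %in% g$nodes)) {
      stop("DAG for ", d, " has a parent entry for a non-node term")
    }
    .check_acyclic(g, d)
  }
  structure(list(diseases = names(dags), dags = dags,
                 universe_size = universe_size),
            class = "dag_corpus")
}

# DFS cycle check over child -> parent edges
.check_acyclic <- function(g, label) {
  state <- new.env(parent = emptyenv())
  visit <- function(t) {
    st <- if (is.null(state[[t]])) 0L else state[[t]]
    if (st == 1L) stop("cycle detected in DAG for ", label)
    if (st == 2L) return(invisible())
    state[[t]] <- 1L
    for (p in g$parents[[t]]) visit(p)
    state[[t]] <- 2L
  }
  for (t in g$nodes) visit(t)
}

#' @export
print.dag_corpus <- function(x, ...) {
  cat(sprintf("dag_corpus: %d diseases, universe size %d\n",
              length(x$diseases), x$universe_size))
  invisible(x)
}

#' Read a DAG corpus from an edge file and a roster file
#'
#' The edge file is a TSV with columns (child term, parent term), pooled
#' across diseases. The roster file is a TSV with columns (disease, term)
#' listing the node set of every disease's DAG; edges are restricted to each
#' disease's roster. `#` comment lines are ignored in both files.
#'
#' @param edges_path TSV of child/parent term pairs.
#' @param roster_path TSV of disease/term pairs.
#' @param universe_size optional universe override.
#' @return A [dag_corpus()].
#' @export
load_dag_corpus <- function(edges_path, roster_path, universe_size = NULL) {
  ed <- utils::read.table(edges_path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("child", "parent"))
  ro <- utils::read.table(roster_path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("disease", "term"))
  dags <- lapply(split(ro$term, ro$disease), function(nodes) {
    nodes <- unique(nodes)
    sel <- ed$child %in% nodes & ed$parent %in% nodes
    parents <- split(ed$parent[sel], ed$child[sel])
    list(nodes = nodes, parents = lapply(parents, unique))
  })
  if (is.null(universe_size)) universe_size <- length(dags)
  dag_corpus(dags, universe_size)
}

#' Write a DAG corpus in the edge + roster layout read by [load_dag_corpus()]
#'
#' @param corpus a [dag_corpus()].
#' @param edges_path,roster_path output TSV paths.
#' @export
save_dag_corpus <- function(corpus, edges_path, roster_path) {
  stopifnot(inherits(corpus, "dag_corpus"))
  edges <- character(0)
  roster <- character(0)
  for (d in corpus$diseases) {
    g <- corpus$dags[[d]]
    roster <- c(roster, paste(d, g$nodes, sep = "\t"))
    for (ch in names(g$parents)) {
      edges <- c(edges, paste(ch, g$parents[[ch]], sep = "\t"))
    }
  }
  writeLines(unique(edges), edges_path)
  writeLines(roster, roster_path)
  invisible(corpus)
}

#' Decay-model semantic contributions of a disease's ancestor terms
#'
#' The disease itself contributes 1; every other term `t` in the DAG
#' contributes `max(delta * contribution(child))` over its children inside
#' the DAG, so a term's contribution decays geometrically with its distance
#' from the disease.
#'
#' @param corpus a [dag_corpus()].
#' @param disease disease identifier present in the corpus.
#' @param delta semantic contribution factor in (0, 1]; default 0.5.
#' @return named numeric vector of contributions over the DAG's terms.
#' @export
contribution_model1 <- function(corpus, disease, delta = 0.5) {
  stopifnot(inherits(corpus, "dag_corpus"))
  if (!(delta > 0 && delta <= 1)) stop("delta must be in (0, 1]")
  g <- corpus$dags[[disease]]
  if (is.null(g)) stop("disease not in corpus: ", disease)
  # children map: child -> parent edges reversed
  children <- lapply(stats::setNames(g$nodes, g$nodes), function(...) character(0))
  for (ch in names(g$parents)) {
    for (p in g$parents[[ch]]) children[[p]] <- c(children[[p]], ch)
  }
  memo <- new.env(parent = emptyenv())
  active <- new.env(parent = emptyenv())
  dd1 <- function(t) {
    if (!is.null(memo[[t]])) return(memo[[t]])
    if (isTRUE(active[[t]])) stop("cycle detected in DAG for ", disease)
    active[[t]] <- TRUE
    val <- if (t == disease) {
      1
    } else {
      ch <- children[[t]]
      if (length(ch) == 0L) {
        stop("term '", t, "' in DAG for ", disease,
             " is not an ancestor of the disease (no child path)")
      }
      max(vapply(ch, function(c) delta * dd1(c), numeric(1)))
    }
    active[[t]] <- FALSE
    memo[[t]] <- val
    val
  }
  vapply(stats::setNames(g$nodes, g$nodes), dd1, numeric(1))
}

#' Sum a contribution map into a semantic value
#'
#' @param contribs named numeric vector of per-term contributions.
#' @return The disease's semantic value (sum of contributions).
#' @export
semantic_value <- function(contribs) {
  if (length(contribs) == 0L) stop("empty contribution map")
  sum(contribs)
}

#' Frequency-model semantic contributions, shared across the corpus
#'
#' A term's contribution is `-log(n_t / N)` (natural log), where `n_t` is
#' the number of corpus DAGs containing the term and `N` is the universe
#' size, so rare terms contribute more than ubiquitous ones. The value is
#' corpus-wide: unlike the decay model it does not depend on which disease's
#' DAG the term is viewed from.
#'
#' @param corpus a [dag_corpus()].
#' @return named numeric vector over all terms appearing in the corpus.
#' @export
contribution_model2 <- function(corpus) {
  stopifnot(inherits(corpus, "dag_corpus"))
  if (corpus$universe_size < 1) stop("universe_size must be >= 1")
  terms <- unlist(lapply(corpus$dags, `[[`, "nodes"), use.names = FALSE)
  counts <- table(terms)
  if (any(counts == 0)) stop("term with zero DAG count")
  vals <- -log(as.numeric(counts) / corpus$universe_size)
  stats::setNames(vals, names(counts))
}

#' Semantic similarity between one pair of diseases
#'
#' Shared-ancestor similarity: the contributions of terms in the
#' intersection of the two DAGs, from both sides, divided by the sum of the
#' two semantic values. Works for either contribution model.
#'
#' @param corpus a [dag_corpus()].
#' @param d_i,d_j disease identifiers.
#' @param contribs_i,contribs_j named contribution vectors for the two DAGs.
#' @param dv_i,dv_j the corresponding semantic values (must be positive).
#' @return similarity in \[0, 1\].
#' @export
semantic_similarity_pair <- function(corpus, d_i, d_j, contribs_i, contribs_j,
                                     dv_i, dv_j) {
  stopifnot(inherits(corpus, "dag_corpus"))
  if (!(d_i %in% corpus$diseases) || !(d_j %in% corpus$diseases)) {
    stop("both diseases must be in the corpus")
  }
  if (dv_i + dv_j <= 0) stop("zero denominator: semantic values must be positive")
  shared <- intersect(names(contribs_i), names(contribs_j))
  if (length(shared) == 0L) return(0)
  sum(contribs_i[shared] + contribs_j[shared]) / (dv_i + dv_j)
}

#' Disease semantic similarity matrix from a DAG corpus
#'
#' Computes shared-ancestor similarity under both contribution models (the
#' geometric decay model and the corpus-frequency model) and averages them.
#' The diagonal is exactly 1. Diseases requested but absent from the corpus
#' get similarity 0 to every other disease (and 1 to themselves); the fused
#' Gaussian-profile kernel supplies their signal downstream.
#'
#' @param corpus a [dag_corpus()].
#' @param delta decay factor for the first contribution model; default 0.5.
#' @param diseases identifiers for the output matrix; defaults to the corpus
#'   diseases. May include diseases without a DAG.
#' @return A [similarity_matrix()] over `diseases`.
#' @export
build_semantic_similarity <- function(corpus, delta = 0.5,
                                      diseases = corpus$diseases) {
  stopifnot(inherits(corpus, "dag_corpus"))
  have <- diseases[diseases %in% corpus$diseases]
  dd2 <- contribution_model2(corpus)
  c1 <- lapply(stats::setNames(have, have), contribution_model1,
               corpus = corpus, delta = delta)
  c2 <- lapply(stats::setNames(have, have),
               function(d) dd2[corpus$dags[[d]]$nodes])
  dv1 <- vapply(c1, semantic_value, numeric(1))
  dv2 <- vapply(c2, function(x) sum(x), numeric(1))
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (length(have) >= 2L) {
    for (a in seq_len(length(have) - 1L)) {
      for (b in seq((a + 1L), length(have))) {
        di <- have[a]; dj <- have[b]
        ss1 <- semantic_similarity_pair(corpus, di, dj, c1[[di]], c1[[dj]],
                                        dv1[di], dv1[dj])
        ss2 <- if (dv2[di] + dv2[dj] > 0) {
          semantic_similarity_pair(corpus, di, dj, c2[[di]], c2[[dj]],
                                   dv2[di], dv2[dj])
        } else {
          # all shared terms ubiquitous: frequency model carries no signal
          0
        }
        S[di, dj] <- S[dj, di] <- (ss1 + ss2) / 2
      }
    }
  }
  similarity_matrix(S, diseases, symmetrize = FALSE)
}
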