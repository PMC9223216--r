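#' Generate a synthetic miRNA-disease benchmark dataset
#'
#' Plants exactly the structure the prediction pipeline assumes: a low-rank
#' bipartite association pattern, similarity inputs consistent with the
#' planted latent factors, and sparse symmetric label noise (the outliers
#' the matrix-decomposition step is meant to suppress).
#'
#' Latent factors `U0` (nm x r) and `V0` (nd x r) are drawn i.i.d.
#' `|N(0,1)|`; the score matrix `U0 V0'` is thresholded at its
#' `1 - density` quantile to produce the clean positives. A fraction
#' `noise_rate` of the positives is flipped to 0 and the same count of
#' random zeros is flipped to 1. The functional similarity input is the
#' cosine similarity of the `U0` rows (non-negative factors, so already in
#' \[0, 1\]). The disease DAG corpus is a forest built by nearest-neighbor
#' linkage in `V0` space (each disease's parent is its nearest predecessor),
#' so tree distance tracks latent distance.
#'
#' @param nm,nd numbers of miRNAs and diseases; defaults 120 and 80.
#' @param rank planted latent dimension; default 5.
#' @param density fraction of pairs that are clean positives, in (0, 1);
#'   default 0.05.
#' @param noise_rate fraction of positives flipped (and matched zeros
#'   flipped in), in \[0, 1); default 0.1.
#' @param seed RNG seed; the whole object is a deterministic function of it.
#' @return An object of class `synthetic_dataset`: `dataset`
#'   ([association_dataset()]), `sm_functional` ([similarity_matrix()]),
#'   `dag_corpus` ([dag_corpus()]), ground truth `U0`, `V0`, `clean_A`,
#'   noise record (`flipped_out`, `flipped_in`) and `params`.
#' @export
generate_synthetic <- function(nm = 120L, nd = 80L, rank = 5L,
                               density = 0.05, noise_rate = 0.1, seed = 1L) {
  if (rank > min(nm, nd)) stop("rank must be <= min(nm, nd)")
  if (!(density > 0 && density < 1)) stop("density must be in (0, 1)")
  if (!(noise_rate >= 0 && noise_rate < 1)) stop("noise_rate must be in [0, 1)")
  set.seed(seed)
  mirna_ids <- sprintf("m%03d", seq_len(nm))
  disease_ids <- sprintf("d%03d", seq_len(nd))
  U0 <- abs(matrix(stats::rnorm(nm * rank), nm, rank))
  V0 <- abs(matrix(stats::rnorm(nd * rank), nd, rank))
  score <- tcrossprod(U0, V0)
  npos <- round(density * nm * nd)
  if (npos < 1) stop("density too low: no positives planted")
  thr <- stats::quantile(score, 1 - density, names = FALSE)
  A <- matrix(0, nm, nd, dimnames = list(mirna_ids, disease_ids))
  A[score >= thr] <- 1
  # quantile ties could over/under-shoot: keep exactly npos strongest pairs
  if (sum(A) != npos) {
    A[] <- 0
    A[order(-score)[seq_len(npos)]] <- 1
  }
  clean_A <- A
  flipped_out <- integer(0)
  flipped_in <- integer(0)
  nflip <- round(noise_rate * sum(clean_A))
  if (nflip > 0) {
    pos_idx <- which(clean_A == 1)
    zero_idx <- which(clean_A == 0)
    flipped_out <- sample(pos_idx, nflip)
    flipped_in <- sample(zero_idx, nflip)
    A[flipped_out] <- 0
    A[flipped_in] <- 1
  }
  dataset <- association_dataset(A, mirna_ids, disease_ids)
  # cosine similarity of planted miRNA factors
  nrm <- sqrt(rowSums(U0^2))
  C <- tcrossprod(U0 / nrm)
  C[C > 1] <- 1
  diag(C) <- 1
  sm_functional <- similarity_matrix(C, mirna_ids, symmetrize = TRUE)
  # nearest-predecessor forest over diseases in V0 space
  parent <- rep(NA_integer_, nd)
  if (nd >= 2L) {
    D2 <- as.matrix(stats::dist(V0))
    for (i in 2:nd) parent[i] <- which.min(D2[i, seq_len(i - 1L)])
  }
  dags <- lapply(seq_len(nd), function(i) {
    chain <- i
    while (!is.na(parent[chain[length(chain)]])) {
      chain <- c(chain, parent[chain[length(chain)]])
    }
    nodes <- disease_ids[chain]
    parents <- if (length(chain) > 1L) {
      stats::setNames(lapply(seq_len(length(chain) - 1L),
                             function(t) nodes[t + 1L]),
                      nodes[seq_len(length(chain) - 1L)])
    } else {
      stats::setNames(list(), character(0))
    }
    list(nodes = nodes, parents = parents)
  })
  names(dags) <- disease_ids
  corpus <- dag_corpus(dags, universe_size = nd)
  structure(list(dataset = dataset, sm_functional = sm_functional,
                 dag_corpus = corpus, U0 = U0, V0 = V0, clean_A = clean_A,
                 flipped_out = flipped_out, flipped_in = flipped_in,
                 params = list(nm = nm, nd = nd, rank = rank,
                               density = density, noise_rate = noise_rate,
                               seed = seed)),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf("synthetic_dataset: %d x %d, rank %d, density %.3f, noise %.2f, seed %d\n",
              p$nm, p$nd, p$rank, p$density, p$noise_rate, p$seed))
  invisible(x)
}

#' Hold out a fraction of the known associations
#'
#' Samples `fraction` of the observed positives, zeroes them in a training
#' copy of the association matrix, and returns both pieces. Train positives
#' and the held-out list partition the original positives.
#'
#' @param ds a `synthetic_dataset` or [association_dataset()].
#' @param fraction fraction of positives to hold out, in (0, 1).
#' @param seed RNG seed for the draw.
#' @return list with `train` ([association_dataset()]) and `heldout`
#'   (two-column index matrix of held-out positive entries).
#' @export
heldout_split <- function(ds, fraction, seed = 1L) {
  dataset <- if (inherits(ds, "synthetic_dataset")) ds$dataset else ds
  stopifnot(inherits(dataset, "association_dataset"))
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  nh <- round(fraction * nrow(pos))
  if (nh >= nrow(pos)) stop("fraction would remove all positives")
  if (nh < 1L) {
    return(list(train = dataset,
                heldout = pos[integer(0), , drop = FALSE]))
  }
  set.seed(seed)
  take <- sample(nrow(pos), nh)
  heldout <- pos[take, , drop = FALSE]
  list(train = .mask_positives(dataset, heldout), heldout = heldout)
}

#' Write all synthetic input files for a file-driven pipeline run
#'
#' Emits the association edge list, the functional similarity matrix, and
#' the DAG corpus (edges + roster) in the formats the loaders read.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_synthetic_inputs <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(associations = file.path(dir, "associations.tsv"),
             sm_functional = file.path(dir, "sm_functional.tsv"),
             dag_edges = file.path(dir, "dag_edges.tsv"),
             dag_roster = file.path(dir, "dag_roster.tsv"))
  save_association_edges(ds$dataset, paths[["associations"]])
  save_similarity_matrix(ds$sm_functional, paths[["sm_functional"]])
  save_dag_corpus(ds$dag_corpus, paths[["dag_edges"]], paths[["dag_roster"]])
  paths
}
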