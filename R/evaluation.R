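#' Rank-based AUC (Mann-Whitney statistic)
#'
#' Probability that a random positive outscores a random negative, with
#' ties counted one half: equivalent to the area under the ROC curve.
#'
#' @param scores numeric vector.
#' @param labels binary vector (1 = positive), same length.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  labels <- as.numeric(labels)
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) stop("need at least one positive and one negative")
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' ROC curve points
#'
#' @inheritParams auc_rank
#' @return data.frame with columns `fpr`, `tpr`, one row per threshold.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.numeric(labels)
  ord <- order(-scores)
  tp <- cumsum(labels[ord] == 1)
  fp <- cumsum(labels[ord] == 0)
  data.frame(fpr = c(0, fp / max(1, sum(labels == 0))),
             tpr = c(0, tp / max(1, sum(labels == 1))))
}

.cv_result <- function(protocol, aucs, folds = NULL, roc = NULL, seed = NULL) {
  structure(list(protocol = protocol, aucs = aucs, mean = mean(aucs),
                 sd = stats::sd(aucs), folds = folds, roc = roc, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: mean AUC %.4f (sd %.4f, n=%d)\n",
              x$protocol, x$mean, if (is.na(x$sd)) 0 else x$sd, length(x$aucs)))
  invisible(x)
}

# zero the given positive entries (matrix of (row, col) indices) in a copy
.mask_positives <- function(dataset, idx) {
  A <- dataset$A
  A[idx] <- 0
  association_dataset(A, dataset$mirna_ids, dataset$disease_ids)
}

#' Fivefold cross-validation over known associations
#'
#' Per repeat, the known pairs are randomly split into five folds. For each
#' fold the test positives are zeroed in the training matrix and the full
#' model is refit on the masked matrix (Gaussian-profile kernels, kernel
#' fusion, matrix decomposition and factorization are all recomputed, so no
#' test information leaks through the kernels). The fold's test positives
#' are then ranked against the common candidate set -- all pairs unknown in
#' the full matrix -- and the fold AUCs are averaged into one AUC per
#' repeat.
#'
#' @param dataset an [association_dataset()].
#' @param sm_functional miRNA functional [similarity_matrix()]
#'   (fold-independent input).
#' @param sd_semantic disease semantic [similarity_matrix()]
#'   (fold-independent input).
#' @param config a [pipeline_config()]; controls every model stage.
#' @param repeats number of repeated random segmentations; default 5 (use
#'   100 to match the reference protocol; tests use fewer for speed).
#' @param seed RNG seed for the fold assignments.
#' @param scorer function `(train_dataset, sm_functional, sd_semantic,
#'   config) -> score_matrix`; defaults to the full pipeline
#'   [predict_associations()]. Injectable for harness tests.
#' @return A `cv_result` with one AUC per repeat and the pooled ROC points
#'   of the first repeat.
#' @export
five_fold_cv <- function(dataset, sm_functional, sd_semantic,
                         config = pipeline_config(), repeats = 5L, seed = 1L,
                         scorer = predict_associations) {
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  if (nrow(pos) < 5L) stop("need at least 5 known associations for fivefold CV")
  cand <- dataset$A == 0
  set.seed(seed)
  aucs <- numeric(repeats)
  fold_record <- vector("list", repeats)
  roc <- NULL
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep(seq_len(5L), length.out = nrow(pos)))
    fold_record[[rep_i]] <- fold
    fold_aucs <- numeric(5L)
    pool_scores <- NULL; pool_labels <- NULL
    for (f in seq_len(5L)) {
      test_idx <- pos[fold == f, , drop = FALSE]
      train <- .mask_positives(dataset, test_idx)
      sc <- scorer(train, sm_functional, sd_semantic, config)
      scores <- .score_mat(sc)
      s <- c(scores[test_idx], scores[cand])
      l <- c(rep(1, nrow(test_idx)), rep(0, sum(cand)))
      fold_aucs[f] <- auc_rank(s, l)
      if (rep_i == 1L) {
        pool_scores <- c(pool_scores, s)
        pool_labels <- c(pool_labels, l)
      }
    }
    aucs[rep_i] <- mean(fold_aucs)
    if (rep_i == 1L) roc <- roc_points(pool_scores, pool_labels)
  }
  .cv_result("5cv", aucs, folds = fold_record, roc = roc, seed = seed)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is held out in turn, the model is refit on the
#' remaining associations, and the held-out pair is ranked against all
#' unknown pairs of the full matrix. The reported AUC is the average, over
#' held-out pairs, of the probability that the pair outranks a random
#' candidate (ties one half) -- the Mann-Whitney form of the pooled ROC.
#'
#' @inheritParams five_fold_cv
#' @return A `cv_result` with a single pooled AUC (`aucs` holds the
#'   per-pair win probabilities).
#' @export
global_loocv <- function(dataset, sm_functional, sd_semantic,
                         config = pipeline_config(),
                         scorer = predict_associations) {
  pos <- which(dataset$A == 1, arr.ind = TRUE)
  if (nrow(pos) < 2L) stop("need at least 2 known associations")
  cand <- dataset$A == 0
  ncand <- sum(cand)
  if (ncand == 0L) stop("no candidate (unknown) pairs")
  pp <- numeric(nrow(pos))
  for (t in seq_len(nrow(pos))) {
    test_idx <- pos[t, , drop = FALSE]
    train <- .mask_positives(dataset, test_idx)
    scores <- .score_mat(scorer(train, sm_functional, sd_semantic, config))
    s_pos <- scores[test_idx]
    s_cand <- scores[cand]
    pp[t] <- (sum(s_cand < s_pos) + 0.5 * sum(s_cand == s_pos)) / ncand
  }
  res <- .cv_result("global-loocv", pp)
  res$mean <- mean(pp)
  res
}

#' Local (per-disease) leave-one-out cross-validation
#'
#' For each evaluated disease, all of that disease's known associations are
#' zeroed, the model is refit, and the held-out positives are ranked
#' against the disease's own unknown miRNAs only. Diseases without any
#' positive, or without any negative, are skipped with a warning. The
#' reported AUC is the mean of the per-disease AUCs.
#'
#' @inheritParams five_fold_cv
#' @param diseases disease identifiers to evaluate; default all.
#' @return A `cv_result` with one AUC per evaluated disease.
#' @export
local_loocv <- function(dataset, sm_functional, sd_semantic,
                        config = pipeline_config(), diseases = NULL,
                        scorer = predict_associations) {
  if (is.null(diseases)) diseases <- dataset$disease_ids
  aucs <- c()
  kept <- c()
  for (d in diseases) {
    j <- match(d, dataset$disease_ids)
    if (is.na(j)) stop("unknown disease id: ", d)
    posm <- which(dataset$A[, j] == 1)
    if (length(posm) == 0L) {
      warning("disease ", d, " has no known associations; skipped")
      next
    }
    if (length(posm) == length(dataset$mirna_ids)) {
      warning("disease ", d, " has no unknown miRNAs; skipped")
      next
    }
    test_idx <- cbind(posm, j)
    train <- .mask_positives(dataset, test_idx)
    scores <- .score_mat(scorer(train, sm_functional, sd_semantic, config))
    col <- scores[, j]
    lab <- as.numeric(dataset$A[, j] == 1)
    aucs <- c(aucs, auc_rank(col, lab))
    kept <- c(kept, d)
  }
  if (length(aucs) == 0L) stop("no evaluable disease")
  res <- .cv_result("local-loocv", stats::setNames(aucs, kept))
  res
}
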