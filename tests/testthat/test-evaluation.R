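test_that("rank AUC handles perfect, inverted and tied rankings", {
  expect_equal(auc_rank(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc_rank(c(0.1, 0.9), c(1, 0)), 0)
  expect_equal(auc_rank(c(0.5, 0.5, 0.2), c(1, 0, 0)), 0.75)
  expect_error(auc_rank(c(1, 2), c(1, 1)), "positive and")
})

test_that("rank AUC equals the brute-force pair-counting oracle", {
  set.seed(51)
  for (case in 1:100) {
    n <- sample(5:40, 1)
    scores <- sample(round(runif(n), 2))  # coarse grid to force ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0) labels[1] <- 1
    if (sum(labels) == n) labels[n] <- 0
    expect_equal(auc_rank(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("rank AUC is invariant under strictly monotone score transforms", {
  set.seed(52)
  scores <- runif(30); labels <- rbinom(30, 1, 0.5)
  labels[1] <- 1; labels[2] <- 0
  a0 <- auc_rank(scores, labels)
  expect_equal(auc_rank(exp(3 * scores), labels), a0)
  expect_equal(auc_rank(rank(scores), labels), a0)
})

test_that("fivefold folds are a true partition and runs are reproducible", {
  ds <- generate_synthetic(nm = 25, nd = 15, rank = 3, density = 0.12,
                           noise_rate = 0, seed = 6)$dataset
  sm <- similarity_matrix(diag(25), ds$mirna_ids)
  sd <- similarity_matrix(diag(15), ds$disease_ids)
  truth <- ds$A
  r1 <- five_fold_cv(ds, sm, sd, repeats = 2, seed = 99,
                     scorer = oracle_scorer(truth))
  r2 <- five_fold_cv(ds, sm, sd, repeats = 2, seed = 99,
                     scorer = oracle_scorer(truth))
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$aucs, r2$aucs)
  npos <- sum(ds$A)
  for (f in r1$folds) {
    expect_length(f, npos)
    expect_setequal(unique(f), 1:5)
  }
})

test_that("an oracle scorer achieves AUC 1 in every protocol", {
  ds <- generate_synthetic(nm = 20, nd = 12, rank = 3, density = 0.15,
                           noise_rate = 0, seed = 8)$dataset
  sm <- similarity_matrix(diag(20), ds$mirna_ids)
  sd <- similarity_matrix(diag(12), ds$disease_ids)
  sc <- oracle_scorer(ds$A)
  expect_equal(five_fold_cv(ds, sm, sd, repeats = 1, seed = 1, scorer = sc)$mean, 1)
  expect_equal(global_loocv(ds, sm, sd, scorer = sc)$mean, 1)
  loc <- suppressWarnings(local_loocv(ds, sm, sd, scorer = sc))
  expect_true(all(loc$aucs == 1))
})

test_that("global LOOCV refits once per positive", {
  A <- matrix(0, 4, 3, dimnames = list(paste0("m", 1:4), paste0("d", 1:3)))
  A[cbind(c(1, 2, 3, 4, 1), c(1, 2, 3, 1, 2))] <- 1
  ds <- association_dataset(A)
  calls <- 0
  counting <- function(train, sm, sd, config) {
    calls <<- calls + 1
    score_matrix(matrix(runif(12), 4, 3), ds$mirna_ids, ds$disease_ids)
  }
  set.seed(1)
  global_loocv(ds, NULL, NULL, scorer = counting)
  expect_equal(calls, sum(A))
})

test_that("local LOOCV skips degenerate diseases with a warning", {
  A <- cbind(d1 = c(1, 1, 1), d2 = c(1, 0, 0), d3 = c(0, 0, 0))
  rownames(A) <- paste0("m", 1:3)
  ds <- association_dataset(A)
  sc <- oracle_scorer(A)
  warns <- capture_warnings(res <- local_loocv(ds, NULL, NULL, scorer = sc))
  # d1 all positive (no negatives) and d3 no positives are both skipped
  expect_length(warns, 2)
  expect_match(warns, "skipped", all = TRUE)
  expect_equal(names(res$aucs), "d2")
})

test_that("kernels inside CV are recomputed from masked training data only", {
  ds <- generate_synthetic(nm = 15, nd = 10, rank = 2, density = 0.2,
                           noise_rate = 0, seed = 10)$dataset
  seen <- list()
  spy <- function(train, sm, sd, config) {
    seen[[length(seen) + 1]] <<- train$A
    score_matrix(matrix(0, 15, 10), ds$mirna_ids, ds$disease_ids)
  }
  res <- tryCatch(five_fold_cv(ds, NULL, NULL, repeats = 1, seed = 3,
                               scorer = spy),
                  error = function(e) NULL)  # AUC on all-zero scores is fine (all ties)
  pos <- which(ds$A == 1, arr.ind = TRUE)
  fold <- NULL
  # each training matrix must equal the full matrix minus its fold positives
  expect_length(seen, 5)
  masked_total <- Reduce(`+`, lapply(seen, function(tr) sum(ds$A) - sum(tr)))
  expect_equal(masked_total, nrow(pos))
  for (tr in seen) {
    expect_true(all(tr <= ds$A))      # only removals, never additions
    changed <- which(ds$A == 1 & tr == 0)
    expect_true(length(changed) >= 1)
    # zeroing a test entry changes the corresponding GIP profile
    i <- arrayInd(changed[1], dim(ds$A))
    km_full <- gip_kernel(ds$A)
    km_train <- gip_kernel(tr)
    expect_false(isTRUE(all.equal(km_full$S[i[1], ], km_train$S[i[1], ])))
  }
})

test_that("fivefold on a planted dataset with the real pipeline beats 0.85", {
  ds <- generate_synthetic(nm = 40, nd = 25, rank = 3, density = 0.1,
                           noise_rate = 0.05, seed = 20)
  sd1 <- build_semantic_similarity(ds$dag_corpus,
                                   diseases = ds$dataset$disease_ids)
  res <- five_fold_cv(ds$dataset, ds$sm_functional, sd1,
                      config = tiny_config(), repeats = 2, seed = 20)
  expect_gt(res$mean, 0.85)
  expect_equal(res$mean, mean(res$aucs))
})

test_that("global LOOCV agrees with n-fold pooling on a tiny instance", {
  # with one positive per fold and a deterministic scorer, fivefold with
  # folds = n reduces to global LOOCV under the shared candidate convention
  A <- matrix(0, 5, 4, dimnames = list(paste0("m", 1:5), paste0("d", 1:4)))
  A[cbind(1:5, c(1, 2, 3, 4, 1))] <- 1
  ds <- association_dataset(A)
  det_scorer <- function(train, sm, sd, config) {
    # deterministic function of the training matrix
    score_matrix(train$A * 2 + outer(rowSums(train$A), colSums(train$A)) / 10,
                 ds$mirna_ids, ds$disease_ids)
  }
  glo <- global_loocv(ds, NULL, NULL, scorer = det_scorer)
  # manual per-positive ranking cross-check of the first held-out pair
  pos <- which(A == 1, arr.ind = TRUE)
  tr1 <- ds$A; tr1[pos[1, , drop = FALSE]] <- 0
  sc1 <- det_scorer(association_dataset(tr1), NULL, NULL, NULL)$scores
  cand <- ds$A == 0
  manual <- (sum(sc1[cand] < sc1[pos[1, , drop = FALSE]]) +
             0.5 * sum(sc1[cand] == sc1[pos[1, , drop = FALSE]])) / sum(cand)
  expect_equal(glo$aucs[1], manual)
  expect_equal(glo$mean, mean(glo$aucs))
})

test_that("roc points start at the origin and end at (1, 1)", {
  set.seed(53)
  sc <- runif(20); lb <- rbinom(20, 1, 0.5); lb[1] <- 1; lb[2] <- 0
  roc <- roc_points(sc, lb)
  expect_equal(as.numeric(roc[1, ]), c(0, 0))
  expect_equal(as.numeric(roc[nrow(roc), ]), c(1, 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})
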