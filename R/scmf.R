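#' Objective of the similarity-constrained matrix factorization
#'
#' `L = 1/2 sum_ij (a*_ij - u_i v_j')^2 + theta/2 (||U||_F^2 + ||V||_F^2)
#'    + sigma/2 sum_ij ||u_i - u_j||^2 SM_ij
#'    + sigma/2 sum_ij ||v_i - v_j||^2 SD_ij`
#'
#' The data term fits the (denoised) association matrix, the L2 terms guard
#' against overfitting, and the graph terms pull latent rows of similar
#' miRNAs (diseases) together.
#'
#' @param U nm x rank latent miRNA factors (rows `u_i`).
#' @param V nd x rank latent disease factors (rows `v_j`).
#' @param A_star a [score_matrix()] or plain matrix (nm x nd).
#' @param SM,SD miRNA / disease [similarity_matrix()] (or plain matrices).
#' @param theta L2 regularization weight, `>= 0`.
#' @param sigma similarity-constraint weight, `>= 0`.
#' @return scalar objective value.
#' @export
scmf_objective <- function(U, V, A_star, SM, SD, theta, sigma) {
  As <- .score_mat(A_star)
  SMm <- .sim_mat(SM); SDm <- .sim_mat(SD)
  if (nrow(U) != nrow(As) || nrow(V) != ncol(As) || ncol(U) != ncol(V)) {
    stop("shape mismatch among U, V and A_star")
  }
  if (nrow(SMm) != nrow(U) || nrow(SDm) != nrow(V)) {
    stop("shape mismatch between similarity matrices and factors")
  }
  fit <- 0.5 * sum((As - tcrossprod(U, V))^2)
  l2 <- 0.5 * theta * (sum(U^2) + sum(V^2))
  graph <- 0.5 * sigma * (.pairwise_penalty(U, SMm) + .pairwise_penalty(V, SDm))
  fit + l2 + graph
}

.score_mat <- function(x) if (inherits(x, "score_matrix")) x$scores else as.matrix(x)

# sum_ij ||z_i - z_j||^2 G_ij without forming the n^2 x rank expansion
.pairwise_penalty <- function(Z, G) {
  sq <- rowSums(Z^2)
  sum((rowSums(G) + colSums(G)) * sq) - 2 * sum(Z * (G %*% Z))
}

#' Exact coordinate update for one miRNA latent row
#'
#' Minimizes the objective with respect to `u_i`, all other rows fixed: a
#' rank x rank linear solve
#' `u_i = (A*(i,) V + sigma * w' U) (V'V + theta I + sigma * c_i I)^-1`
#' where `w_j = SM_ij + SM_ji` for `j != i` (the self term drops out of the
#' penalty identically) and `c_i = sum(w)`. With `theta > 0` the system is
#' strictly positive definite.
#'
#' @param i row index to update.
#' @inheritParams scmf_objective
#' @return the updated rank-vector `u_i`.
#' @export
update_row_u <- function(i, U, V, A_star, SM, theta, sigma) {
  As <- .score_mat(A_star)
  SMm <- .sim_mat(SM)
  .row_update(i, U, V, As, SMm, theta, sigma, byrow = TRUE)
}

#' Exact coordinate update for one disease latent row
#'
#' Mirror of [update_row_u()] for `v_j`, using the columns of `A*` and the
#' disease similarity `SD`.
#'
#' @param j row index of `V` to update.
#' @inheritParams scmf_objective
#' @return the updated rank-vector `v_j`.
#' @export
update_row_v <- function(j, U, V, A_star, SD, theta, sigma) {
  As <- .score_mat(A_star)
  SDm <- .sim_mat(SD)
  .row_update(j, V, U, As, SDm, theta, sigma, byrow = FALSE)
}

# shared row solver: when byrow, Z = U and W = V and target = A*[i, ];
# otherwise Z = V, W = U, target = A*[, j]
.row_update <- function(i, Z, W, As, G, theta, sigma, byrow) {
  r <- ncol(W)
  w <- G[i, ] + G[, i]
  w[i] <- 0
  ci <- sum(w)
  M <- crossprod(W) + diag(theta + sigma * ci, r)
  target <- if (byrow) As[i, ] else As[, i]
  rhs <- as.numeric(target %*% W) + sigma * as.numeric(w %*% Z)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    stop(sprintf("singular %s-update system at row %d (set theta > 0)",
                 if (byrow) "u" else "v", i))
  })
  as.numeric(sol)
}

#' Fit the similarity-constrained matrix factorization
#'
#' Alternates exact per-row Newton (coordinate) updates: one sweep updates
#' all miRNA rows `u_i` in ascending order (Gauss-Seidel, each row seeing
#' already-updated predecessors), then all disease rows `v_j`. Every update
#' is the exact minimizer of a strictly convex quadratic, so the recorded
#' objective trace is non-increasing. Stops when the relative objective
#' change falls below `tol` or after `max_sweeps` sweeps.
#'
#' @inheritParams scmf_objective
#' @param rank latent dimension, `1 <= rank <= min(nm, nd)`; default 50
#'   (capped at `min(nm, nd)`).
#' @param theta L2 weight; default 4 (best value on the reference
#'   hyperparameter grid).
#' @param sigma similarity-constraint weight; default 1.
#' @param max_sweeps sweep cap; default 200.
#' @param tol relative objective-change tolerance; default 1e-6.
#' @param init `"svd"` (deterministic truncated-SVD start,
#'   `U = U_r sqrt(S_r)`, `V = V_r sqrt(S_r)`) or `"random"` (seeded
#'   `0.01 * U(0,1)` entries).
#' @param seed RNG seed for `init = "random"`.
#' @return An object of class `scmf_model` with fields `U`, `V`,
#'   `objective` (per-sweep trace, starting with the initial value),
#'   `sweeps`, `converged`, and the hyperparameters.
#' @export
fit_scmf <- function(A_star, SM, SD, rank = 50L, theta = 4, sigma = 1,
                     max_sweeps = 200L, tol = 1e-6,
                     init = c("svd", "random"), seed = 1L) {
  init <- match.arg(init)
  As <- .score_mat(A_star)
  SMm <- .sim_mat(SM); SDm <- .sim_mat(SD)
  nm <- nrow(As); nd <- ncol(As)
  if (nrow(SMm) != nm) stop("SM must be nm x nm")
  if (nrow(SDm) != nd) stop("SD must be nd x nd")
  if (theta < 0 || sigma < 0) stop("theta and sigma must be >= 0")
  rank <- as.integer(min(rank, nm, nd))
  if (rank < 1L) stop("rank must be >= 1")
  if (init == "svd") {
    sv <- svd(As, nu = rank, nv = rank)
    sc <- sqrt(sv$d[seq_len(rank)])
    U <- sv$u * rep(sc, each = nm)
    V <- sv$v * rep(sc, each = nd)
  } else {
    set.seed(seed)
    U <- matrix(stats::runif(nm * rank), nm, rank) * 0.01
    V <- matrix(stats::runif(nd * rank), nd, rank) * 0.01
  }
  # precompute symmetric-pair weights and their row sums; diagonal excluded
  # because the self term cancels identically in the penalty
  WM <- SMm + t(SMm); diag(WM) <- 0
  WD <- SDm + t(SDm); diag(WD) <- 0
  cm <- rowSums(WM)
  cd <- rowSums(WD)
  obj <- scmf_objective(U, V, As, SMm, SDm, theta, sigma)
  trace <- obj
  converged <- FALSE
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    # U phase: V fixed, so V'V is fixed; eigendecompose once and solve each
    # row's (V'V + (theta + sigma c_i) I) system in the eigenbasis
    eV <- eigen(crossprod(V), symmetric = TRUE)
    for (i in seq_len(nm)) {
      rhs <- as.numeric(As[i, ] %*% V) + sigma * as.numeric(WM[i, ] %*% U)
      y <- crossprod(eV$vectors, rhs) / (eV$values + theta + sigma * cm[i])
      U[i, ] <- as.numeric(eV$vectors %*% y)
    }
    eU <- eigen(crossprod(U), symmetric = TRUE)
    for (j in seq_len(nd)) {
      rhs <- as.numeric(As[, j] %*% U) + sigma * as.numeric(WD[j, ] %*% V)
      y <- crossprod(eU$vectors, rhs) / (eU$values + theta + sigma * cd[j])
      V[j, ] <- as.numeric(eU$vectors %*% y)
    }
    newobj <- scmf_objective(U, V, As, SMm, SDm, theta, sigma)
    trace <- c(trace, newobj)
    if (abs(obj - newobj) / max(abs(obj), 1) < tol) {
      obj <- newobj
      converged <- TRUE
      break
    }
    obj <- newobj
  }
  structure(list(U = U, V = V, objective = trace, sweeps = sweeps,
                 converged = converged, rank = rank, theta = theta,
                 sigma = sigma, init = init, seed = seed,
                 mirna_ids = rownames(As), disease_ids = colnames(As)),
            class = "scmf_model")
}

#' @export
print.scmf_model <- function(x, ...) {
  cat(sprintf("scmf_model: rank %d, theta=%g, sigma=%g, %d sweeps, objective %.6g\n",
              x$rank, x$theta, x$sigma, x$sweeps,
              x$objective[length(x$objective)]))
  invisible(x)
}

#' Predicted association scores from a fitted factorization
#'
#' `A' = U V'`; higher scores mean stronger predicted association.
#'
#' @param model an [fit_scmf()] model.
#' @return A [score_matrix()].
#' @export
predict_scores <- function(model) {
  stopifnot(inherits(model, "scmf_model"))
  P <- tcrossprod(model$U, model$V)
  score_matrix(P,
               mirna_ids = model$mirna_ids %||% paste0("m", seq_len(nrow(P))),
               disease_ids = model$disease_ids %||% paste0("d", seq_len(ncol(P))))
}

#' Dump a fitted model as labeled TSV factors plus a JSON sidecar
#'
#' @param model an [fit_scmf()] model.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
save_scmf_model <- function(model, dir) {
  stopifnot(inherits(model, "scmf_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  U <- model$U; V <- model$V
  rownames(U) <- model$mirna_ids %||% paste0("m", seq_len(nrow(U)))
  colnames(U) <- paste0("f", seq_len(ncol(U)))
  rownames(V) <- model$disease_ids %||% paste0("d", seq_len(nrow(V)))
  colnames(V) <- paste0("f", seq_len(ncol(V)))
  .write_labeled_matrix(U, file.path(dir, "U.tsv"))
  .write_labeled_matrix(V, file.path(dir, "V.tsv"))
  meta <- list(rank = model$rank, theta = model$theta, sigma = model$sigma,
               init = model$init, seed = model$seed, sweeps = model$sweeps,
               converged = model$converged, objective = model$objective)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
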