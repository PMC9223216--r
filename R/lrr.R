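#' Singular value thresholding
#'
#' Proximal operator of the nuclear norm: SVD the input, shrink every
#' singular value by `threshold` (floored at 0), and reconstruct. Solves
#' `argmin_J threshold * ||J||_* + 1/2 ||J - M||_F^2`.
#'
#' @param M numeric matrix with finite entries.
#' @param threshold shrinkage level, `>= 0`.
#' @return matrix of the same shape.
#' @export
svt <- function(M, threshold) {
  M <- as.matrix(M)
  if (!all(is.finite(M))) stop("svt: non-finite input")
  if (threshold < 0) stop("svt: threshold must be >= 0")
  if (threshold == 0) return(M)
  sv <- svd(M)
  d <- pmax(sv$d - threshold, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  sv$u[, keep, drop = FALSE] %*% (d[keep] * t(sv$v[, keep, drop = FALSE]))
}

#' Column-wise L2,1 shrinkage
#'
#' Proximal operator of the L2,1 norm (sum of column Euclidean norms): a
#' column with norm below `threshold` is zeroed, otherwise scaled by
#' `(norm - threshold) / norm`. Solves
#' `argmin_X threshold * ||X||_{2,1} + 1/2 ||X - M||_F^2`.
#'
#' @inheritParams svt
#' @return matrix of the same shape.
#' @export
l21_shrink <- function(M, threshold) {
  M <- as.matrix(M)
  if (threshold < 0) stop("l21_shrink: threshold must be >= 0")
  if (threshold == 0) return(M)
  nrm <- sqrt(colSums(M^2))
  scale <- ifelse(nrm > threshold, (nrm - threshold) / nrm, 0)
  sweep(M, 2L, scale, "*")
}

#' L2,1 norm (sum of column Euclidean norms)
#' @param M numeric matrix.
#' @return scalar.
#' @export
l21_norm <- function(M) sum(sqrt(colSums(as.matrix(M)^2)))

#' Nuclear norm (sum of singular values)
#' @param M numeric matrix.
#' @return scalar.
#' @export
nuclear_norm <- function(M) sum(svd(as.matrix(M))$d)

#' Low-rank self-expression decomposition by inexact ALM
#'
#' Solves `min ||Y||_* + phi * ||X||_{2,1}  s.t.  A = A Y + X` with the
#' inexact augmented Lagrange multiplier method. `Y` (diseases x diseases)
#' is a low-rank self-expression of the association matrix's columns and
#' `X` collects sparse columnwise outliers; `A Y` is the denoised
#' association matrix.
#'
#' Each iteration updates, in order: `J` by singular value thresholding at
#' `1/alpha` of `Y + F2/alpha`; `Y` by the closed-form normal equation
#' `(I + A'A)^-1 (A'A - A'X + J + (A'F1 - F2)/alpha)` (the factorization of
#' `I + A'A` is computed once); `X` by L2,1 shrinkage at `phi/alpha` of
#' `A - A Y + F1/alpha`; the multipliers `F1`, `F2`; and the penalty
#' `alpha <- min(growth * alpha, alpha_max)`.
#'
#' @param A binary association matrix (miRNAs x diseases).
#' @param phi trade-off between the nuclear and L2,1 terms; default 1.
#' @param alpha0 initial penalty; default 1e-4.
#' @param alpha_max penalty cap; default 1e10.
#' @param growth multiplicative penalty growth factor; default 1.1.
#' @param eps convergence tolerance on both infinity-norm residuals
#'   `||A - AY - X||_inf` and `||Y - J||_inf`; default 1e-8.
#' @param max_iters safety cap; default 500. Non-convergence returns the
#'   current iterate with `converged = FALSE` and a warning.
#' @return An object of class `lrr_result` with fields `Y`, `X`, `J`, `F1`,
#'   `F2`, `iterations`, `r1`, `r2`, `converged`, `residual_trace`.
#' @export
ialm_lrr <- function(A, phi = 1, alpha0 = 1e-4, alpha_max = 1e10,
                     growth = 1.1, eps = 1e-8, max_iters = 500L) {
  A <- as.matrix(A)
  if (nrow(A) < 1L || ncol(A) < 1L) stop("A must be non-empty")
  if (phi <= 0) stop("phi must be positive")
  if (alpha0 <= 0 || growth <= 1 || eps <= 0) stop("invalid IALM parameters")
  nm <- nrow(A); nd <- ncol(A)
  AtA <- crossprod(A)
  # factor (I + A'A) once; it is SPD so use Cholesky
  R <- chol(diag(nd) + AtA)
  solve_sys <- function(B) backsolve(R, backsolve(R, B, transpose = TRUE))
  Y <- matrix(0, nd, nd)
  X <- matrix(0, nm, nd)
  J <- matrix(0, nd, nd)
  F1 <- matrix(0, nm, nd)
  F2 <- matrix(0, nd, nd)
  alpha <- alpha0
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  r1 <- r2 <- Inf
  while (iter < max_iters) {
    iter <- iter + 1L
    J <- svt(Y + F2 / alpha, 1 / alpha)
    Y <- solve_sys(AtA - crossprod(A, X) + J + (crossprod(A, F1) - F2) / alpha)
    AY <- A %*% Y
    X <- l21_shrink(A - AY + F1 / alpha, phi / alpha)
    R1 <- A - AY - X
    R2 <- Y - J
    F1 <- F1 + alpha * R1
    F2 <- F2 + alpha * R2
    alpha <- min(growth * alpha, alpha_max)
    r1 <- max(abs(R1))
    r2 <- max(abs(R2))
    trace <- c(trace, r1)
    if (r1 < eps && r2 < eps) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf("IALM did not converge in %d iterations (r1=%.3g, r2=%.3g)",
                    max_iters, r1, r2))
  }
  structure(list(Y = Y, X = X, J = J, F1 = F1, F2 = F2, iterations = iter,
                 r1 = r1, r2 = r2, converged = converged,
                 residual_trace = trace, phi = phi),
            class = "lrr_result")
}

#' @export
print.lrr_result <- function(x, ...) {
  cat(sprintf("lrr_result: %d iterations, r1=%.3g, r2=%.3g, converged=%s\n",
              x$iterations, x$r1, x$r2, x$converged))
  invisible(x)
}

#' Denoised association matrix from a decomposition
#'
#' `A* = A Y`: the low-rank self-expression reconstruction of the
#' association matrix, with the outlier part removed.
#'
#' @param dataset an [association_dataset()] (or plain binary matrix).
#' @param result an [ialm_lrr()] result computed on the same matrix.
#' @return A [score_matrix()] holding `A*`.
#' @export
reconstruct <- function(dataset, result) {
  stopifnot(inherits(result, "lrr_result"))
  A <- if (inherits(dataset, "association_dataset")) dataset$A else as.matrix(dataset)
  if (ncol(A) != nrow(result$Y)) stop("shape mismatch between A and Y")
  As <- A %*% result$Y
  score_matrix(As,
               mirna_ids = rownames(A) %||% paste0("m", seq_len(nrow(A))),
               disease_ids = colnames(A) %||% paste0("d", seq_len(ncol(A))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
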