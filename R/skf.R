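#' Column-normalize a similarity kernel
#'
#' `F(i, j) = S(i, j) / sum_k S(k, j)`; every column of the result sums to 1.
#'
#' @param S a [similarity_matrix()] or plain square matrix.
#' @return plain matrix with unit column sums.
#' @export
normalize_kernel <- function(S) {
  M <- .sim_mat(S)
  cs <- colSums(M)
  if (any(cs <= 0)) stop("zero column in kernel: cannot normalize")
  sweep(M, 2L, cs, "/")
}

.sim_mat <- function(S) {
  if (inherits(S, "similarity_matrix")) S$S else as.matrix(S)
}

# top-k neighbor index sets: i itself plus the k-1 largest entries of
# S[i, ] among the others, ties broken by ascending index
.neighbor_sets <- function(M, k) {
  n <- nrow(M)
  if (k < 1 || k > n) stop("k must be in 1..n")
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-M[i, others], others)]
    sort(c(i, ord[seq_len(k - 1L)]))
  })
}

#' Neighbor-restricted row-stochastic kernel
#'
#' Keeps, per row `i`, only the `k` strongest neighbors `N_i` (always
#' including `i` itself; ties by ascending index) and renormalizes the row
#' over that support, so each row sums to 1.
#'
#' @param S a [similarity_matrix()] or plain square matrix.
#' @param k neighborhood size, `1 <= k <= n`.
#' @return plain matrix, row-stochastic on its support.
#' @export
neighbor_kernel <- function(S, k) {
  M <- .sim_mat(S)
  nb <- .neighbor_sets(M, k)
  out <- matrix(0, nrow(M), ncol(M), dimnames = dimnames(M))
  for (i in seq_len(nrow(M))) {
    mass <- sum(M[i, nb[[i]]])
    if (mass <= 0) stop("all-zero neighbor mass in row ", i)
    out[i, nb[[i]]] <- M[i, nb[[i]]] / mass
  }
  out
}

#' Neighbor-agreement weight mask
#'
#' `W(i, j)` is 1 when `i` and `j` are mutual neighbors, 0 when neither is
#' in the other's neighbor set, and 0.5 otherwise. The diagonal is 1 and `W`
#' is symmetric; it is used to damp unreliable entries of the fused kernel.
#'
#' @inheritParams neighbor_kernel
#' @return plain matrix with entries in \{0, 0.5, 1\}.
#' @export
weight_matrix <- function(S, k) {
  M <- .sim_mat(S)
  n <- nrow(M)
  nb <- .neighbor_sets(M, k)
  inN <- matrix(FALSE, n, n)  # inN[i, j] <=> j in N_i
  for (i in seq_len(n)) inN[i, nb[[i]]] <- TRUE
  W <- matrix(0.5, n, n, dimnames = dimnames(M))
  W[inN & t(inN)] <- 1
  W[!inN & !t(inN)] <- 0
  W
}

#' Cross-diffuse two similarity kernels
#'
#' Iterates each kernel through its neighbor-restricted kernel while mixing
#' in the other kernel's current and initial normalized forms:
#' `F_n^(l+1) = tau * S_n (F_t^l / divisor) t(S_n) + (1 - tau) * F_t^0 / divisor`
#' (`t` the other kernel), re-symmetrizing after every update, until the
#' largest absolute change drops below `tol` or `max_iters` is reached. The
#' overall kernel is the average `(F_1 + F_2) / 2` of the final iterates.
#'
#' @param kernels list of exactly two [similarity_matrix()] objects over the
#'   same identifiers.
#' @param k_neighbors neighborhood size; default `max(3, round(n / 10))`.
#' @param tau diffusion weight in (0, 1); default 0.5.
#' @param max_iters maximum diffusion iterations; default 20.
#' @param tol convergence tolerance on the max-abs iterate change; default 1e-6.
#' @param divisor_mode `"literal-2"` (divide the cross terms by 2, as
#'   printed in the formulation this package follows) or `"n-minus-1"` (the
#'   usual cross-diffusion normalization; identical here since only one
#'   other kernel exists... it divides by 1).
#' @return list of class `fusion_state`: `F0` (initial normalized kernels),
#'   `Sn` (neighbor kernels), `F` (final iterates), `SMstar` (overall
#'   kernel), `iterations`, `delta` (last max-abs change), `ids`.
#' @export
fuse_kernels <- function(kernels, k_neighbors = NULL, tau = 0.5,
                         max_iters = 20L, tol = 1e-6,
                         divisor_mode = c("literal-2", "n-minus-1")) {
  divisor_mode <- match.arg(divisor_mode)
  if (length(kernels) != 2L) stop("exactly two kernels are fused")
  M1 <- .sim_mat(kernels[[1L]]); M2 <- .sim_mat(kernels[[2L]])
  if (!all(dim(M1) == dim(M2))) stop("kernel shape mismatch")
  ids <- rownames(M1)
  if (inherits(kernels[[1L]], "similarity_matrix") &&
      inherits(kernels[[2L]], "similarity_matrix") &&
      !identical(kernels[[1L]]$ids, kernels[[2L]]$ids)) {
    stop("kernel identifier mismatch")
  }
  n <- nrow(M1)
  if (is.null(k_neighbors)) k_neighbors <- min(n, max(3L, round(n / 10)))
  if (!(tau > 0 && tau < 1)) stop("tau must be in (0, 1)")
  divisor <- if (divisor_mode == "literal-2") 2 else 1
  F0 <- list(normalize_kernel(M1), normalize_kernel(M2))
  Sn <- list(neighbor_kernel(M1, k_neighbors), neighbor_kernel(M2, k_neighbors))
  Fc <- F0
  iter <- 0L
  delta <- Inf
  while (iter < max_iters && delta >= tol) {
    other <- c(2L, 1L)
    Fnew <- lapply(1:2, function(nk) {
      t <- other[nk]
      Fn <- tau * (Sn[[nk]] %*% (Fc[[t]] / divisor) %*% t(Sn[[nk]])) +
        (1 - tau) * (F0[[t]] / divisor)
      (Fn + t(Fn)) / 2
    })
    delta <- max(abs(Fnew[[1L]] - Fc[[1L]]), abs(Fnew[[2L]] - Fc[[2L]]))
    Fc <- Fnew
    iter <- iter + 1L
  }
  SMstar <- (Fc[[1L]] + Fc[[2L]]) / 2
  structure(list(F0 = F0, Sn = Sn, F = Fc, SMstar = SMstar,
                 iterations = iter, delta = delta, ids = ids,
                 k_neighbors = k_neighbors),
            class = "fusion_state")
}

#' Apply the neighbor-agreement mask to the fused kernel
#'
#' Entrywise (Hadamard) product of the weight mask and the overall kernel,
#' then symmetrization. The mask's neighborhoods are taken on the fused
#' kernel itself.
#'
#' @param state a `fusion_state` from [fuse_kernels()].
#' @param W optional weight matrix; defaults to
#'   `weight_matrix(state$SMstar, state$k_neighbors)`.
#' @return the final fused [similarity_matrix()].
#' @export
apply_weight <- function(state, W = NULL) {
  stopifnot(inherits(state, "fusion_state"))
  if (is.null(W)) W <- weight_matrix(state$SMstar, state$k_neighbors)
  if (!all(dim(W) == dim(state$SMstar))) stop("weight matrix shape mismatch")
  SM <- W * state$SMstar
  SM <- (SM + t(SM)) / 2
  ids <- if (is.null(state$ids)) paste0("e", seq_len(nrow(SM))) else state$ids
  similarity_matrix(SM, ids, symmetrize = FALSE)
}

#' Similarity kernel fusion, end to end
#'
#' Convenience wrapper: [fuse_kernels()] followed by [apply_weight()].
#'
#' @inheritParams fuse_kernels
#' @return the fused [similarity_matrix()].
#' @export
skf <- function(kernels, k_neighbors = NULL, tau = 0.5, max_iters = 20L,
                tol = 1e-6, divisor_mode = c("literal-2", "n-minus-1")) {
  state <- fuse_kernels(kernels, k_neighbors = k_neighbors, tau = tau,
                        max_iters = max_iters, tol = tol,
                        divisor_mode = divisor_mode)
  apply_weight(state)
}
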