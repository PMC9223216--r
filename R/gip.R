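#' Gaussian interaction profile kernel bandwidth
#'
#' Normalizes the original bandwidth by the mean squared norm of the binary
#' interaction profiles: `rho = rho_prime / mean(||row_i||^2)`. For binary
#' profiles the mean squared norm is the average number of known
#' associations per entity.
#'
#' @param profiles n x p binary matrix, one interaction profile per row.
#' @param rho_prime original bandwidth, positive; default 1 (the convention
#'   in the Gaussian interaction profile literature).
#' @return the normalized bandwidth, a positive scalar.
#' @export
gip_bandwidth <- function(profiles, rho_prime = 1) {
  profiles <- as.matrix(profiles)
  if (rho_prime <= 0) stop("rho_prime must be positive")
  msq <- mean(rowSums(profiles^2))
  if (msq == 0) stop("all-zero profile matrix: bandwidth undefined")
  rho_prime / msq
}

#' Gaussian interaction profile kernel
#'
#' `S(i, j) = exp(-rho * ||row_i - row_j||^2)` with the bandwidth from
#' [gip_bandwidth()]. The miRNA kernel uses the rows of the association
#' matrix as profiles; the disease kernel uses its columns (`t(A)`).
#'
#' @inheritParams gip_bandwidth
#' @param ids identifiers for the rows of `profiles`.
#' @return A [similarity_matrix()]: symmetric, unit diagonal, entries in
#'   (0, 1].
#' @export
gip_kernel <- function(profiles, rho_prime = 1, ids = rownames(profiles)) {
  profiles <- as.matrix(profiles)
  rho <- gip_bandwidth(profiles, rho_prime)
  sq <- rowSums(profiles^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0  # clip tiny negative round-off
  S <- exp(-rho * d2)
  diag(S) <- 1
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(S)))
  similarity_matrix(S, ids, symmetrize = TRUE)
}
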