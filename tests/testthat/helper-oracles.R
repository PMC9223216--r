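# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# AUC by brute-force positive-negative pair counting, ties one half
oracle_auc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) tot <- tot + sum(p > ns) + 0.5 * sum(p == ns)
  tot / (length(ps) * length(ns))
}

# decay-model contributions by exhaustive path enumeration: for each term,
# max over all directed child->parent paths from the disease of delta^length
oracle_dd1 <- function(g, disease, delta) {
  best <- stats::setNames(rep(-Inf, length(g$nodes)), g$nodes)
  walk <- function(t, depth) {
    if (delta^depth > best[[t]]) {
      best[[t]] <<- delta^depth
      for (p in g$parents[[t]]) walk(p, depth + 1L)
    }
  }
  walk(disease, 0L)
  best[is.finite(best)]
}

# random DAG over <= n_max nodes: node 1 is the disease; each later node
# gets parents only among later-numbered... build ancestors upward: node i's
# parents drawn from nodes i+1..n so edges child->parent are acyclic, and
# every node is reachable from the disease
random_dag <- function(n_max = 8L, p_edge = 0.5) {
  n <- sample(1:n_max, 1L)
  nodes <- paste0("t", seq_len(n))
  parents <- stats::setNames(vector("list", n), nodes)
  for (i in seq_len(n)) parents[[i]] <- character(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      cand <- (i + 1L):n
      pick <- cand[stats::runif(length(cand)) < p_edge]
      parents[[i]] <- nodes[pick]
    }
  }
  # restrict to the ancestor closure of the disease (node set must be T(D))
  reach <- nodes[1L]
  repeat {
    more <- unique(unlist(parents[reach], use.names = FALSE))
    new <- setdiff(more, reach)
    if (length(new) == 0L) break
    reach <- c(reach, new)
  }
  reach <- nodes[nodes %in% reach]
  parents <- parents[reach]
  parents <- lapply(parents, function(p) p[p %in% reach])
  list(nodes = reach, parents = parents, disease = nodes[1L])
}

# central-difference gradient of the factorization objective wrt one row of Z
numgrad_row <- function(fn, Z, i, h = 1e-6) {
  g <- numeric(ncol(Z))
  for (k in seq_len(ncol(Z))) {
    Zp <- Z; Zp[i, k] <- Zp[i, k] + h
    Zm <- Z; Zm[i, k] <- Zm[i, k] - h
    g[k] <- (fn(Zp) - fn(Zm)) / (2 * h)
  }
  g
}

# local prox operators for the independent solver (kept separate from the
# package implementations on purpose)
.or_svt <- function(M, tau) {
  s <- svd(M)
  d <- pmax(s$d - tau, 0)
  s$u %*% (d * t(s$v))
}
.or_colshrink <- function(M, tau) {
  nr <- sqrt(colSums(M^2))
  sc <- ifelse(nr > tau, (nr - tau) / nr, 0)
  sweep(M, 2L, sc, "*")
}

# independent first-order solver for min ||Y||_* + phi ||A - A Y||_{2,1}
# (the self-expression problem with X eliminated) by the Chambolle-Pock
# primal-dual algorithm; returns Y
oracle_lrr_cp <- function(A, phi, iters = 40000L) {
  nd <- ncol(A)
  L <- max(svd(A)$d)
  tau <- 0.95 / L
  sig <- 0.95 / L
  Y <- matrix(0, nd, nd)
  Ybar <- Y
  P <- matrix(0, nrow(A), nd)
  for (it in seq_len(iters)) {
    # dual ascent on P for H(Z) = phi ||A - Z||_{2,1}, Z = A Ybar
    Q <- P + sig * (A %*% Ybar)
    # prox_{H/sig} at Q/sig: A - colshrink(A - Q/sig, phi/sig)
    prox <- A - .or_colshrink(A - Q / sig, phi / sig)
    P <- Q - sig * prox
    Yold <- Y
    Y <- .or_svt(Y - tau * crossprod(A, P), tau)
    Ybar <- 2 * Y - Yold
  }
  Y
}

# tiny deterministic association fixture used by several files
toy_dataset <- function() {
  A <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 1, 0, 1))
  association_dataset(A, c("m1", "m2", "m3"), c("d1", "d2", "d3", "d4"))
}

# a scorer that "cheats" by reading the full (unmasked) truth; used to
# sanity-check the CV harness itself
oracle_scorer <- function(truth) {
  force(truth)
  function(train, sm, sd, config) {
    score_matrix(truth + 0, rownames(truth), colnames(truth))
  }
}

# small fast config for CV tests
tiny_config <- function(...) {
  pipeline_config(rank = 6L, max_sweeps = 40L, lrr_max_iters = 400L, ...)
}
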