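random_instance <- function(nm = 7, nd = 5, r = 3) {
  list(A = matrix(rnorm(nm * nd), nm, nd),
       SM = { M <- matrix(runif(nm * nm), nm, nm); (M + t(M)) / 2 },
       SD = { M <- matrix(runif(nd * nd), nd, nd); (M + t(M)) / 2 },
       U = matrix(rnorm(nm * r), nm, r),
       V = matrix(rnorm(nd * r), nd, r))
}

test_that("objective evaluates its four terms correctly", {
  A <- matrix(1:6 / 6, 2, 3)
  U0 <- matrix(0, 2, 2); V0 <- matrix(0, 3, 2)
  expect_equal(scmf_objective(U0, V0, A, diag(2), diag(3), 1, 1),
               0.5 * sum(A^2))
  # exact factorization with no regularization
  U <- matrix(rnorm(4), 2, 2); V <- matrix(rnorm(6), 3, 2)
  expect_equal(scmf_objective(U, V, tcrossprod(U, V), diag(2), diag(3), 0, 0), 0)
  # all-ones 2x2 instance, rank 1, theta = sigma = 1: hand evaluation
  A1 <- matrix(1, 2, 2); u1 <- matrix(1, 2, 1); v1 <- matrix(1, 2, 1)
  S1 <- matrix(1, 2, 2)
  # fit 0; L2: 0.5*(2+2); graph: 0.5 * (0) since all rows equal
  expect_equal(scmf_objective(u1, v1, A1, S1, S1, 1, 1), 2)
  # frozen independent evaluation on a random instance via the naive sums
  set.seed(41)
  inst <- random_instance()
  naive <- local({
    fit <- 0.5 * sum((inst$A - inst$U %*% t(inst$V))^2)
    l2 <- 0.5 * (sum(inst$U^2) + sum(inst$V^2))
    gu <- 0; for (i in 1:7) for (j in 1:7)
      gu <- gu + sum((inst$U[i, ] - inst$U[j, ])^2) * inst$SM[i, j]
    gv <- 0; for (i in 1:5) for (j in 1:5)
      gv <- gv + sum((inst$V[i, ] - inst$V[j, ])^2) * inst$SD[i, j]
    fit + l2 + (2 / 2) * (gu + gv)   # sigma = 2
  })
  expect_equal(scmf_objective(inst$U, inst$V, inst$A, inst$SM, inst$SD, 1, 2),
               naive, tolerance = 1e-10)
})

test_that("analytic gradients match central differences of the objective", {
  set.seed(42)
  for (case in 1:5) {
    inst <- random_instance()
    theta <- runif(1, 0.5, 4); sigma <- runif(1, 0.1, 2)
    r <- ncol(inst$U)
    # gradient wrt u_i implied by the row update: grad = u_i M - rhs
    for (i in c(1, 4)) {
      w <- inst$SM[i, ] + inst$SM[, i]; w[i] <- 0
      M <- crossprod(inst$V) + diag(theta + sigma * sum(w), r)
      rhs <- as.numeric(inst$A[i, ] %*% inst$V) +
        sigma * as.numeric(w %*% inst$U)
      ana <- as.numeric(inst$U[i, ] %*% M) - rhs
      num <- numgrad_row(function(U) scmf_objective(U, inst$V, inst$A,
                                                    inst$SM, inst$SD,
                                                    theta, sigma),
                         inst$U, i)
      expect_lt(max(abs(ana - num)) / max(1, max(abs(num))), 1e-5)
    }
    for (j in c(2, 5)) {
      w <- inst$SD[j, ] + inst$SD[, j]; w[j] <- 0
      M <- crossprod(inst$U) + diag(theta + sigma * sum(w), r)
      rhs <- as.numeric(inst$A[, j] %*% inst$U) +
        sigma * as.numeric(w %*% inst$V)
      ana <- as.numeric(inst$V[j, ] %*% M) - rhs
      num <- numgrad_row(function(V) scmf_objective(inst$U, V, inst$A,
                                                    inst$SM, inst$SD,
                                                    theta, sigma),
                         inst$V, j)
      expect_lt(max(abs(ana - num)) / max(1, max(abs(num))), 1e-5)
    }
  }
})

test_that("row updates are exact coordinate minimizers", {
  set.seed(43)
  for (case in 1:5) {
    inst <- random_instance()
    theta <- 2; sigma <- 1
    before <- scmf_objective(inst$U, inst$V, inst$A, inst$SM, inst$SD,
                             theta, sigma)
    i <- sample(nrow(inst$U), 1)
    ui <- update_row_u(i, inst$U, inst$V, inst$A, inst$SM, theta, sigma)
    U2 <- inst$U; U2[i, ] <- ui
    after <- scmf_objective(U2, inst$V, inst$A, inst$SM, inst$SD, theta, sigma)
    expect_lte(after, before + 1e-12)
    # gradient block vanishes at the updated row
    num <- numgrad_row(function(U) scmf_objective(U, inst$V, inst$A,
                                                  inst$SM, inst$SD,
                                                  theta, sigma), U2, i)
    expect_lt(max(abs(num)), 1e-5)  # central-difference noise floor
    j <- sample(nrow(inst$V), 1)
    vj <- update_row_v(j, inst$U, inst$V, inst$A, inst$SD, theta, sigma)
    V2 <- inst$V; V2[j, ] <- vj
    expect_lte(scmf_objective(inst$U, V2, inst$A, inst$SM, inst$SD,
                              theta, sigma), before + 1e-12)
  }
})

test_that("with sigma = 0, theta = 0 and orthonormal V the u-update is least squares", {
  set.seed(44)
  V <- qr.Q(qr(matrix(rnorm(15), 5, 3)))
  A <- matrix(rnorm(20), 4, 5)
  U <- matrix(0, 4, 3)
  SM <- matrix(runif(16), 4, 4)
  u1 <- update_row_u(1, U, V, A, SM, theta = 0, sigma = 0)
  expect_equal(u1, as.numeric(A[1, ] %*% V), tolerance = 1e-10)
})

test_that("fit_scmf: objective trace non-increasing and convergence flagged", {
  set.seed(45)
  inst <- random_instance(nm = 12, nd = 9, r = 3)
  A <- abs(inst$A)
  model <- fit_scmf(A, inst$SM, inst$SD, rank = 3, theta = 2, sigma = 0.5,
                    max_sweeps = 60)
  expect_true(all(diff(model$objective) <= 1e-9))
  expect_true(model$converged)
  # the fitted factors are stationary: every row update is a no-op
  for (i in 1:3) {
    ui <- update_row_u(i, model$U, model$V, A, inst$SM, 2, 0.5)
    expect_lt(max(abs(ui - model$U[i, ])), 1e-2)
  }
})

test_that("planted factorization is recovered at the planted rank", {
  set.seed(46)
  U0 <- abs(matrix(rnorm(60 * 4), 60, 4))
  V0 <- abs(matrix(rnorm(40 * 4), 40, 4))
  As <- tcrossprod(U0, V0)
  model <- fit_scmf(As, diag(60), diag(40), rank = 4, theta = 1e-8, sigma = 0,
                    max_sweeps = 100, tol = 1e-12)
  rel <- sqrt(sum((tcrossprod(model$U, model$V) - As)^2)) / sqrt(sum(As^2))
  expect_lt(rel, 1e-3)
})

test_that("huge sigma with all-ones similarity pulls latent rows together", {
  set.seed(47)
  inst <- random_instance(nm = 10, nd = 8, r = 2)
  ones_m <- matrix(1, 10, 10); ones_d <- matrix(1, 8, 8)
  spread <- function(Z) max(dist(Z))
  m_small <- fit_scmf(abs(inst$A), ones_m, ones_d, rank = 2, theta = 0.1,
                      sigma = 1, max_sweeps = 50)
  m_big <- fit_scmf(abs(inst$A), ones_m, ones_d, rank = 2, theta = 0.1,
                    sigma = 1e4, max_sweeps = 50)
  expect_lt(spread(m_big$U), spread(m_small$U) / 10)
  expect_lt(spread(m_big$V), spread(m_small$V) / 10)
})

test_that("fits are deterministic for a fixed seed and init mode", {
  set.seed(48)
  inst <- random_instance(nm = 9, nd = 6, r = 2)
  A <- abs(inst$A)
  m1 <- fit_scmf(A, inst$SM, inst$SD, rank = 2, seed = 7, init = "random",
                 max_sweeps = 20)
  m2 <- fit_scmf(A, inst$SM, inst$SD, rank = 2, seed = 7, init = "random",
                 max_sweeps = 20)
  expect_identical(m1$U, m2$U)
  expect_identical(m1$V, m2$V)
  s1 <- fit_scmf(A, inst$SM, inst$SD, rank = 2, max_sweeps = 20)
  s2 <- fit_scmf(A, inst$SM, inst$SD, rank = 2, max_sweeps = 20)
  expect_identical(predict_scores(s1)$scores, predict_scores(s2)$scores)
})

test_that("predict_scores returns U V' with degenerate sanity cases", {
  m <- structure(list(U = matrix(0, 3, 2), V = matrix(1, 4, 2),
                      mirna_ids = paste0("m", 1:3),
                      disease_ids = paste0("d", 1:4)),
                 class = "scmf_model")
  expect_equal(unname(predict_scores(m)$scores), matrix(0, 3, 4))
  m$U <- matrix(1, 3, 1); m$V <- matrix(1, 4, 1)
  expect_equal(unname(predict_scores(m)$scores), matrix(1, 3, 4))
})

test_that("model dump writes factors and a JSON sidecar", {
  set.seed(49)
  inst <- random_instance(nm = 5, nd = 4, r = 2)
  model <- fit_scmf(abs(inst$A), inst$SM, inst$SD, rank = 2, max_sweeps = 10)
  d <- withr::local_tempdir()
  save_scmf_model(model, d)
  expect_true(all(file.exists(file.path(d, c("U.tsv", "V.tsv", "model.json")))))
  meta <- jsonlite::read_json(file.path(d, "model.json"))
  expect_equal(meta$rank, 2)
})
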