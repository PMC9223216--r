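#' Assemble the full pipeline configuration
#'
#' Central container of every tunable parameter, with the defaults the
#' package recommends: semantic decay 0.5; Gaussian-profile bandwidth 1 for
#' both entity classes; kernel fusion with `tau = 0.5`, 20 iterations,
#' neighborhood `max(3, n/10)` and the literal divide-by-2 cross term;
#' decomposition with `phi = 1` and the standard inexact-ALM schedule; and
#' factorization with rank 50, `theta = 4`, `sigma = 1` (the best cell of
#' the reference 7 x 7 hyperparameter grid).
#'
#' @param delta semantic contribution decay in (0, 1].
#' @param rho_prime_m,rho_prime_d original Gaussian-profile bandwidths.
#' @param k_neighbors_m,k_neighbors_d fusion neighborhood sizes (`NULL` =
#'   `max(3, round(n/10))`).
#' @param tau,skf_max_iters,skf_tol,divisor_mode fusion controls.
#' @param phi,alpha0,alpha_max,growth,lrr_eps,lrr_max_iters decomposition
#'   controls.
#' @param rank,theta,sigma,max_sweeps,scmf_tol,init factorization controls.
#' @param skip_md if `TRUE` the decomposition step is skipped and the raw
#'   association matrix feeds the factorization (the ablation setting).
#' @param seed global seed driving every stochastic choice.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(delta = 0.5,
                            rho_prime_m = 1, rho_prime_d = 1,
                            k_neighbors_m = NULL, k_neighbors_d = NULL,
                            tau = 0.5, skf_max_iters = 20L, skf_tol = 1e-6,
                            divisor_mode = "literal-2",
                            phi = 1, alpha0 = 1e-4, alpha_max = 1e10,
                            growth = 1.1, lrr_eps = 1e-8,
                            lrr_max_iters = 500L,
                            rank = 50L, theta = 4, sigma = 1,
                            max_sweeps = 200L, scmf_tol = 1e-6,
                            init = "svd", skip_md = FALSE, seed = 1L) {
  cfg <- list(delta = delta, rho_prime_m = rho_prime_m,
              rho_prime_d = rho_prime_d, k_neighbors_m = k_neighbors_m,
              k_neighbors_d = k_neighbors_d, tau = tau,
              skf_max_iters = skf_max_iters, skf_tol = skf_tol,
              divisor_mode = divisor_mode, phi = phi, alpha0 = alpha0,
              alpha_max = alpha_max, growth = growth, lrr_eps = lrr_eps,
              lrr_max_iters = lrr_max_iters, rank = rank, theta = theta,
              sigma = sigma, max_sweeps = max_sweeps, scmf_tol = scmf_tol,
              init = init, skip_md = skip_md, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Score all miRNA-disease pairs with the full pipeline
#'
#' The core prediction flow on in-memory inputs: Gaussian-profile kernels
#' are computed from the association matrix for both entity classes and
#' fused (by similarity kernel fusion) with the supplied functional and
#' semantic similarities; the association matrix is denoised by the
#' low-rank decomposition (unless `skip_md`); and the
#' similarity-constrained factorization of the denoised matrix yields the
#' final scores. The fit diagnostics of the two iterative stages are
#' attached as attribute `"diagnostics"`.
#'
#' @param dataset an [association_dataset()].
#' @param sm_functional miRNA functional [similarity_matrix()], aligned to
#'   the dataset's miRNAs.
#' @param sd_semantic disease semantic [similarity_matrix()], aligned to
#'   the dataset's diseases.
#' @param config a [pipeline_config()].
#' @return A [score_matrix()] of predicted association scores.
#' @export
predict_associations <- function(dataset, sm_functional, sd_semantic,
                                 config = pipeline_config()) {
  stopifnot(inherits(dataset, "association_dataset"))
  smf <- .sim_mat(sm_functional)
  sds <- .sim_mat(sd_semantic)
  if (nrow(smf) != length(dataset$mirna_ids)) {
    stop("stage similarity: miRNA functional similarity misaligned with dataset")
  }
  if (nrow(sds) != length(dataset$disease_ids)) {
    stop("stage similarity: disease semantic similarity misaligned with dataset")
  }
  A <- dataset$A
  sm2 <- gip_kernel(A, rho_prime = config$rho_prime_m, ids = dataset$mirna_ids)
  sd2 <- gip_kernel(t(A), rho_prime = config$rho_prime_d,
                    ids = dataset$disease_ids)
  SM <- skf(list(similarity_matrix(smf, dataset$mirna_ids), sm2),
            k_neighbors = config$k_neighbors_m, tau = config$tau,
            max_iters = config$skf_max_iters, tol = config$skf_tol,
            divisor_mode = config$divisor_mode)
  SD <- skf(list(similarity_matrix(sds, dataset$disease_ids), sd2),
            k_neighbors = config$k_neighbors_d, tau = config$tau,
            max_iters = config$skf_max_iters, tol = config$skf_tol,
            divisor_mode = config$divisor_mode)
  lrr <- NULL
  if (isTRUE(config$skip_md)) {
    A_star <- score_matrix(A, dataset$mirna_ids, dataset$disease_ids)
  } else {
    lrr <- ialm_lrr(A, phi = config$phi, alpha0 = config$alpha0,
                    alpha_max = config$alpha_max, growth = config$growth,
                    eps = config$lrr_eps, max_iters = config$lrr_max_iters)
    A_star <- reconstruct(dataset, lrr)
  }
  model <- fit_scmf(A_star, SM, SD, rank = config$rank, theta = config$theta,
                    sigma = config$sigma, max_sweeps = config$max_sweeps,
                    tol = config$scmf_tol, init = config$init,
                    seed = config$seed)
  scores <- predict_scores(model)
  attr(scores, "diagnostics") <- list(
    lrr = if (is.null(lrr)) NULL else
      list(iterations = lrr$iterations, r1 = lrr$r1, r2 = lrr$r2,
           converged = lrr$converged),
    scmf = list(sweeps = model$sweeps, converged = model$converged,
                objective = model$objective[length(model$objective)]))
  scores
}

# resolve file-driven inputs named in a config-like list
.load_pipeline_inputs <- function(paths, delta) {
  dataset <- load_association_edges(paths$associations)
  smf <- load_similarity_matrix(paths$sm_functional)
  corpus <- load_dag_corpus(paths$dag_edges, paths$dag_roster)
  sds <- build_semantic_similarity(corpus, delta = delta,
                                   diseases = dataset$disease_ids)
  al <- align_inputs(dataset, smf, sds)
  list(dataset = al$dataset, sm_functional = al$sm, sd_semantic = al$sd)
}

#' Run the prediction pipeline from input files
#'
#' Loads the association edge list, functional similarity matrix and DAG
#' corpus named in `paths`, computes disease semantic similarity, aligns
#' everything, runs [predict_associations()], and writes the score matrix,
#' per-disease ranked candidate lists, and a JSON run report (all effective
#' parameters plus stage diagnostics) into `output_dir`.
#'
#' @param paths named list with `associations`, `sm_functional`,
#'   `dag_edges`, `dag_roster`.
#' @param config a [pipeline_config()].
#' @param output_dir directory for artifacts (created if needed).
#' @param top_n length of each per-disease ranked list; default 30.
#' @return the [score_matrix()], invisibly.
#' @export
run_predict <- function(paths, config = pipeline_config(),
                        output_dir = "scmfpred_out", top_n = 30L) {
  inputs <- .load_pipeline_inputs(paths, config$delta)
  scores <- predict_associations(inputs$dataset, inputs$sm_functional,
                                 inputs$sd_semantic, config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  save_scores(scores, file.path(output_dir, "scores.tsv"))
  ranked <- do.call(rbind, lapply(inputs$dataset$disease_ids, function(d) {
    tk <- top_k(scores, d, top_n, exclude_known = TRUE,
                dataset = inputs$dataset)
    cbind(disease = d, tk)
  }))
  utils::write.table(ranked, file.path(output_dir, "ranked_candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(config = unclass(config),
                 n_mirna = length(inputs$dataset$mirna_ids),
                 n_disease = length(inputs$dataset$disease_ids),
                 n_associations = sum(inputs$dataset$A),
                 diagnostics = attr(scores, "diagnostics"))
  jsonlite::write_json(report, file.path(output_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(scores)
}

#' Run a cross-validation protocol from input files
#'
#' @inheritParams run_predict
#' @param protocol one of `"5cv"`, `"global-loocv"`, `"local-loocv"`.
#' @param repeats repeats for the fivefold protocol.
#' @param diseases disease subset for the local protocol (default all).
#' @return the `cv_result`, invisibly; JSON summary and ROC TSV are written
#'   to `output_dir`.
#' @export
run_evaluate <- function(paths, protocol = c("5cv", "global-loocv", "local-loocv"),
                         config = pipeline_config(), repeats = 5L,
                         diseases = NULL, output_dir = "scmfpred_out") {
  protocol <- match.arg(protocol)
  inputs <- .load_pipeline_inputs(paths, config$delta)
  res <- switch(protocol,
    "5cv" = five_fold_cv(inputs$dataset, inputs$sm_functional,
                         inputs$sd_semantic, config, repeats = repeats,
                         seed = config$seed),
    "global-loocv" = global_loocv(inputs$dataset, inputs$sm_functional,
                                  inputs$sd_semantic, config),
    "local-loocv" = local_loocv(inputs$dataset, inputs$sm_functional,
                                inputs$sd_semantic, config,
                                diseases = diseases))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(protocol = res$protocol, mean = res$mean,
                            sd = res$sd, aucs = res$aucs,
                            seed = config$seed),
                       file.path(output_dir, paste0("cv_", protocol, ".json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$roc)) {
    utils::write.table(res$roc, file.path(output_dir, paste0("roc_", protocol, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(res)
}

#' Hyperparameter grid over the two regularization weights
#'
#' Runs fivefold cross-validation for every `(theta, sigma)` combination
#' and tabulates the mean AUCs, mirroring the reference grid experiment
#' (`2^-3 .. 2^3` on both axes) at whatever scale the inputs allow.
#'
#' @inheritParams five_fold_cv
#' @param theta_grid,sigma_grid numeric vectors of weights to try.
#' @return matrix of mean AUCs, thetas in rows, sigmas in columns.
#' @export
run_grid <- function(dataset, sm_functional, sd_semantic,
                     config = pipeline_config(),
                     theta_grid = 2^(-3:3), sigma_grid = 2^(-3:3),
                     repeats = 3L, seed = 1L) {
  out <- matrix(NA_real_, length(theta_grid), length(sigma_grid),
                dimnames = list(paste0("theta=", theta_grid),
                                paste0("sigma=", sigma_grid)))
  for (a in seq_along(theta_grid)) {
    for (b in seq_along(sigma_grid)) {
      cfg <- config
      cfg$theta <- theta_grid[a]
      cfg$sigma <- sigma_grid[b]
      res <- five_fold_cv(dataset, sm_functional, sd_semantic, cfg,
                          repeats = repeats, seed = seed)
      out[a, b] <- res$mean
    }
  }
  out
}
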