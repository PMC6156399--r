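#' Configuration for label propagation
#'
#' @param alpha Retention rate in (0, 1): the weight on information arriving
#'   from network neighbours at each step; `1 - alpha` is the weight on the
#'   initial labels.
#' @param beta Combination weight in \[0, 1\] between the miRNA-side and
#'   disease-side propagation results (default 0.5, weighting both sides
#'   equally).
#' @param tol Convergence tolerance (max-norm of the update), `> 0`.
#' @param max_iter Iteration cap for the iterative mode.
#' @param mode `"closed_form"` (exact solve, default at these problem sizes)
#'   or `"iterative"`.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.5, beta = 0.5, tol = 1e-6,
                               max_iter = 1000L,
                               mode = c("closed_form", "iterative")) {
  mode <- match.arg(mode)
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_snmda("alpha must lie strictly between 0 and 1")
  if (length(beta) != 1L || !is.finite(beta) || beta < 0 || beta > 1)
    stop_snmda("beta must lie in [0, 1]")
  if (tol <= 0) stop_snmda("tol must be positive")
  if (max_iter < 1L) stop_snmda("max_iter must be positive")
  structure(list(alpha = alpha, beta = beta, tol = tol,
                 max_iter = as.integer(max_iter), mode = mode),
            class = "propagation_config")
}

#' Symmetrically normalize a similarity matrix for propagation
#'
#' Computes `MS = Dg^(-1/2) %*% S %*% Dg^(-1/2)` where `Dg` is diagonal with
#' the row sums of `S`. For a symmetric nonnegative `S` this bounds the
#' spectral radius by 1, which is what guarantees convergence of the label
#' propagation iteration. Rows (and matching columns) with zero sum are left
#' all-zero rather than divided.
#'
#' @param S A symmetric nonnegative [similarity_matrix()].
#' @return A [similarity_matrix()] with `kind = "normalized"`.
#' @export
normalize_similarity <- function(S) {
  M <- as_base_matrix(S)
  if (any(M < 0)) stop_snmda("cannot normalize a similarity with negative entries")
  rs <- rowSums(M)
  d <- ifelse(rs > 0, 1 / sqrt(rs), 0)
  out <- M * outer(d, d)
  similarity_matrix(out, kind = "normalized")
}

#' Propagate labels on a normalized similarity network
#'
#' Diffuses the initial label matrix `Y` over the network: each node keeps a
#' fraction `alpha` of its neighbours' current labels and re-injects a
#' fraction `1 - alpha` of its initial labels,
#' `F(t+1) = alpha * MS %*% F(t) + (1 - alpha) * Y`, starting from
#' `F(0) = Y`. For a normalized `MS` this converges geometrically (rate
#' `<= alpha`) to the closed form `(1 - alpha) * solve(I - alpha * MS) %*% Y`,
#' which the `"closed_form"` mode computes directly.
#'
#' @param MS A normalized [similarity_matrix()] (spectral radius `<= 1`).
#' @param Y Initial label matrix; rows match the entities of `MS`.
#' @param cfg A [propagation_config()].
#' @param check_spectrum Validate the spectral radius bound before
#'   propagating (default `TRUE`).
#' @return The converged label matrix, same shape as `Y`.
#' @export
propagate_labels <- function(MS, Y, cfg = propagation_config(),
                             check_spectrum = TRUE) {
  M <- as_base_matrix(MS)
  Y <- as.matrix(Y)
  if (nrow(M) != nrow(Y))
    stop_snmda("label matrix rows do not match the similarity network")
  if (check_spectrum) {
    rho <- max(abs(eigen(M, symmetric = TRUE, only.values = TRUE)$values))
    if (rho > 1 + 1e-8)
      stop_snmda(sprintf("similarity network is not normalized (spectral radius %.6f > 1)",
                         rho))
  }
  alpha <- cfg$alpha
  if (cfg$mode == "closed_form") {
    F_new <- solve(diag(nrow(M)) - alpha * M, (1 - alpha) * Y)
  } else {
    F_cur <- Y
    resid <- Inf
    for (iter in seq_len(cfg$max_iter)) {
      F_new <- alpha * (M %*% F_cur) + (1 - alpha) * Y
      resid <- max(abs(F_new - F_cur))
      F_cur <- F_new
      if (resid < cfg$tol) break
    }
    if (resid >= cfg$tol)
      stop_snmda(sprintf("propagation did not converge in %d iterations (residual %.3g)",
                         cfg$max_iter, resid))
  }
  dimnames(F_new) <- dimnames(Y)
  F_new
}

#' Score all miRNA-disease pairs by two-sided label propagation
#'
#' Runs label propagation on the miRNA similarity network with the known
#' associations as initial labels (`Y = t(A)`, miRNA x disease), and on the
#' disease similarity network with `Y' = A` (disease x miRNA), then combines
#' the two converged score matrices as
#' `F = beta * F_M + (1 - beta) * t(F_D)` (miRNA x disease).
#'
#' @param A An [association_matrix()] (disease x miRNA).
#' @param fms Fused miRNA [similarity_matrix()]; index = columns of `A`.
#' @param fds Fused disease [similarity_matrix()]; index = rows of `A`.
#' @param cfg A [propagation_config()].
#' @return A [score_matrix()] (miRNA x disease).
#' @export
snmda_predict <- function(A, fms, fds, cfg = propagation_config()) {
  if (!identical(rownames(fms), colnames(A)))
    stop_snmda("miRNA similarity index does not match the association columns")
  if (!identical(rownames(fds), rownames(A)))
    stop_snmda("disease similarity index does not match the association rows")
  MS <- normalize_similarity(fms)
  DS <- normalize_similarity(fds)
  F_M <- propagate_labels(MS, t(as_base_matrix(A)), cfg)
  F_D <- propagate_labels(DS, as_base_matrix(A), cfg)
  score_matrix(cfg$beta * F_M + (1 - cfg$beta) * t(F_D))
}

#' Run the full sparse-neighbourhood prediction pipeline
#'
#' End-to-end scoring: reconstruct miRNA and disease similarities from the
#' association network by sparse-neighbourhood coding, fuse them with the
#' precomputed functional/semantic similarities, and propagate the known
#' labels on both fused networks.
#'
#' @param A An [association_matrix()].
#' @param mfs Precomputed miRNA functional [similarity_matrix()] (index =
#'   columns of `A`).
#' @param dss Precomputed disease semantic [similarity_matrix()] (index =
#'   rows of `A`).
#' @param sparse_cfg A [sparse_config()].
#' @param prop_cfg A [propagation_config()].
#' @return A list: `F` (the final [score_matrix()]), the fused matrices
#'   `fms`/`fds`, and the reconstructions `rms`/`rds`.
#' @export
snmda_pipeline <- function(A, mfs, dss,
                           sparse_cfg = sparse_config(),
                           prop_cfg = propagation_config()) {
  rms <- reconstruct_similarity(interaction_profiles(A, "mirna"), sparse_cfg)
  rds <- reconstruct_similarity(interaction_profiles(A, "disease"), sparse_cfg)
  fms <- fuse_similarity(rms$similarity, mfs)
  fds <- fuse_similarity(rds$similarity, dss)
  F <- snmda_predict(A, fms, fds, prop_cfg)
  list(F = F, fms = fms, fds = fds, rms = rms, rds = rds)
}
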