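#' Configuration for sparse-neighbourhood reconstruction
#'
#' @param lam L1 penalty weight, `> 0`. With `lam_scale = "relative"` (the
#'   default) the penalty applied to sample `i` is `lam * max(abs(t(D) %*% x_i))`,
#'   which keeps shrinkage comparable across profiles of different density;
#'   `"absolute"` uses `lam` as-is for every sample.
#' @param eps Sparse-neighbourhood threshold, `>= 0`: only coefficients
#'   strictly greater than `eps` survive as neighbours. `eps = 0` keeps all
#'   strictly positive coefficients.
#' @param nonneg If `TRUE`, solve the nonnegative program directly instead of
#'   clipping negatives after an unconstrained solve.
#' @param symmetrize If `TRUE` (default) the reconstructed similarity is
#'   `(W + t(W))/2`; the downstream fusion and propagation steps presuppose a
#'   symmetric similarity.
#' @param lam_scale `"relative"` or `"absolute"` (see `lam`).
#' @return A `sparse_config` list.
#' @export
sparse_config <- function(lam = 0.01, eps = 1e-4, nonneg = FALSE,
                          symmetrize = TRUE,
                          lam_scale = c("relative", "absolute")) {
  lam_scale <- match.arg(lam_scale)
  if (length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop_snmda("lam must be a positive scalar")
  if (length(eps) != 1L || !is.finite(eps) || eps < 0)
    stop_snmda("eps must be a nonnegative scalar")
  structure(list(lam = lam, eps = eps, nonneg = isTRUE(nonneg),
                 symmetrize = isTRUE(symmetrize), lam_scale = lam_scale),
            class = "sparse_config")
}

#' Interaction profiles of miRNAs or diseases
#'
#' Each entity's feature vector is its binary interaction profile in the
#' association matrix: a miRNA is described by its column of `A` (which
#' diseases it is linked to) and a disease by its row (which miRNAs it is
#' linked to). Profiles are returned as the columns of a matrix, one column
#' per entity of the requested side.
#'
#' @param A An [association_matrix()].
#' @param side `"mirna"` or `"disease"`.
#' @return A `profile_set`: binary matrix whose columns are entity profiles
#'   (length = size of the opposite entity set), with a `side` attribute.
#' @export
interaction_profiles <- function(A, side = c("mirna", "disease")) {
  side <- match.arg(side)
  P <- if (side == "mirna") as_base_matrix(A) else t(as_base_matrix(A))
  attr(P, "side") <- side
  class(P) <- c("profile_set", class(matrix()))
  P
}

#' L1-penalized sparse coding of one sample
#'
#' Expresses the sample `x` as a sparse linear combination of dictionary
#' columns by minimising `||D %*% w - x||^2 + lam * ||w||_1` (the penalized
#' relaxation of the equality-constrained basis-pursuit program, which is
#' also well defined when `x = D %*% w` is infeasible). Solved by cyclic
#' coordinate descent with exact soft-threshold updates; deterministic for
#' fixed inputs.
#'
#' @param x Numeric vector to reconstruct.
#' @param D Dictionary matrix, `length(x)` rows, one candidate per column.
#' @param lam Absolute L1 penalty weight, `> 0`.
#' @param nonneg If `TRUE`, constrain `w >= 0`.
#' @param tol Convergence tolerance on the largest coefficient update.
#' @param max_iter Maximum number of full coordinate sweeps.
#' @return Coefficient vector `w`, one entry per dictionary column.
#' @export
solve_l1 <- function(x, D, lam, nonneg = FALSE, tol = 1e-12, max_iter = 10000L) {
  if (!is.matrix(D)) D <- as.matrix(D)
  if (length(x) != nrow(D)) stop_snmda("x and dictionary dimensions disagree")
  if (length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop_snmda("lam must be a positive scalar")
  if (ncol(D) == 0L) return(numeric(0))
  .cd_lasso(as.numeric(x), D, lam, isTRUE(nonneg), tol, as.integer(max_iter))
}

#' Sparse neighbourhood of a coefficient vector
#'
#' The dictionary samples whose reconstruction coefficient exceeds the
#' threshold `eps`. The sample itself is never a candidate (it is excluded
#' from the dictionary upstream).
#'
#' @param w Coefficient vector.
#' @param eps Threshold `>= 0`.
#' @return Integer indices `j` with `w[j] > eps` (possibly empty).
#' @export
sparse_neighbourhood <- function(w, eps = 0) {
  if (eps < 0) stop_snmda("eps must be nonnegative")
  which(w > eps)
}

#' Reconstruct a similarity matrix from interaction profiles
#'
#' Each entity is sparse-coded against the dictionary formed by all *other*
#' entities' profiles. Coefficients are clipped at zero (a similarity cannot
#' be negative) and thresholded at `eps`; the surviving sparse-neighbourhood
#' weights fill one row of the coefficient matrix `W` (diagonal exactly 0).
#' The reconstructed similarity is `(W + t(W))/2` when `config$symmetrize`
#' is set, else `W` itself. An all-zero profile (an entity with no known
#' associations) yields an all-zero row, with a warning.
#'
#' @param profiles A `profile_set` from [interaction_profiles()].
#' @param config A [sparse_config()].
#' @return A `reconstruction_result` list: `weights` (raw thresholded `W`),
#'   `similarity` (a [similarity_matrix()], `kind = "reconstructed"`), and
#'   `config`.
#' @export
reconstruct_similarity <- function(profiles, config = sparse_config()) {
  P <- as_base_matrix(profiles)
  n <- ncol(P)
  if (n < 2L) stop_snmda("need at least 2 entities to reconstruct similarity")
  nm <- colnames(P)
  W <- matrix(0, n, n, dimnames = list(nm, nm))
  zero_profiles <- character(0)
  for (i in seq_len(n)) {
    x <- P[, i]
    D <- P[, -i, drop = FALSE]
    corr <- max(abs(crossprod(D, x)))
    if (corr == 0) {
      if (all(x == 0)) zero_profiles <- c(zero_profiles, nm[i])
      next                                  # w = 0 is optimal for any lam > 0
    }
    lam_i <- if (config$lam_scale == "relative") config$lam * corr else config$lam
    w <- solve_l1(x, D, lam_i, nonneg = config$nonneg)
    w <- pmax(w, 0)
    w[w <= config$eps] <- 0
    W[i, -i] <- w
  }
  if (length(zero_profiles))
    warning("all-zero interaction profile(s), left unreconstructed: ",
            paste(utils::head(zero_profiles, 5L), collapse = ", "),
            call. = FALSE)
  S <- if (config$symmetrize) (W + t(W)) / 2 else W
  structure(list(weights = W,
                 similarity = similarity_matrix(S, kind = "reconstructed",
                                                check_symmetry = config$symmetrize),
                 config = config),
            class = "reconstruction_result")
}

#' @export
print.reconstruction_result <- function(x, ...) {
  nz <- sum(x$weights > 0)
  cat(sprintf("<reconstruction_result> %d entities, %d sparse-neighbourhood weights\n",
              nrow(x$weights), nz))
  invisible(x)
}
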