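#' Fuse a reconstructed similarity with a precomputed one
#'
#' Entrywise integration of the learned (sparse-neighbourhood) similarity
#' with the precomputed prior (miRNA functional similarity or disease
#' semantic similarity): where the prior is exactly zero the reconstructed
#' value is used alone, otherwise the two are averaged with equal weights.
#'
#' @param reconstructed A [similarity_matrix()] from
#'   [reconstruct_similarity()].
#' @param precomputed A [similarity_matrix()] over the same entities, in the
#'   same order.
#' @return A [similarity_matrix()] with `kind = "fused"`.
#' @export
fuse_similarity <- function(reconstructed, precomputed) {
  if (!identical(dimnames(reconstructed), dimnames(precomputed)))
    stop_snmda("similarity matrices to fuse are over different indices")
  R <- as_base_matrix(reconstructed)
  P <- as_base_matrix(precomputed)
  out <- ifelse(P == 0, R, (R + P) / 2)
  similarity_matrix(out, kind = "fused")
}

#' Validate a fused similarity matrix as a similarity network
#'
#' The similarity network is the matrix itself: nodes are the entities and
#' every nonzero off-diagonal entry is a weighted edge. This is an identity
#' pass-through that re-validates symmetry/nonnegativity and reports the
#' edge count.
#'
#' @param S A [similarity_matrix()].
#' @return `S`, invisibly unchanged; the off-diagonal edge count is attached
#'   as attribute `n_edges` and reported via `message()`.
#' @export
build_network <- function(S) {
  M <- as_base_matrix(S)
  if (any(M < 0)) stop_snmda("similarity network has negative entries")
  if (max(abs(M - t(M))) > 1e-10) stop_snmda("similarity network is asymmetric")
  off <- M
  diag(off) <- 0
  n_edges <- sum(off[upper.tri(off)] != 0)
  message(sprintf("similarity network: %d nodes, %d weighted edges",
                  nrow(M), n_edges))
  attr(S, "n_edges") <- n_edges
  S
}
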