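#' Fixed 5 x 5 toy association network
#'
#' A frozen miniature of a miRNA-disease interaction network with 5 miRNAs
#' and 5 diseases, whose first miRNA has interaction profile
#' `(1, 1, 0, 1, 0)` and first disease has profile `(1, 0, 1, 0, 0)`. The
#' 16 cells not pinned down by those two profiles are arbitrary constants,
#' frozen once so the fixture is stable.
#'
#' @return An [association_matrix()] (diseases D1..D5 x miRNAs M1..M5).
#' @export
figure2_fixture <- function() {
  values <- matrix(c(
    1, 0, 1, 0, 0,
    1, 1, 0, 0, 1,
    0, 0, 1, 1, 0,
    1, 0, 0, 1, 0,
    0, 1, 0, 0, 1), nrow = 5, byrow = TRUE,
    dimnames = list(paste0("D", 1:5), paste0("M", 1:5)))
  association_matrix(values)
}

#' Specification of a planted-block synthetic network
#'
#' Describes a bipartite association network with community structure:
#' diseases and miRNAs are split into blocks, associations are dense within
#' a block and sparse across blocks, and the precomputed similarity matrices
#' carry a configurable amount of the block signal. The defaults define the
#' package's standard recoverability benchmark: 60 diseases x 80 miRNAs in
#' 4 blocks with within-block association probability 0.35 against a 0.02
#' background, priors carrying 70% block signal, seed 7.
#'
#' @param n_diseases,n_mirnas Entity counts, positive.
#' @param n_blocks Number of planted blocks (block sizes differ by at most
#'   1 on each side).
#' @param p_within Association probability inside a block, in (0, 1\].
#' @param p_noise Background association probability, in \[0, 1), strictly
#'   below `p_within`.
#' @param prior_strength Fraction of block signal in the similarity priors,
#'   in \[0, 1\] (the rest is symmetric uniform noise).
#' @param seed Integer seed; the generated network is a pure function of
#'   the spec.
#' @return A `planted_network_spec` list.
#' @export
planted_network_spec <- function(n_diseases = 60L, n_mirnas = 80L,
                                 n_blocks = 4L, p_within = 0.35,
                                 p_noise = 0.02, prior_strength = 0.7,
                                 seed = 7L) {
  if (n_diseases < 1L || n_mirnas < 1L) stop_snmda("entity counts must be positive")
  if (n_blocks < 1L || n_blocks > min(n_diseases, n_mirnas))
    stop_snmda("n_blocks must leave no block empty")
  if (p_within <= 0 || p_within > 1 || p_noise < 0 || p_noise >= 1)
    stop_snmda("probabilities out of range")
  if (p_within <= p_noise) stop_snmda("p_within must exceed p_noise")
  if (prior_strength < 0 || prior_strength > 1)
    stop_snmda("prior_strength must lie in [0, 1]")
  structure(list(n_diseases = as.integer(n_diseases),
                 n_mirnas = as.integer(n_mirnas),
                 n_blocks = as.integer(n_blocks),
                 p_within = p_within, p_noise = p_noise,
                 prior_strength = prior_strength, seed = as.integer(seed)),
            class = "planted_network_spec")
}

sym_noise <- function(n) {
  N <- matrix(stats::runif(n * n), n, n)
  (N + t(N)) / 2
}

#' Generate a planted-block association network with similarity priors
#'
#' Draws the association matrix and block-informed miRNA/disease similarity
#' matrices described by a [planted_network_spec()]. The similarity priors
#' are `prior_strength * same_block + (1 - prior_strength) * noise`,
#' symmetrized, clipped to \[0, 1\], with unit diagonal. Fully determined by
#' the spec (including its seed).
#'
#' @param spec A [planted_network_spec()].
#' @return A list: `A` ([association_matrix()]), `mfs` and `dss`
#'   ([similarity_matrix()] priors), `spec`, and the block assignments
#'   `block_d`, `block_m`.
#' @export
planted_network <- function(spec = planted_network_spec()) {
  nd <- spec$n_diseases; nm <- spec$n_mirnas; nb <- spec$n_blocks
  d_names <- sprintf("D%03d", seq_len(nd))
  m_names <- sprintf("M%03d", seq_len(nm))
  block_d <- rep_len(seq_len(nb), nd)
  block_m <- rep_len(seq_len(nb), nm)
  with_seed(spec$seed, {
    same <- outer(block_d, block_m, "==")
    prob <- ifelse(same, spec$p_within, spec$p_noise)
    A <- matrix(stats::rbinom(nd * nm, 1L, prob), nd, nm,
                dimnames = list(d_names, m_names))
    if (sum(A) == 0L)
      stop_snmda("generated network has no associations; increase p_within")
    prior <- function(block, names) {
      n <- length(block)
      S <- spec$prior_strength * outer(block, block, "==") +
        (1 - spec$prior_strength) * sym_noise(n)
      S <- pmin(pmax(S, 0), 1)
      diag(S) <- 1
      dimnames(S) <- list(names, names)
      similarity_matrix(S, kind = "precomputed")
    }
    mfs <- prior(block_m, m_names)
    dss <- prior(block_d, d_names)
    list(A = association_matrix(A), mfs = mfs, dss = dss, spec = spec,
         block_d = block_d, block_m = block_m)
  })
}

#' Generate a heavy-tailed bipartite association network
#'
#' Emulates the degree regime of real association catalogues, where most
#' entities have very few known links: degrees are drawn from a truncated
#' discrete power law (`P(k)` proportional to `k^-exponent` on
#' `1..max_degree`), stub totals on the two sides are equalised by dropping
#' random stubs from the larger side, stubs are matched by a random
#' permutation (configuration model), and multi-edges are collapsed to a
#' simple bipartite graph -- realised degrees can therefore fall below the
#' drawn ones.
#'
#' @param n_diseases,n_mirnas Entity counts.
#' @param exponent Power-law exponent, `> 1`.
#' @param seed Integer seed.
#' @param max_degree Truncation of the degree law (default: opposite side
#'   size, capped at 50).
#' @return An [association_matrix()].
#' @export
powerlaw_bipartite <- function(n_diseases, n_mirnas, exponent = 2.5, seed = 1L,
                               max_degree = NULL) {
  if (exponent <= 1) stop_snmda("exponent must exceed 1")
  with_seed(seed, {
    draw <- function(n, kmax) {
      k <- seq_len(kmax)
      sample(k, n, replace = TRUE, prob = k^(-exponent))
    }
    for (attempt in 1:10) {
      deg_d <- draw(n_diseases, min(if (is.null(max_degree)) 50L else max_degree,
                                    n_mirnas))
      deg_m <- draw(n_mirnas, min(if (is.null(max_degree)) 50L else max_degree,
                                  n_diseases))
      stubs_d <- rep(seq_len(n_diseases), deg_d)
      stubs_m <- rep(seq_len(n_mirnas), deg_m)
      if (length(stubs_d) > 0L && length(stubs_m) > 0L) break
      warning("degenerate degree sequence, resampling", call. = FALSE)
    }
    n_edge <- min(length(stubs_d), length(stubs_m))
    if (length(stubs_d) > n_edge) stubs_d <- sample(stubs_d, n_edge)
    if (length(stubs_m) > n_edge) stubs_m <- sample(stubs_m, n_edge)
    stubs_m <- sample(stubs_m)
    A <- matrix(0L, n_diseases, n_mirnas,
                dimnames = list(sprintf("D%04d", seq_len(n_diseases)),
                                sprintf("M%04d", seq_len(n_mirnas))))
    A[cbind(stubs_d, stubs_m)] <- 1L
    association_matrix(A)
  })
}

#' Generate a toy disease DAG
#'
#' A rooted tree of the given depth and branching factor (depth 1 is just
#' the root), optionally augmented with extra cross-parents: each node at
#' depth 3 or deeper may, with probability `cross_parent_frac`, acquire an
#' additional parent from at least two levels above it. All extra edges
#' point strictly upward, so the graph stays acyclic by construction.
#'
#' @param depth Number of levels, `>= 1`.
#' @param branching Children per internal node, `>= 1` (1 gives a chain).
#' @param seed Integer seed (only consumed when `cross_parent_frac > 0`).
#' @param cross_parent_frac Probability of an extra cross-parent per
#'   eligible node, in \[0, 1\].
#' @return A [disease_dag()]; nodes are named `t1`, `t2`, ... in
#'   breadth-first order, `t1` the root.
#' @export
toy_dag <- function(depth = 3L, branching = 2L, seed = 1L,
                    cross_parent_frac = 0) {
  if (depth < 1L) stop_snmda("depth must be at least 1")
  if (branching < 1L) stop_snmda("branching must be at least 1")
  level_sizes <- branching^(seq_len(depth) - 1L)
  n <- sum(level_sizes)
  nodes <- paste0("t", seq_len(n))
  level_of <- rep(seq_len(depth), level_sizes)
  first_of <- cumsum(c(1L, utils::head(level_sizes, -1L)))
  parents <- stats::setNames(vector("list", n), nodes)
  for (i in seq_len(n)[level_of > 1L]) {
    lev <- level_of[i]
    off <- i - first_of[lev]                       # 0-based offset in level
    parents[[i]] <- nodes[first_of[lev - 1L] + off %/% branching]
  }
  if (cross_parent_frac > 0) {
    with_seed(seed, {
      for (i in seq_len(n)[level_of >= 3L]) {
        if (stats::runif(1) < cross_parent_frac) {
          pool <- setdiff(nodes[level_of <= level_of[i] - 2L], parents[[i]])
          if (length(pool))
            parents[[i]] <- c(parents[[i]], sample(pool, 1L))
        }
      }
    })
  }
  disease_dag(nodes, parents)
}
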