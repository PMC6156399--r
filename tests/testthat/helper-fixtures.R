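# Shared fixtures and independent oracles for the test suite.

# Small planted network, cheap enough for full-mode (leakage-free) CV.
tiny_planted <- function(seed = 42L) {
  planted_network(planted_network_spec(
    n_diseases = 12L, n_mirnas = 14L, n_blocks = 2L,
    p_within = 0.8, p_noise = 0.05, prior_strength = 0.8, seed = seed))
}

write_edge_list <- function(edges, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(edges, function(e) paste(e, collapse = "\t"), character(1)),
             path)
  path
}

write_dag_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), character(1)),
             path)
  path
}

# --- independent oracles --------------------------------------------------

# Exhaustive ascending-path enumeration: the contribution of ancestor t to
# disease d is max over all ascending paths d -> ... -> t of decay^length.
contrib_oracle <- function(dag, d, decay = 0.5) {
  best <- new.env(parent = emptyenv())
  rec <- function(node, len) {
    cur <- get0(node, envir = best, ifnotfound = -Inf)
    if (decay^len > cur) assign(node, decay^len, envir = best)
    for (p in dag$parents[[node]]) rec(p, len + 1L)
  }
  rec(d, 0L)
  vals <- mget(ls(best), envir = best)
  stats::setNames(as.numeric(vals), names(vals))
}

semantic_oracle <- function(dag, a, b, decay = 0.5) {
  ca <- contrib_oracle(dag, a, decay)
  cb <- contrib_oracle(dag, b, decay)
  sh <- intersect(names(ca), names(cb))
  sum(ca[sh] + cb[sh]) / (sum(ca) + sum(cb))
}

# Random DAG with nodes in topological order (parents always earlier).
random_dag <- function(n, p_edge = 0.4) {
  nodes <- paste0("n", seq_len(n))
  parents <- stats::setNames(vector("list", n), nodes)
  if (n > 1L) for (i in 2:n) {
    cand <- nodes[seq_len(i - 1L)]
    pick <- cand[stats::runif(i - 1L) < p_edge]
    parents[[i]] <- pick
  }
  disease_dag(nodes, parents)
}

# Penalized-lasso objective and the independent convex-program oracle
# (glmnet minimises RSS/(2n) + lambda*||w||_1, so lambda = lam/(2n)).
l1_objective <- function(x, D, w, lam) {
  sum((D %*% w - x)^2) + lam * sum(abs(w))
}

glmnet_oracle <- function(x, D, lam, nonneg = FALSE) {
  n <- length(x)
  fit <- glmnet::glmnet(D, x, lambda = lam / (2 * n), standardize = FALSE,
                        intercept = FALSE, thresh = 1e-14, maxit = 1e7,
                        lower.limits = if (nonneg) 0 else -Inf)
  as.numeric(stats::coef(fit))[-1]
}

# ADMM splitting for the same program (a different algorithm family than the
# coordinate descent under test): w-step is a ridge solve, z-step the L1 prox.
admm_oracle <- function(x, D, lam, nonneg = FALSE, rho = 1, iters = 20000L) {
  p <- ncol(D)
  G <- 2 * crossprod(D)
  c2 <- 2 * crossprod(D, x)
  R <- chol(G + rho * diag(p))
  z <- u <- numeric(p)
  for (i in seq_len(iters)) {
    w <- backsolve(R, forwardsolve(t(R), c2 + rho * (z - u)))
    v <- w + u
    z_new <- if (nonneg) pmax(0, v - lam / rho)
             else sign(v) * pmax(0, abs(v) - lam / rho)
    du <- w - z_new
    if (max(abs(du)) < 1e-13 && max(abs(z_new - z)) < 1e-13) { z <- z_new; break }
    z <- z_new
    u <- u + du
  }
  z
}

# Reference optimum: the better of the two independent solvers.
l1_oracle <- function(x, D, lam, nonneg = FALSE) {
  cand <- list(admm_oracle(x, D, lam, nonneg))
  if (requireNamespace("glmnet", quietly = TRUE) && ncol(D) >= 2)
    cand <- c(cand, list(glmnet_oracle(x, D, lam, nonneg)))
  objs <- vapply(cand, function(w) l1_objective(x, D, w, lam), numeric(1))
  cand[[which.min(objs)]]
}

# Brute-force AUC: fraction of (positive, negative) pairs correctly ordered,
# ties counted one half.
auc_bruteforce <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
  tot / (length(sp) * length(sn))
}
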