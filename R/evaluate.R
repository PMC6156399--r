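#' ROC curve and AUC via the rank statistic
#'
#' AUC is computed as the Mann-Whitney statistic with average ranks for
#' ties, which equals the area under the tie-aware ROC curve obtained by
#' sweeping a threshold over the scores (ties grouped into single curve
#' vertices, traversed diagonally).
#'
#' @param scores Numeric vector of scores (higher = more positive).
#' @param labels Binary vector (0/1), same length; both classes must be
#'   present.
#' @return A list: `auc` (scalar in \[0, 1\]) and `roc` (data frame of
#'   `fpr`, `tpr` points from (0, 0) to (1, 1)).
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_snmda("scores and labels lengths differ")
  if (anyNA(scores) || anyNA(labels)) stop_snmda("NA in scores or labels")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop_snmda("labels must be 0/1")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_snmda("need at least one positive and one negative label")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- cumsum(rle(s)$lengths)     # last index of each tie group
  tpr <- c(0, cumsum(l)[last] / n_pos)
  fpr <- c(0, cumsum(1L - l)[last] / n_neg)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}

cv_result <- function(auc, roc, mode, reps, per_rep_auc, seed = NA_integer_) {
  structure(list(auc = auc, roc = roc, mode = mode, reps = reps,
                 per_rep_auc = per_rep_auc, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: AUC = %.4f (%d rep%s)\n",
              x$mode, x$auc, x$reps, if (x$reps > 1) "s" else ""))
  invisible(x)
}

# Shared machinery: score held-out folds of known associations.
#
# Returns a function(pairs) -> scores where `pairs` is a 2-column matrix of
# (disease row, miRNA col) indices masked *together* as one fold; the whole
# pipeline is re-run on the masked network in "full" mode, while "fast" mode
# keeps the full-data similarity networks and only re-propagates the masked
# label matrix (documented shortcut: the reconstruction then sees the
# held-out edges).
fold_scorer <- function(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode,
                        pipeline_fn, full_run) {
  if (cv_mode == "fast") {
    a <- prop_cfg$alpha
    MS <- as_base_matrix(normalize_similarity(full_run$fms))
    DS <- as_base_matrix(normalize_similarity(full_run$fds))
    P_M <- (1 - a) * solve(diag(nrow(MS)) - a * MS)
    P_D <- (1 - a) * solve(diag(nrow(DS)) - a * DS)
    function(pairs) {
      A_m <- as_base_matrix(A)
      A_m[pairs] <- 0
      F_M <- P_M %*% t(A_m)
      F_D <- P_D %*% A_m
      Ft <- t(prop_cfg$beta * F_M + (1 - prop_cfg$beta) * t(F_D)) # disease x miRNA
      Ft[pairs]
    }
  } else {
    function(pairs) {
      A_m <- as_base_matrix(A)
      A_m[pairs] <- 0
      res <- suppressWarnings(
        pipeline_fn(association_matrix(A_m), mfs, dss, sparse_cfg, prop_cfg))
      t(res$F)[pairs]
    }
  }
}

cv_setup <- function(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode, pipeline_fn,
                     min_pos = 2L) {
  pos <- which(as_base_matrix(A) == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  if (nrow(pos) < min_pos)
    stop_snmda("need at least ", min_pos, " known associations")
  full_run <- suppressWarnings(pipeline_fn(A, mfs, dss, sparse_cfg, prop_cfg))
  scorer <- fold_scorer(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode,
                        pipeline_fn, full_run)
  Ft_full <- t(as_base_matrix(full_run$F))   # disease x miRNA, aligned with A
  list(pos = pos, full_run = full_run, scorer = scorer, Ft_full = Ft_full)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is removed in turn and re-scored by the model
#' trained without it; the held-out scores are pooled with the scores of
#' every never-known (unconfirmed) pair, taken once from the full-data
#' model, and summarised as a single ranking AUC. In `"full"` mode the
#' entire pipeline (reconstruction, fusion, propagation) is re-run per
#' holdout so the masked edge is invisible everywhere; `"fast"` mode reuses
#' the full-data similarity networks and only re-propagates the masked
#' labels, trading a small information leak in the reconstruction step for
#' a large speedup.
#'
#' @param A An [association_matrix()] with at least 2 known associations.
#' @param mfs,dss Precomputed similarity matrices (see [snmda_pipeline()]).
#' @param sparse_cfg A [sparse_config()].
#' @param prop_cfg A [propagation_config()].
#' @param cv_mode `"full"` (leakage-free, default) or `"fast"`.
#' @param pipeline_fn Pipeline function (exposed for instrumentation;
#'   default [snmda_pipeline()]).
#' @return A `cv_result` with `mode = "global_loocv"`.
#' @export
global_loocv <- function(A, mfs, dss,
                         sparse_cfg = sparse_config(),
                         prop_cfg = propagation_config(),
                         cv_mode = c("full", "fast"),
                         pipeline_fn = snmda_pipeline) {
  cv_mode <- match.arg(cv_mode)
  st <- cv_setup(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode, pipeline_fn)
  pos_scores <- vapply(seq_len(nrow(st$pos)), function(i) {
    st$scorer(st$pos[i, , drop = FALSE])
  }, numeric(1))
  neg_scores <- st$Ft_full[as_base_matrix(A) == 0]
  ra <- roc_auc(c(pos_scores, neg_scores),
                c(rep(1L, length(pos_scores)), rep(0L, length(neg_scores))))
  cv_result(ra$auc, ra$roc, "global_loocv", 1L, ra$auc)
}

# Pool per-disease holdout outcomes: each positive contributes its tie-aware
# win fraction u against its own disease's unconfirmed pairs.
local_pool <- function(A, pos, pos_scores, Ft_full) {
  A <- as_base_matrix(A)
  u <- numeric(0)
  skipped <- character(0)
  for (d in seq_len(nrow(A))) {
    in_d <- which(pos[, 1] == d)
    if (length(in_d) == 0L) next
    negs <- Ft_full[d, A[d, ] == 0]
    if (length(negs) == 0L) {
      skipped <- c(skipped, rownames(A)[d])
      next
    }
    u <- c(u, vapply(pos_scores[in_d], function(s) {
      (sum(negs < s) + 0.5 * sum(negs == s)) / length(negs)
    }, numeric(1)))
  }
  if (length(skipped))
    warning("disease(s) with no unconfirmed pairs skipped in local LOOCV: ",
            paste(utils::head(skipped, 5L), collapse = ", "), call. = FALSE)
  if (length(u) == 0L) stop_snmda("no scorable positives for local LOOCV")
  ts <- sort(unique(c(1 - u, 1)))
  roc <- data.frame(fpr = c(0, ts),
                    tpr = c(0, vapply(ts, function(t) mean((1 - u) <= t),
                                      numeric(1))))
  list(auc = mean(u), roc = roc)
}

#' Local leave-one-out cross-validation
#'
#' As [global_loocv()], but each held-out association is ranked only against
#' the unconfirmed pairs of its own disease: every positive contributes its
#' tie-aware win fraction within that disease's candidate list, and the
#' pooled mean of these fractions is the local AUC. This is the harder task
#' (no credit for ranking a disease's candidates above another disease's).
#' Diseases with no unconfirmed pairs are skipped with a warning.
#'
#' @inheritParams global_loocv
#' @return A `cv_result` with `mode = "local_loocv"`.
#' @export
local_loocv <- function(A, mfs, dss,
                        sparse_cfg = sparse_config(),
                        prop_cfg = propagation_config(),
                        cv_mode = c("full", "fast"),
                        pipeline_fn = snmda_pipeline) {
  cv_mode <- match.arg(cv_mode)
  st <- cv_setup(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode, pipeline_fn)
  pos_scores <- vapply(seq_len(nrow(st$pos)), function(i) {
    st$scorer(st$pos[i, , drop = FALSE])
  }, numeric(1))
  lp <- local_pool(A, st$pos, pos_scores, st$Ft_full)
  cv_result(lp$auc, lp$roc, "local_loocv", 1L, lp$auc)
}

#' Repeated k-fold cross-validation
#'
#' The known associations are partitioned uniformly at random into `k`
#' disjoint subsets; each subset is masked in turn, the model is re-run, and
#' the masked pairs are scored against the unconfirmed pairs (full-data
#' scores) to give one pooled AUC per repetition. The final AUC is the mean
#' over repetitions. With `k` equal to the number of known associations and
#' `reps = 1` this reduces exactly to global LOOCV.
#'
#' @inheritParams global_loocv
#' @param k Number of folds, `>= 2`.
#' @param reps Number of random re-partitions to average over.
#' @param seed Integer seed fully determining the fold partitions.
#' @return A `cv_result` with `mode = "kfold"`, carrying `per_rep_auc`.
#' @export
kfold_cv <- function(A, mfs, dss,
                     sparse_cfg = sparse_config(),
                     prop_cfg = propagation_config(),
                     k = 5L, reps = 20L, seed = 1L,
                     cv_mode = c("full", "fast"),
                     pipeline_fn = snmda_pipeline) {
  cv_mode <- match.arg(cv_mode)
  if (k < 2L) stop_snmda("k must be at least 2")
  st <- cv_setup(A, mfs, dss, sparse_cfg, prop_cfg, cv_mode, pipeline_fn,
                 min_pos = as.integer(k))
  n_pos <- nrow(st$pos)
  neg_scores <- st$Ft_full[as_base_matrix(A) == 0]
  all_pos_scores <- NULL
  per_rep <- numeric(reps)
  with_seed(seed, kind = "L'Ecuyer-CMRG", {
    for (r in seq_len(reps)) {
      fold_of <- sample(rep_len(seq_len(k), n_pos))
      pos_scores <- numeric(n_pos)
      for (f in seq_len(k)) {
        idx <- which(fold_of == f)
        if (length(idx) == 0L) next
        pos_scores[idx] <- st$scorer(st$pos[idx, , drop = FALSE])
      }
      ra <- roc_auc(c(pos_scores, neg_scores),
                    c(rep(1L, n_pos), rep(0L, length(neg_scores))))
      per_rep[r] <- ra$auc
      all_pos_scores <- c(all_pos_scores, pos_scores)
    }
  })
  pooled <- roc_auc(c(all_pos_scores, rep(neg_scores, reps)),
                    c(rep(1L, n_pos * reps), rep(0L, length(neg_scores) * reps)))
  cv_result(mean(per_rep), pooled$roc, "kfold", as.integer(reps), per_rep,
            as.integer(seed))
}

#' Chance-level baseline for the cross-validation harness
#'
#' Replaces the model by a uniform-random scorer (every pair scored
#' `runif(1)`) and applies the same pooling as the corresponding LOOCV
#' framework. Useful as a calibration check: the AUC should sit at 0.5 up
#' to sampling noise.
#'
#' @param A An [association_matrix()].
#' @param mode `"global"` or `"local"`.
#' @param seed Integer seed for the random scores.
#' @return A `cv_result`.
#' @export
null_cv <- function(A, mode = c("global", "local"), seed = 1L) {
  mode <- match.arg(mode)
  Av <- as_base_matrix(A)
  pos <- which(Av == 1, arr.ind = TRUE)
  dimnames(pos) <- NULL
  if (nrow(pos) < 2L) stop_snmda("need at least 2 known associations")
  S <- with_seed(seed, kind = "L'Ecuyer-CMRG",
                 matrix(stats::runif(length(Av)), nrow(Av),
                        dimnames = dimnames(Av)))
  if (mode == "global") {
    ra <- roc_auc(c(S[pos], S[Av == 0]),
                  c(rep(1L, nrow(pos)), rep(0L, sum(Av == 0))))
    cv_result(ra$auc, ra$roc, "global_loocv", 1L, ra$auc, as.integer(seed))
  } else {
    lp <- local_pool(A, pos, S[pos], S)
    cv_result(lp$auc, lp$roc, "local_loocv", 1L, lp$auc, as.integer(seed))
  }
}

#' Degree distributions of the association network
#'
#' Tabulates how many known associations each disease (row sums) and each
#' miRNA (column sums) participates in. On real association catalogues both
#' histograms are heavy-tailed: most entities have very few known links,
#' which is the sparsity the reconstruction step exploits.
#'
#' @param A An [association_matrix()].
#' @return A list of two data frames (`disease`, `mirna`), each with columns
#'   `degree` and `count`.
#' @export
degree_distribution <- function(A) {
  Av <- as_base_matrix(A)
  tab <- function(deg) {
    t <- table(deg)
    data.frame(degree = as.integer(names(t)), count = as.integer(t))
  }
  list(disease = tab(rowSums(Av)), mirna = tab(colSums(Av)))
}
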