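test_that("the rank-statistic AUC matches direct cases", {
  expect_identical(roc_auc(c(0.9, 0.1), c(1, 0))$auc, 1)
  expect_identical(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 0, 1))$auc, 0.5)
  expect_identical(roc_auc(c(3, 2, 1, 0), c(1, 0, 1, 0))$auc, 0.75)
  expect_error(roc_auc(c(1, 2), c(1, 1)), "negative label")
})

test_that("AUC equals the brute-force pairwise ordering fraction with ties", {
  withr::with_seed(51, {
    for (rep in 1:100) {
      n <- sample(4:50, 1)
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      labels <- c(1, 0, rbinom(n - 2, 1, 0.4))                 # both classes
      ra <- roc_auc(scores, labels)
      expect_equal(ra$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
      # curve invariants
      expect_identical(c(ra$roc$fpr[1], ra$roc$tpr[1]), c(0, 0))
      expect_identical(c(tail(ra$roc$fpr, 1), tail(ra$roc$tpr, 1)), c(1, 1))
      expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(52, {
    for (rep in 1:5) {
      scores <- runif(40)
      labels <- rbinom(40, 1, 0.3)
      if (sum(labels) %in% c(0, 40)) next
      expect_equal(roc_auc(scores, labels)$auc,
                   as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                  quiet = TRUE,
                                                  direction = "<"))),
                   tolerance = 1e-12)
    }
  })
})

test_that("global LOOCV recovers planted structure and needs two positives", {
  net <- tiny_planted()
  g_fast <- global_loocv(net$A, net$mfs, net$dss, cv_mode = "fast")
  expect_s3_class(g_fast, "cv_result")
  expect_gt(g_fast$auc, 0.7)

  A1 <- association_matrix(matrix(c(1L, 0L), 1, 2,
                                  dimnames = list("d", c("m1", "m2"))))
  expect_error(global_loocv(A1, NULL, NULL), "at least 2")
})

test_that("fast mode equals explicit re-propagation of masked labels", {
  net <- tiny_planted()
  full <- suppressWarnings(snmda_pipeline(net$A, net$mfs, net$dss))
  cfg <- propagation_config()
  MS <- normalize_similarity(full$fms)
  DS <- normalize_similarity(full$fds)
  pos <- which(unclass(net$A) == 1, arr.ind = TRUE)[1:3, , drop = FALSE]
  scorer <- snmda:::fold_scorer(net$A, net$mfs, net$dss, sparse_config(), cfg,
                                "fast", snmda_pipeline, full)
  for (i in 1:3) {
    pair <- pos[i, , drop = FALSE]
    A_m <- unclass(net$A) + 0
    A_m[pair] <- 0
    F_M <- propagate_labels(MS, t(A_m), cfg)
    F_D <- propagate_labels(DS, A_m, cfg)
    manual <- (cfg$beta * F_M + (1 - cfg$beta) * t(F_D))[pair[2], pair[1]]
    expect_equal(scorer(pair), manual, tolerance = 1e-10)
  }
})

test_that("full-mode cross-validation never shows the pipeline a masked edge", {
  net <- tiny_planted()
  seen <- list()
  recorder <- function(A, mfs, dss, sparse_cfg, prop_cfg) {
    seen[[length(seen) + 1]] <<- unclass(A)
    snmda_pipeline(A, mfs, dss, sparse_cfg, prop_cfg)
  }
  g <- global_loocv(net$A, net$mfs, net$dss, cv_mode = "full",
                    pipeline_fn = recorder)
  pos <- which(unclass(net$A) == 1, arr.ind = TRUE)
  expect_length(seen, nrow(pos) + 1L)        # full run + one per holdout
  for (i in seq_len(nrow(pos)))
    expect_identical(seen[[i + 1L]][pos[i, 1], pos[i, 2]], 0L)
  # and full mode agrees with itself on rerun (pure determinism)
  g2 <- global_loocv(net$A, net$mfs, net$dss, cv_mode = "full")
  expect_identical(g$auc, g2$auc)
})

test_that("local LOOCV pools within diseases and skips saturated ones", {
  net <- tiny_planted()
  l <- local_loocv(net$A, net$mfs, net$dss, cv_mode = "fast")
  g <- global_loocv(net$A, net$mfs, net$dss, cv_mode = "fast")
  expect_true(l$auc >= 0 && l$auc <= 1)
  expect_identical(c(l$roc$fpr[1], l$roc$tpr[1]), c(0, 0))
  expect_identical(c(tail(l$roc$fpr, 1), tail(l$roc$tpr, 1)), c(1, 1))

  # a disease with every miRNA known has no unconfirmed pairs to rank against
  A <- unclass(net$A) + 0L
  A[1, ] <- 1L
  A_sat <- association_matrix(A)
  expect_warning(local_loocv(A_sat, net$mfs, net$dss, cv_mode = "fast"),
                 "skipped")
})

test_that("k-fold with singleton folds degenerates to global LOOCV", {
  net <- tiny_planted()
  n_pos <- sum(net$A)
  g <- global_loocv(net$A, net$mfs, net$dss, cv_mode = "fast")
  kf <- kfold_cv(net$A, net$mfs, net$dss, k = n_pos, reps = 1, seed = 9,
                 cv_mode = "fast")
  expect_equal(kf$auc, g$auc, tolerance = 1e-12)
  expect_error(kfold_cv(net$A, net$mfs, net$dss, k = 1), "at least 2")
})

test_that("repeated k-fold is seed-reproducible with per-rep bookkeeping", {
  net <- tiny_planted()
  k1 <- kfold_cv(net$A, net$mfs, net$dss, k = 5, reps = 3, seed = 7,
                 cv_mode = "fast")
  k2 <- kfold_cv(net$A, net$mfs, net$dss, k = 5, reps = 3, seed = 7,
                 cv_mode = "fast")
  expect_identical(k1$per_rep_auc, k2$per_rep_auc)
  expect_length(k1$per_rep_auc, 3L)
  expect_equal(k1$auc, mean(k1$per_rep_auc))
  k3 <- kfold_cv(net$A, net$mfs, net$dss, k = 5, reps = 3, seed = 8,
                 cv_mode = "fast")
  expect_false(identical(k1$per_rep_auc, k3$per_rep_auc))
})

test_that("degree histograms satisfy the handshake identity", {
  A <- figure2_fixture()
  dd <- degree_distribution(A)
  expect_identical(sum(dd$disease$degree * dd$disease$count),
                   sum(dd$mirna$degree * dd$mirna$count))
  expect_identical(sum(dd$disease$degree * dd$disease$count), sum(A))
  empty <- association_matrix(matrix(0L, 2, 2,
                                     dimnames = list(c("d1", "d2"),
                                                     c("m1", "m2"))))
  de <- degree_distribution(empty)
  expect_identical(de$disease$degree, 0L)
  expect_identical(de$disease$count, 2L)
})
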