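rand_sim <- function(n) {
  S <- matrix(runif(n * n), n)
  S <- (S + t(S)) / 2
  nm <- paste0("e", seq_len(n))
  dimnames(S) <- list(nm, nm)
  similarity_matrix(S)
}

test_that("symmetric degree normalization preserves the fixed points", {
  flip <- similarity_matrix(matrix(c(0, 1, 1, 0), 2,
                                   dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(unclass(normalize_similarity(flip)),
               matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)
  eye <- similarity_matrix(matrix(diag(3), 3,
                                  dimnames = list(letters[1:3], letters[1:3])))
  expect_equal(unclass(normalize_similarity(eye)), diag(3), ignore_attr = TRUE)
})

test_that("normalization bounds the spectral radius by one", {
  withr::with_seed(41, {
    for (rep in 1:10) {
      MS <- normalize_similarity(rand_sim(6))
      rho <- max(abs(eigen(unclass(MS), symmetric = TRUE,
                           only.values = TRUE)$values))
      expect_lte(rho, 1 + 1e-10)
    }
  })
})

test_that("zero-degree rows survive normalization untouched", {
  S <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  S[1, 2] <- S[2, 1] <- 1
  MS <- normalize_similarity(similarity_matrix(S))
  expect_identical(unname(MS[3, ]), c(0, 0, 0))
  Y <- matrix(1, 3, 2, dimnames = list(letters[1:3], NULL))
  F <- propagate_labels(MS, Y, propagation_config(alpha = 0.4))
  # the isolated node's score comes entirely from its injected label
  expect_equal(unname(F[3, ]), c(0.6, 0.6))
})

test_that("iterative propagation matches the closed-form solve", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      MS <- normalize_similarity(rand_sim(8))
      Y <- matrix(runif(8 * 3), 8,
                  dimnames = list(rownames(MS), NULL))
      it <- propagate_labels(MS, Y, propagation_config(alpha = 0.5, tol = 1e-12,
                                                       max_iter = 5000,
                                                       mode = "iterative"))
      cf <- propagate_labels(MS, Y, propagation_config(alpha = 0.5))
      expect_lt(max(abs(it - cf)), 1e-8)
    }
  })
})

test_that("the iteration error contracts at least geometrically at rate alpha", {
  withr::with_seed(43, {
    alpha <- 0.5
    MS <- unclass(normalize_similarity(rand_sim(8)))
    Y <- matrix(runif(8 * 2), 8)
    Fstar <- solve(diag(8) - alpha * MS, (1 - alpha) * Y)
    F <- Y
    err <- sqrt(sum((F - Fstar)^2))
    for (t in 1:30) {
      F <- alpha * MS %*% F + (1 - alpha) * Y
      err_new <- sqrt(sum((F - Fstar)^2))
      if (err > 1e-13) expect_lte(err_new, alpha * err + 1e-12)
      err <- err_new
    }
    expect_lt(err, 1e-8)
  })
})

test_that("degenerate parameter limits reproduce the labels", {
  MS <- normalize_similarity(rand_sim(5))
  Y <- matrix(withr::with_seed(44, runif(5 * 2)), 5,
              dimnames = list(rownames(MS), NULL))
  near0 <- propagate_labels(MS, Y, propagation_config(alpha = 1e-12))
  expect_lt(max(abs(near0 - Y)), 1e-9)

  Z <- similarity_matrix(matrix(0, 4, 4, dimnames = list(letters[1:4],
                                                         letters[1:4])),
                         kind = "normalized")
  Y4 <- matrix(1, 4, 1, dimnames = list(letters[1:4], NULL))
  expect_equal(unname(propagate_labels(Z, Y4,
                                       propagation_config(alpha = 0.3))[, 1]),
               rep(0.7, 4))
})

test_that("unnormalized networks and exhausted iteration budgets error", {
  S <- rand_sim(4) # raw similarity: spectral radius far above 1
  Y <- matrix(1, 4, 1)
  expect_error(propagate_labels(S, Y, propagation_config()),
               "spectral radius")
  MS <- normalize_similarity(withr::with_seed(45, rand_sim(6)))
  Y6 <- matrix(withr::with_seed(46, runif(6)), 6)
  expect_error(propagate_labels(MS, Y6,
                                propagation_config(alpha = 0.9, tol = 1e-14,
                                                   max_iter = 3,
                                                   mode = "iterative")),
               "did not converge.*residual")
})

test_that("beta selects between the two propagation sides exactly", {
  net <- tiny_planted()
  rms <- reconstruct_similarity(interaction_profiles(net$A, "mirna"))$similarity
  rds <- reconstruct_similarity(interaction_profiles(net$A, "disease"))$similarity
  fms <- fuse_similarity(rms, net$mfs)
  fds <- fuse_similarity(rds, net$dss)
  F_M <- propagate_labels(normalize_similarity(fms), t(unclass(net$A)),
                          propagation_config())
  F_D <- propagate_labels(normalize_similarity(fds), unclass(net$A) + 0,
                          propagation_config())
  b1 <- snmda_predict(net$A, fms, fds, propagation_config(beta = 1))
  b0 <- snmda_predict(net$A, fms, fds, propagation_config(beta = 0))
  expect_equal(unclass(b1), F_M, ignore_attr = TRUE)
  expect_equal(unclass(b0), t(F_D), ignore_attr = TRUE)
})

test_that("identity similarities turn prediction into label recovery", {
  A <- figure2_fixture()
  eye_m <- similarity_matrix(matrix(diag(5), 5,
                                    dimnames = list(colnames(A), colnames(A))))
  eye_d <- similarity_matrix(matrix(diag(5), 5,
                                    dimnames = list(rownames(A), rownames(A))))
  F <- snmda_predict(A, eye_m, eye_d, propagation_config(alpha = 0.5, beta = 0.5))
  # (1-a)(I - a I)^{-1} = I, so both sides return Y and F = t(A)
  expect_equal(unclass(F), t(unclass(A)) + 0, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("propagation configuration validates its ranges", {
  expect_error(propagation_config(alpha = 1), "strictly between")
  expect_error(propagation_config(beta = 2), "0, 1")
  expect_error(propagation_config(tol = 0), "positive")
})
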