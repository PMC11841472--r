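probs_of <- function(params, design)
  mncm_probabilities(mncm_tendencies(params, design), design)

test_that("ability centering shifts intercepts by the compensating amount", {
  # already centered: nothing changes
  fx <- rand_params(S = 6, I = 3, C = 4, D = 2, seed = 1)
  fx$params$Theta <- sweep(fx$params$Theta, 2, colMeans(fx$params$Theta))
  out <- center_abilities(fx$params)
  expect_equal(out$b, fx$params$b, tolerance = 1e-12)
  # direct substitution: D = 1, mean ability 0.5, slope 2 -> delta b = 1
  d <- mncm_design(1, 2)
  p <- mncm_params(matrix(2, 1, 2), c(0, 0), matrix(c(0, 1), 2, 1), d)
  out2 <- center_abilities(p)
  expect_equal(out2$b, c(1, 1), tolerance = 1e-12)
  expect_equal(colMeans(out2$Theta), 0, tolerance = 1e-12, ignore_attr = TRUE)
  # invariance oracle: tendencies unchanged on a random instance
  fx3 <- rand_params(S = 7, I = 4, C = 5, D = 3, seed = 3)
  t_before <- mncm_tendencies(fx3$params, fx3$design)
  out3 <- center_abilities(fx3$params)
  expect_lt(max(abs(colMeans(out3$Theta))), 1e-12)
  expect_equal(mncm_tendencies(out3, fx3$design), t_before, tolerance = 1e-10)
})

test_that("category constraints zero the reference and preserve probabilities", {
  fx <- rand_params(S = 5, I = 3, C = 4, D = 2, seed = 6)
  p0 <- probs_of(fx$params, fx$design)
  # deviation constraints: per-item means zero, idempotent
  dev <- apply_category_constraints(fx$params, fx$design, "deviation")
  for (i in 1:3) {
    cols <- ((i - 1) * 4 + 1):(i * 4)
    expect_lt(max(abs(rowMeans(dev$A[, cols]))), 1e-12)
    expect_lt(abs(mean(dev$b[cols])), 1e-12)
  }
  dev2 <- apply_category_constraints(dev, fx$design, "deviation")
  expect_equal(dev2$A, dev$A, tolerance = 1e-12)
  expect_equal(probs_of(dev, fx$design), p0, tolerance = 1e-10)
  # simple constraints: correct category exactly zero
  key <- c(2L, 1L, 4L)
  dk <- mncm_design(3, 4, correct = key)
  simp <- apply_category_constraints(fx$params, dk, "simple")
  for (i in 1:3) {
    j <- (i - 1) * 4 + key[i]
    expect_identical(unname(simp$A[, j]), rep(0, 2))
    expect_identical(simp$b[j], 0)
  }
  expect_equal(probs_of(simp, dk), p0, tolerance = 1e-10)
  # missing key under simple mode is a configuration error
  expect_error(apply_category_constraints(fx$params, fx$design, "simple"),
               "answer key")
})

test_that("whitening yields identity ability covariance and ordered slopes", {
  # construct a 2-D instance with strongly correlated abilities
  set.seed(14)
  d <- mncm_design(6, 5)
  L <- matrix(c(1, 0.8, 0, 0.6), 2)
  Theta <- matrix(rnorm(400), 200) %*% L
  A <- matrix(rnorm(60, 0, 0.8), 2, 30)
  p <- mncm_params(A, rnorm(30), Theta, d)
  p <- center_abilities(p)
  p <- apply_category_constraints(p, d, "deviation")
  t_before <- mncm_tendencies(p, d)
  w <- whiten_and_order(p, NULL, "deviation")
  Xc <- sweep(w$params$Theta, 2, colMeans(w$params$Theta))
  expect_lt(max(abs(crossprod(Xc) / nrow(Xc) - diag(2))), 1e-8)
  lam <- diag(w$cov_A)
  expect_true(all(diff(lam) <= 1e-12))
  expect_equal(mncm_tendencies(w$params, d), t_before, tolerance = 1e-8)
  # an input already satisfying the constraints maps to itself (up to sign)
  w2 <- whiten_and_order(w$params, NULL, "deviation")
  expect_equal(abs(w2$M), diag(2), tolerance = 1e-6)
  expect_equal(w2$params$A, w$params$A, tolerance = 1e-6)
})

test_that("singular ability covariance is reported as rank deficiency", {
  d <- mncm_design(3, 4)
  Theta <- cbind(rnorm(50), 0)  # dimension 2 has no variance
  p <- mncm_params(matrix(rnorm(24), 2), rnorm(12), Theta, d)
  expect_error(whiten_and_order(center_abilities(p), NULL), "singular")
})

test_that("pruning removes only collapsed dimensions", {
  fx <- rand_params(S = 30, I = 4, C = 5, D = 3, seed = 9)
  fx$params$A[2, ] <- 0
  fit <- list(params = fx$params, cov_A = diag(c(3, 0, 1)), uncertainty = NULL)
  out <- prune_dimensions(fit, threshold = 0.005)
  expect_equal(out$D_hat, 2L)
  expect_equal(nrow(out$params$A), 2L)
  expect_equal(ncol(out$params$Theta), 2L)
  expect_equal(diag(out$cov_A), c(3, 1))
  # nothing pruned when all norms exceed the threshold
  fx2 <- rand_params(S = 30, I = 4, C = 5, D = 3, seed = 10)
  out2 <- prune_dimensions(list(params = fx2$params, cov_A = diag(3),
                                uncertainty = NULL), 0.005)
  expect_equal(out2$D_hat, 3L)
  # pruning everything returns a zero-dimension fit with a warning
  fx2$params$A[] <- 0
  expect_warning(out3 <- prune_dimensions(list(params = fx2$params,
                                               cov_A = diag(3),
                                               uncertainty = NULL), 0.005),
                 "zero-dimension")
  expect_equal(out3$D_hat, 0L)
})

test_that("identification preserves probabilities and is idempotent", {
  set.seed(21)
  fx <- rand_params(S = 80, I = 5, C = 4, D = 3, seed = 21)
  sds <- list(Theta = matrix(runif(240, 0.05, 0.3), 80, 3),
              A = matrix(runif(60, 0.02, 0.2), 3, 20),
              b = runif(20, 0.02, 0.2))
  est <- list(params = fx$params, sds = sds)
  p0 <- probs_of(fx$params, fx$design)
  fit1 <- identify_fit(est, fx$design, mode = "deviation")
  p1 <- probs_of(mncm_params(fit1$A, fit1$b, fit1$Theta, fx$design), fx$design)
  expect_equal(p1, p0, tolerance = 1e-8)
  # re-running the composition on the identified fit is a no-op
  est2 <- list(params = mncm_params(fit1$A, fit1$b, fit1$Theta, fx$design),
               sds = NULL, uncertainty = fit1$uncertainty)
  fit2 <- identify_fit(est2, fx$design, mode = "deviation")
  expect_equal(fit2$A, fit1$A, tolerance = 1e-8)
  expect_equal(fit2$b, fit1$b, tolerance = 1e-8)
  expect_equal(fit2$Theta, fit1$Theta, tolerance = 1e-8)
  expect_equal(fit2$D_hat, fit1$D_hat)
})

test_that("identified fits satisfy the stated structural invariants", {
  set.seed(33)
  fx <- rand_params(S = 60, I = 6, C = 4, D = 3, seed = 33)
  key <- sample(1:4, 6, replace = TRUE)
  dk <- mncm_design(6, 4, correct = key)
  est <- list(params = fx$params, sds = NULL)
  fit <- identify_fit(est, dk, mode = "simple")
  expect_lt(max(abs(colMeans(fit$Theta))), 1e-10)
  Xc <- fit$Theta
  expect_lt(max(abs(crossprod(Xc) / nrow(Xc) - diag(fit$D_hat))), 1e-8)
  expect_true(all(diff(diag(fit$cov_A)) <= 1e-12))
  for (i in 1:6) {
    j <- (i - 1) * 4 + key[i]
    expect_lt(max(abs(fit$A[, j])), 1e-10)
    expect_lt(abs(fit$b[j]), 1e-10)
  }
})
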