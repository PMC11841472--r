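test_that("the log joint matches a term-by-term hand computation", {
  # 2 respondents x 2 items, C = 3, D = 2, everything at zero, unit scales
  d <- mncm_design(2, 3)
  S <- 2; D <- 2; IC <- 6
  p <- mncm_params(matrix(0, D, IC), rep(0, IC), matrix(0, S, D), d)
  R <- matrix(1L, S, 2)
  pr <- mncm_prior()
  # independent oracle: half-Cauchy via the folded Cauchy density, normal
  # terms via dnorm, likelihood = S * I * log(1/C)
  lp_hc <- function(x, s) log(2) + dcauchy(x, 0, s, log = TRUE)
  expected <- 2 * lp_hc(1, 5) + lp_hc(1, 5) +
    (D * IC + IC) * dnorm(0, 0, 1, log = TRUE) +
    S * D * dnorm(0, log = TRUE) + S * 2 * log(1 / 3)
  got <- mncm_log_joint(R, d, pr, p, alpha = c(1, 1), beta = 1)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("the prior factorizes over dimensions and scales", {
  fx <- rand_params(S = 3, I = 2, C = 3, D = 2, seed = 2)
  R <- matrix(2L, 3, 2)
  pr <- mncm_prior()
  base <- mncm_log_joint(R, fx$design, pr, fx$params, c(1, 1), 1.2)
  moved <- mncm_log_joint(R, fx$design, pr, fx$params, c(2, 1), 1.2)
  # doubling alpha_1 changes only dimension 1's slope-prior and its own
  # half-Cauchy term; verify against the analytic difference
  lp_hc <- function(x, s) log(2) + dcauchy(x, 0, s, log = TRUE)
  a1 <- fx$params$A[1, ]
  delta <- (sum(dnorm(a1, 0, 2, log = TRUE)) - sum(dnorm(a1, 0, 1, log = TRUE))) +
    (lp_hc(2, 5) - lp_hc(1, 5))
  expect_equal(moved - base, delta, tolerance = 1e-10)
  # the log joint decays as any single ability grows without bound
  vals <- sapply(c(1, 5, 25), function(v) {
    pp <- fx$params; pp$Theta[2, 1] <- v
    mncm_log_joint(R, fx$design, pr, pp, c(1, 1), 1.2)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("surrogate-space evaluation includes the softplus Jacobian", {
  fx <- rand_params(S = 3, I = 2, C = 3, D = 2, seed = 4)
  R <- matrix(1L, 3, 2)
  pr <- mncm_prior()
  u <- c(0.3, -1.2); v <- 0.5
  sp <- function(x) log1p(exp(x))
  direct <- mncm_log_joint(R, fx$design, pr, fx$params, sp(u), sp(v))
  jac <- sum(plogis(u, log.p = TRUE)) + plogis(v, log.p = TRUE)
  expect_equal(mncm_log_joint(R, fx$design, pr, fx$params, u, v,
                              surrogate = TRUE),
               direct + jac, tolerance = 1e-10)
})

test_that("posterior initialization follows the configured scheme", {
  spec <- synthesis_spec(S_levels = 300, I = 10, C = 4, D = 1, gamma = 1,
                         base_seed = 6)
  truth <- synthesize_dataset(spec, 1)
  R <- truth$R[["300"]]
  ctrl <- mncm_control(D = 3, seed = 5)
  init <- mncm_init(R, truth$design, ctrl)
  # all posterior SDs start at 0.1 regardless of method
  expect_true(all(init$theta_sd == 0.1) && all(init$a_sd == 0.1) &&
                all(init$b_sd == 0.1) && all(init$u_sd == 0.1) &&
                init$v_sd == 0.1)
  # heuristic slope initialization correlates with the true slopes on
  # unidimensional data (after sign alignment)
  r <- cor(init$a_mu[1, ], truth$A[1, ])
  expect_gt(abs(r), 0.3)
  expect_true(all(init$a_mu[2:3, ] == 0))
  # random init is reproducible for a fixed seed
  ctrl_r <- mncm_control(D = 3, seed = 5, init_method = "random")
  i1 <- mncm_init(R, truth$design, ctrl_r)
  i2 <- mncm_init(R, truth$design, ctrl_r)
  expect_identical(i1$theta_mu, i2$theta_mu)
  expect_false(identical(i1$theta_mu, init$theta_mu))
  # degenerate data falls back to random initialization with a warning
  R_const <- matrix(1L, 50, 10)
  expect_warning(mncm_init(R_const, truth$design, ctrl), "random")
})

test_that("the ELBO lower-bounds the quadrature log marginal on a toy", {
  # 2 respondents, 2 items, C = 2, D = 1; item parameters held fixed, so the
  # marginal likelihood is a per-respondent integral over theta
  d <- mncm_design(2, 2)
  A <- matrix(c(0.9, -0.9, 1.4, -1.4), 1)
  b <- c(0.3, -0.3, -0.2, 0.2)
  R <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  log_marg <- sum(sapply(1:2, function(s) {
    f <- function(th) sapply(th, function(t1) {
      p <- mncm_params(A, b, matrix(t1, 1, 1), d)
      exp(mncm_loglik(R[s, , drop = FALSE], p, d)) * dnorm(t1)
    })
    log(integrate(f, -9, 9, rel.tol = 1e-10)$value)
  }))
  # several arbitrary mean-field posteriors, all bounded above by log p(R)
  for (seed in 1:4) {
    set.seed(seed)
    q <- list(theta_mu = matrix(rnorm(2, 0, 0.8), 2, 1),
              theta_sd = matrix(runif(2, 0.3, 1.2), 2, 1))
    el <- mncm_elbo(q, R, d, n_samples = 4000, seed = seed,
                    fix_items = list(A = A, b = b))
    expect_lt(el, log_marg + 0.02)  # small MC allowance
  }
  # the variational optimum cannot exceed the bound either: check a posterior
  # close to the true per-respondent conditional
  q_opt <- list(theta_mu = matrix(c(0.4, -0.4), 2, 1),
                theta_sd = matrix(0.8, 2, 1))
  el_opt <- mncm_elbo(q_opt, R, d, n_samples = 4000, seed = 9,
                      fix_items = list(A = A, b = b))
  expect_lt(el_opt, log_marg + 0.02)
})

test_that("SVI is deterministic, improves the ELBO, and reports estimates", {
  spec <- synthesis_spec(S_levels = 200, I = 8, C = 4, D = 1, gamma = 1,
                         base_seed = 12)
  truth <- synthesize_dataset(spec, 1)
  R <- truth$R[["200"]]
  ctrl <- mncm_control(D = 2, n_steps = 800, seed = 31)
  p1 <- mncm_svi(R, truth$design, mncm_prior(), ctrl)
  p2 <- mncm_svi(R, truth$design, mncm_prior(), ctrl)
  expect_identical(p1$theta_mu, p2$theta_mu)
  expect_identical(p1$elbo, p2$elbo)
  expect_true(all(is.finite(p1$elbo)))
  # optimization makes clear progress
  expect_gt(mean(tail(p1$elbo, 80)), mean(head(p1$elbo, 80)) + 100)
  # smoothed trace over the final 10% is non-decreasing within noise
  tail_idx <- seq(floor(0.9 * length(p1$elbo)), length(p1$elbo))
  slope <- coef(lm(p1$elbo[tail_idx] ~ tail_idx))[2]
  expect_gt(slope, -1)
  # estimates: layout round trip and positive scales
  est <- mncm_estimates(p1)
  expect_identical(est$params$A, p1$a_mu)
  expect_identical(est$params$Theta, p1$theta_mu)
  expect_identical(est$sds$b, p1$b_sd)
  expect_true(all(est$alpha > 0) && est$beta > 0)
})

test_that("the C++ objective agrees with the R Monte-Carlo ELBO", {
  spec <- synthesis_spec(S_levels = 60, I = 4, C = 3, D = 1, gamma = 1,
                         base_seed = 3)
  truth <- synthesize_dataset(spec, 1)
  R <- truth$R[["60"]]
  ctrl <- mncm_control(D = 2, n_steps = 400, seed = 8)
  post <- mncm_svi(R, truth$design, mncm_prior(), ctrl)
  cpp_end <- mean(tail(post$elbo, 60))
  r_est <- mncm_elbo(post, R, truth$design, mncm_prior(),
                     n_samples = 600, seed = 4)
  # both estimate the same bound; agreement within Monte-Carlo noise
  expect_lt(abs(cpp_end - r_est), 0.05 * abs(r_est) + 5)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(mncm_control(D = 0), "positive")
  expect_error(mncm_control(D = 2, n_steps = 0), "n_steps")
  expect_error(mncm_control(D = 2, lr_peak = -1), "lr_peak")
  expect_error(mncm_prior(slope_scale = 0), "positive")
})
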