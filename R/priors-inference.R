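#' Hierarchical prior specification
#'
#' The model places half-Cauchy priors on the per-dimension slope scale
#' `alpha_d` and the intercept scale `beta`, conditionally normal priors on
#' slopes and intercepts given those scales, and a standard-normal prior on
#' every ability:
#' \deqn{\alpha_d, \beta \sim \mathrm{HalfCauchy}(5),\quad
#'       a_d^{(i,c)} \sim N(0, \alpha_d),\quad
#'       b^{(i,c)} \sim N(0, \beta),\quad
#'       \theta_s^{(d)} \sim N(0, 1).}
#' The half-Cauchy scale 5 is the default; it is exposed for sensitivity
#' analysis only.
#'
#' @param slope_scale Half-Cauchy scale for each `alpha_d` (default 5).
#' @param intercept_scale Half-Cauchy scale for `beta` (default 5).
#' @return An object of class `mncm_prior`.
#' @export
mncm_prior <- function(slope_scale = 5, intercept_scale = 5) {
  if (slope_scale <= 0 || intercept_scale <= 0) stop("prior scales must be positive")
  structure(list(slope_scale = slope_scale, intercept_scale = intercept_scale),
            class = "mncm_prior")
}

#' Fitting configuration for stochastic variational inference
#'
#' Defaults follow the method's reference settings: a learning rate decaying from
#' 0.05 to zero over a predetermined 30,000-step schedule, posterior standard
#' deviations initialized to 0.1, and a fast heuristic initialization of the
#' posterior means with a random fallback.
#'
#' @param D Maximum number of latent dimensions to fit.
#' @param n_steps Number of optimizer steps (default 30000).
#' @param lr_peak Initial learning rate (default 0.05).
#' @param lr_schedule One of `"linear"` (default), `"cosine"`, `"constant"`.
#'   Only the endpoints of the schedule are prescribed; linear decay is the simplest
#'   curve consistent with "0.05 to zero".
#' @param elbo_samples Monte-Carlo samples per ELBO gradient step (default 1).
#' @param seed Integer seed controlling initialization and the stochastic
#'   gradient stream.
#' @param init_method `"heuristic"` (default) or `"random"`.
#' @param init_posterior_sd Initial posterior SD for every variable
#'   (default 0.1).
#' @return An object of class `mncm_control`.
#' @export
mncm_control <- function(D, n_steps = 30000L, lr_peak = 0.05,
                         lr_schedule = c("linear", "cosine", "constant"),
                         elbo_samples = 1L, seed = 1L,
                         init_method = c("heuristic", "random"),
                         init_posterior_sd = 0.1) {
  D <- as.integer(D); n_steps <- as.integer(n_steps)
  if (is.na(D) || D < 1L) stop("D must be a positive integer")
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (lr_peak <= 0) stop("lr_peak must be positive")
  if (init_posterior_sd <= 0) stop("init_posterior_sd must be positive")
  structure(list(D = D, n_steps = n_steps, lr_peak = lr_peak,
                 lr_schedule = match.arg(lr_schedule),
                 elbo_samples = as.integer(elbo_samples),
                 seed = as.integer(seed),
                 init_method = match.arg(init_method),
                 init_posterior_sd = init_posterior_sd),
            class = "mncm_control")
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

#' Log joint density of the hierarchical MNCM
#'
#' Evaluates the unnormalized log posterior (log prior plus log likelihood)
#' at a full parameter assignment.  Scale parameters are given on their
#' positive scale; set `surrogate = TRUE` to evaluate instead in the
#' unconstrained surrogate space used by the variational family, where
#' `alpha = softplus(u)` and the log-Jacobian of the bijection is included.
#'
#' @param R Integer response matrix.
#' @param design An [mncm_design()].
#' @param prior An [mncm_prior()].
#' @param params An [mncm_params()] assignment.
#' @param alpha Positive slope-scale vector (length `D`), or surrogate `u`
#'   when `surrogate = TRUE`.
#' @param beta Positive intercept scale, or surrogate `v`.
#' @param surrogate Logical; interpret `alpha`, `beta` as unconstrained
#'   surrogates.
#' @return Scalar log joint density.
#' @export
mncm_log_joint <- function(R, design, prior, params, alpha, beta,
                           surrogate = FALSE) {
  D <- nrow(params$A); IC <- design$I * design$C
  if (length(alpha) != D) stop("alpha must have one entry per dimension")
  jac <- 0
  if (surrogate) {
    u <- alpha; v <- beta
    alpha <- softplus(u); beta <- softplus(v)
    # log |d alpha / d u| = log sigmoid(u)
    jac <- sum(stats::plogis(u, log.p = TRUE)) + stats::plogis(v, log.p = TRUE)
  }
  if (any(alpha <= 0) || beta <= 0) stop("scales must be positive")
  lp_hc <- function(x, s) log(2 / (pi * s)) - log1p((x / s)^2)
  lp <- sum(lp_hc(alpha, prior$slope_scale)) + lp_hc(beta, prior$intercept_scale) + jac
  lp <- lp + sum(stats::dnorm(params$A, 0, rep(alpha, IC), log = TRUE))
  lp <- lp + sum(stats::dnorm(params$b, 0, beta, log = TRUE))
  lp <- lp + sum(stats::dnorm(params$Theta, log = TRUE))
  lp + mncm_loglik(R, params, design)
}

#' Initialize the variational posterior
#'
#' Posterior SDs for every variable start at `init_posterior_sd` (0.1 by
#' default).  Under the heuristic method, posterior means are seeded from a
#' cheap one-dimensional IRT-style approximation: respondents are scored
#' (number-correct when an answer key is available, otherwise the first
#' principal component of the centered category-indicator matrix), the
#' z-scored totals initialize the first ability dimension, the correlation of
#' each category indicator with the score initializes the first slope row,
#' and centered log observed category frequencies initialize the intercepts.
#' All remaining means start at zero.  Degenerate data (zero score variance)
#' triggers a warning and a silent fallback to random initialization.
#'
#' @param R Integer response matrix.
#' @param design An [mncm_design()].
#' @param control An [mncm_control()].
#' @return List of posterior mean/SD arrays (class `mncm_posterior`).
#' @export
mncm_init <- function(R, design, control) {
  R <- validate_responses(R, design)
  S <- nrow(R); IC <- design$I * design$C; D <- control$D
  sd0 <- control$init_posterior_sd
  random_init <- function() {
    with_seed(child_seed(control$seed, 11L), list(
      theta_mu = matrix(stats::rnorm(S * D, 0, 0.1), S, D),
      a_mu = matrix(stats::rnorm(D * IC, 0, 0.1), D, IC),
      b_mu = stats::rnorm(IC, 0, 0.1)))
  }
  mu <- NULL
  if (control$init_method == "heuristic") {
    mu <- tryCatch({
      X <- indicator_matrix(R, design)          # S x IC in {0,1}, NA rows -> 0
      f <- colMeans(X)
      if (!is.null(design$correct)) {
        score <- rowSums(X[, (seq_len(design$I) - 1L) * design$C + design$correct,
                           drop = FALSE])
      } else {
        Xc <- sweep(X, 2L, f)
        pc1 <- eigen(crossprod(Xc) / S, symmetric = TRUE)$vectors[, 1L]
        if (pc1[which.max(abs(pc1))] < 0) pc1 <- -pc1
        score <- drop(Xc %*% pc1)
      }
      if (stats::sd(score) < 1e-12) stop("degenerate scores")
      z <- (score - mean(score)) / stats::sd(score)
      a1 <- suppressWarnings(apply(X, 2L, function(col) stats::cor(col, z)))
      a1[!is.finite(a1)] <- 0
      logf <- log(pmax(f, 1e-6))
      bm <- as.numeric(logf - rep(tapply(logf, rep(seq_len(design$I), each = design$C), mean),
                                  each = design$C))
      theta_mu <- matrix(0, S, D); theta_mu[, 1L] <- z
      a_mu <- matrix(0, D, IC); a_mu[1L, ] <- a1
      list(theta_mu = theta_mu, a_mu = a_mu, b_mu = bm)
    }, error = function(e) {
      warning("heuristic initialization failed (", conditionMessage(e),
              "); falling back to random initialization")
      NULL
    })
  }
  if (is.null(mu)) mu <- random_init()
  structure(list(
    theta_mu = mu$theta_mu, theta_sd = matrix(sd0, S, D),
    a_mu = mu$a_mu, a_sd = matrix(sd0, D, IC),
    b_mu = mu$b_mu, b_sd = rep(sd0, IC),
    u_mu = rep(softplus_inv(1), D), u_sd = rep(sd0, D),
    v_mu = softplus_inv(1), v_sd = sd0,
    design = design, control = control), class = "mncm_posterior")
}

# 0/1 indicator expansion of a response matrix onto the flattened IC axis.
indicator_matrix <- function(R, design) {
  S <- nrow(R); IC <- design$I * design$C
  X <- matrix(0, S, IC)
  for (i in seq_len(design$I)) {
    r <- R[, i]; ok <- !is.na(r)
    X[cbind(which(ok), (i - 1L) * design$C + r[ok])] <- 1
  }
  X
}

#' Fit the hierarchical MNCM by stochastic variational inference
#'
#' Maximizes a reparameterized one-sample (by default) Monte-Carlo estimate
#' of the ELBO over a fully factorized normal variational family, using Adam
#' with the configured learning-rate schedule.  Surrogate variables for the
#' positive scales are mapped through the softplus bijection.  The per-step
#' ELBO trace is retained for diagnostics.  Runs are deterministic for a
#' given seed.
#'
#' @inheritParams mncm_init
#' @param prior An [mncm_prior()].
#' @param init Optional [mncm_init()] result to start from.
#' @return An `mncm_posterior` with fitted means/SDs and an `elbo` trace.
#' @export
mncm_svi <- function(R, design, prior = mncm_prior(), control, init = NULL) {
  R <- validate_responses(R, design)
  if (is.null(init)) init <- mncm_init(R, design, control)
  Rz <- R; Rz[is.na(Rz)] <- 0L
  out <- svi_fit_cpp(Rz, design$C, control$D,
                     prior$slope_scale, prior$intercept_scale,
                     init$theta_mu, init$a_mu, init$b_mu, init$u_mu, init$v_mu,
                     control$init_posterior_sd,
                     control$n_steps, control$lr_peak, control$lr_schedule,
                     control$elbo_samples, child_seed(control$seed, 97L))
  post <- structure(list(
    theta_mu = out$theta_mu, theta_sd = out$theta_sd,
    a_mu = out$a_mu, a_sd = out$a_sd,
    b_mu = drop(out$b_mu), b_sd = drop(out$b_sd),
    u_mu = drop(out$u_mu), u_sd = drop(out$u_sd),
    v_mu = out$v_mu, v_sd = out$v_sd,
    elbo = drop(out$elbo),
    design = design, control = control, prior = prior),
    class = "mncm_posterior")
  post
}

#' @export
print.mncm_posterior <- function(x, ...) {
  S <- nrow(x$theta_mu); D <- ncol(x$theta_mu)
  cat(sprintf("MNCM mean-field posterior: S = %d respondents, D = %d dimensions\n", S, D))
  if (!is.null(x$elbo))
    cat(sprintf("  final ELBO estimate: %.2f over %d steps\n",
                utils::tail(x$elbo, 1), length(x$elbo)))
  invisible(x)
}

#' Extract raw EAP estimates from a fitted posterior
#'
#' Arranges posterior means into the model-parameter layout and pushes the
#' surrogate scale posteriors through the softplus bijection.  The positive
#' scale EAPs are Monte-Carlo means of `softplus(u)` under the surrogate
#' normal (1,000 seeded draws); the pushforward mean has no closed form.
#'
#' @param posterior A fitted `mncm_posterior`.
#' @param n_draws Monte-Carlo draws for the scale pushforward (default 1000).
#' @return List with `params` ([mncm_params()] of EAP means), `sds`
#'   (matching posterior SD arrays), and `alpha`, `beta` scale EAPs.
#' @export
mncm_estimates <- function(posterior, n_draws = 1000L) {
  design <- posterior$design
  params <- mncm_params(posterior$a_mu, posterior$b_mu, posterior$theta_mu, design)
  alpha <- beta <- NULL
  with_seed(child_seed(posterior$control$seed, 131L), {
    z <- stats::rnorm(n_draws)
    alpha <- vapply(seq_along(posterior$u_mu), function(d)
      mean(softplus(posterior$u_mu[d] + posterior$u_sd[d] * z)), numeric(1))
    beta <- mean(softplus(posterior$v_mu + posterior$v_sd * z))
  })
  list(params = params,
       sds = list(A = posterior$a_sd, b = posterior$b_sd, Theta = posterior$theta_sd),
       alpha = alpha, beta = beta)
}

#' Monte-Carlo ELBO estimate at a fixed posterior
#'
#' Estimates the evidence lower bound for a given mean-field posterior by
#' sampling the reparameterized latent variables and averaging the log joint,
#' then adding the closed-form Gaussian entropy.  With `fix_items`, the
#' items' slopes/intercepts are treated as known constants and only the
#' abilities are latent; this restricted form is useful for validating the
#' bound against quadrature on tiny instances.
#'
#' @param posterior An `mncm_posterior` (for the full model) or, with
#'   `fix_items`, a list with `theta_mu` and `theta_sd` only.
#' @param R Integer response matrix.
#' @param design An [mncm_design()].
#' @param prior An [mncm_prior()] (ignored when `fix_items` is given).
#' @param n_samples Monte-Carlo sample count.
#' @param seed Seed for the estimate.
#' @param fix_items Optional list `(A, b)` of known item parameters.
#' @return Scalar ELBO estimate.
#' @export
mncm_elbo <- function(posterior, R, design, prior = mncm_prior(),
                      n_samples = 100L, seed = 1L, fix_items = NULL) {
  R <- validate_responses(R, design)
  ent_norm <- function(sd) sum(log(sd)) + 0.5 * length(sd) * log(2 * pi * exp(1))
  vals <- NULL
  with_seed(seed, {
    vals <- vapply(seq_len(n_samples), function(k) {
      th <- posterior$theta_mu +
        posterior$theta_sd * matrix(stats::rnorm(length(posterior$theta_mu)),
                                    nrow(posterior$theta_mu))
      if (!is.null(fix_items)) {
        p <- mncm_params(fix_items$A, fix_items$b, th, design)
        sum(stats::dnorm(th, log = TRUE)) + mncm_loglik(R, p, design)
      } else {
        A <- posterior$a_mu + posterior$a_sd * matrix(stats::rnorm(length(posterior$a_mu)),
                                                      nrow(posterior$a_mu))
        b <- posterior$b_mu + posterior$b_sd * stats::rnorm(length(posterior$b_mu))
        u <- posterior$u_mu + posterior$u_sd * stats::rnorm(length(posterior$u_mu))
        v <- posterior$v_mu + posterior$v_sd * stats::rnorm(1)
        mncm_log_joint(R, design, prior, mncm_params(A, b, th, design),
                       u, v, surrogate = TRUE)
      }
    }, numeric(1))
  })
  ent <- ent_norm(posterior$theta_sd)
  if (is.null(fix_items))
    ent <- ent + ent_norm(posterior$a_sd) + ent_norm(posterior$b_sd) +
      ent_norm(posterior$u_sd) + ent_norm(posterior$v_sd)
  mean(vals) + ent
}
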