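# Shared fixtures: small random model instances built in code.

rand_params <- function(S, I, C, D, seed = 1, scale = 0.7) {
  set.seed(seed)
  design <- mncm_design(I, C)
  A <- matrix(rnorm(D * I * C, 0, scale), D, I * C)
  b <- rnorm(I * C, 0, 1)
  Theta <- matrix(rnorm(S * D), S, D)
  list(params = mncm_params(A, b, Theta, design), design = design)
}

# random orthogonal matrix with a fixed seed
rand_orth <- function(D, seed = 1) {
  set.seed(seed)
  qr_out <- qr(matrix(rnorm(D * D), D))
  qr.Q(qr_out) %*% diag(sign(diag(qr.R(qr_out))), D)
}

# brute-force tendency computation, element by element
loop_tendencies <- function(params, design) {
  S <- nrow(params$Theta); D <- ncol(params$Theta)
  IC <- design$I * design$C
  t <- matrix(0, S, IC)
  for (s in seq_len(S)) for (j in seq_len(IC)) {
    acc <- params$b[j]
    for (d in seq_len(D)) acc <- acc + params$Theta[s, d] * params$A[d, j]
    t[s, j] <- acc
  }
  t
}

# fit cache shared across acceptance tests so each heavy cell is fit once
fit_cache <- local({
  env <- new.env(parent = emptyenv())
  function(key, expr) {
    if (!exists(key, envir = env)) assign(key, force(expr), envir = env)
    get(key, envir = env)
  }
})

# one synthesize + fit + identify + score cycle at a single sample size
recovery_cell <- function(gamma, S, rep_i, n_steps = 30000L, D = 9L,
                          seed_base = 20L) {
  spec <- synthesis_spec(S_levels = S, D = D, gamma = gamma,
                         base_seed = seed_base + rep_i)
  truth <- synthesize_dataset(spec, rep_i)
  post <- mncm_svi(truth$R[[as.character(S)]], truth$design, mncm_prior(),
                   mncm_control(D = D, n_steps = n_steps, seed = 100L + rep_i))
  fit <- identify_fit(post, truth$design)
  list(truth = truth, fit = fit,
       scored = align_and_score(truth, fit, S),
       retained = count_retained(fit, truth, S))
}
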