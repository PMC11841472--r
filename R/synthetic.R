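# Synthetic-data generator: ground-truth parameters and nested response
# matrices with exact standardization, so identification and recovery can be
# tested without any external dataset.  Defaults reproduce the reference
# simulation design: 30 items, 5 categories, 9 dimensions, geometric slope
# scales, intercept SD 1.5, nested sample sizes.

#' Synthesis condition descriptor
#'
#' @param S_levels Strictly increasing sample sizes; each level's abilities
#'   and responses contain the previous level's as their leading rows.
#'   Default is the reference grid.
#' @param I Items (default 30).
#' @param C Categories per item (default 5).
#' @param D Synthesized dimensions (default 9).
#' @param gamma Geometric decay of per-dimension slope SDs, in (0, 1];
#'   reference levels are 0.8 and 0.512.
#' @param intercept_sd Standard deviation of the intercept vector
#'   (default 1.5).
#' @param n_replications Number of replications the condition comprises.
#' @param base_seed Seed from which replication and stage seeds derive.
#' @return An object of class `synthesis_spec`.
#' @export
synthesis_spec <- function(S_levels = c(50, 100, 200, 600, 2000, 10000),
                           I = 30L, C = 5L, D = 9L, gamma = 0.8,
                           intercept_sd = 1.5, n_replications = 100L,
                           base_seed = 1L) {
  S_levels <- as.integer(S_levels)
  if (any(diff(S_levels) <= 0L)) stop("S_levels must be strictly increasing")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0, 1]")
  if (intercept_sd < 0) stop("intercept_sd must be non-negative")
  structure(list(S_levels = S_levels, I = as.integer(I), C = as.integer(C),
                 D = as.integer(D), gamma = gamma, intercept_sd = intercept_sd,
                 n_replications = as.integer(n_replications),
                 base_seed = as.integer(base_seed)),
            class = "synthesis_spec")
}

#' Geometric schedule of per-dimension slope standard deviations
#'
#' \deqn{\mathrm{StdDev}[a_d] = 1.0 \times \gamma^{d-1}.}
#'
#' @param gamma Decay factor.
#' @param D Number of dimensions.
#' @return Numeric vector of length `D`.
#' @export
dimension_sds <- function(gamma, D) {
  if (gamma <= 0) stop("gamma must be positive")
  gamma^(seq_len(D) - 1)
}

# Exact standardization: subtract column means, then right-multiply by the
# inverse symmetric square root of the sample second-moment matrix, giving
# zero mean and exactly identity covariance (population denominator).  The
# symmetric root avoids introducing an arbitrary rotation.
standardize_exact <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  S2 <- crossprod(Xc) / nrow(Xc)
  Xc %*% mat_inv_sqrt(S2)
}

#' Synthesize nested ability matrices
#'
#' Each increment block (sizes `S1, S2 - S1, ...`) is drawn standard normal
#' and then exactly standardized to zero mean and identity covariance;
#' levels are the cumulative row-concatenations, so every level contains all
#' smaller levels as its leading rows.
#'
#' @param spec A [synthesis_spec()].
#' @param seed Seed for the draw.
#' @return List of `S x D` matrices, one per `S_levels` entry (named by S).
#' @export
synthesize_abilities <- function(spec, seed) {
  sizes <- diff(c(0L, spec$S_levels))
  if (any(sizes <= spec$D))
    stop("every sample-size increment must exceed D for exact standardization")
  blocks <- NULL
  with_seed(seed, {
    blocks <- lapply(sizes, function(n)
      standardize_exact(matrix(stats::rnorm(n * spec$D), n, spec$D)))
  })
  acc <- NULL
  out <- vector("list", length(sizes))
  for (k in seq_along(sizes)) {
    acc <- rbind(acc, blocks[[k]])
    out[[k]] <- acc
  }
  names(out) <- as.character(spec$S_levels)
  out
}

#' Synthesize item parameters
#'
#' Slopes and intercepts are drawn jointly as an `IC x (D+1)` standard
#' normal matrix, centered within every item's group of `C` rows in all
#' columns, exactly standardized to identity covariance, and the columns
#' scaled to the target SDs `(1, gamma, ..., gamma^(D-1), intercept_sd)`.
#' Whitening preserves the per-item zero means (group means are linear
#' images of zero vectors).  Each dimension's sign is then set so its
#' largest-magnitude slope entry is positive, matching the deviation-mode
#' identification convention, so identification of the truth is a no-op.
#'
#' @param spec A [synthesis_spec()].
#' @param seed Seed for the draw.
#' @return List with slope matrix `A` (`D x IC`) and intercept vector `b`.
#' @export
synthesize_items <- function(spec, seed) {
  IC <- spec$I * spec$C
  if (IC <= spec$D + 1L) stop("I*C must exceed D + 1 for exact standardization")
  M <- NULL
  with_seed(seed, {
    M <- matrix(stats::rnorm(IC * (spec$D + 1L)), IC, spec$D + 1L)
  })
  item <- rep(seq_len(spec$I), each = spec$C)
  for (i in seq_len(spec$I))
    M[item == i, ] <- sweep(M[item == i, , drop = FALSE], 2L,
                            colMeans(M[item == i, , drop = FALSE]))
  M <- M %*% mat_inv_sqrt(crossprod(M) / IC)  # global mean already exactly 0
  M <- sweep(M, 2L, c(dimension_sds(spec$gamma, spec$D), spec$intercept_sd), "*")
  A <- t(M[, seq_len(spec$D), drop = FALSE])
  for (d in seq_len(spec$D))
    if (A[d, which.max(abs(A[d, ]))] < 0) A[d, ] <- -A[d, ]
  list(A = A, b = M[, spec$D + 1L])
}

#' Synthesize nested response matrices
#'
#' Samples every response from the categorical distribution implied by the
#' model tendencies.  Responses are drawn once at the largest sample size;
#' each smaller level is its leading rows, so the nesting is exact.
#'
#' @param theta_levels Output of [synthesize_abilities()].
#' @param A,b Item parameters from [synthesize_items()].
#' @param spec A [synthesis_spec()].
#' @param seed Seed for the categorical draws.
#' @return List of integer response matrices, one per `S_levels` entry.
#' @export
synthesize_responses <- function(theta_levels, A, b, spec, seed) {
  design <- mncm_design(spec$I, spec$C)
  top <- theta_levels[[length(theta_levels)]]
  R_top <- mncm_sample_responses(mncm_params(A, b, top, design), design, seed)
  out <- lapply(spec$S_levels, function(S) R_top[seq_len(S), , drop = FALSE])
  names(out) <- as.character(spec$S_levels)
  out
}

#' Generate one full synthetic replication
#'
#' Runs the three synthesis stages under a replication-specific seed ledger
#' derived from `spec$base_seed`: abilities, items and responses each use
#' their own child seed, all recorded in the returned `seeds` manifest.
#'
#' @param spec A [synthesis_spec()].
#' @param replication Replication index (default 1).
#' @return An object of class `mncm_synthetic`: `Theta` (per level), `A`,
#'   `b`, `R` (per level), `design`, `spec`, `replication`, `seeds`.
#' @export
synthesize_dataset <- function(spec, replication = 1L) {
  rep_seed <- child_seed(spec$base_seed, replication)
  seeds <- list(replication = rep_seed,
                abilities = child_seed(rep_seed, 1L),
                items = child_seed(rep_seed, 2L),
                responses = child_seed(rep_seed, 3L))
  theta <- synthesize_abilities(spec, seeds$abilities)
  items <- synthesize_items(spec, seeds$items)
  R <- synthesize_responses(theta, items$A, items$b, spec, seeds$responses)
  structure(list(Theta = theta, A = items$A, b = items$b, R = R,
                 design = mncm_design(spec$I, spec$C), spec = spec,
                 replication = as.integer(replication), seeds = seeds),
            class = "mncm_synthetic")
}

#' @export
print.mncm_synthetic <- function(x, ...) {
  cat(sprintf("Synthetic MNCM dataset: D = %d, gamma = %g, S levels %s (replication %d)\n",
              x$spec$D, x$spec$gamma,
              paste(x$spec$S_levels, collapse = "/"), x$replication))
  invisible(x)
}

#' Per-dimension tendency variance fractions
#'
#' Decomposes the variance of the synthesized tendencies over dimensions:
#' with unit ability variance, dimension `d` contributes the variance of its
#' slope row.  With `include_intercepts = TRUE` the intercept variance is
#' added to the denominator.  For an exactly synthesized slope matrix the
#' fractions equal \eqn{\gamma^{2(d-1)} / \sum_d \gamma^{2(d-1)}}.
#'
#' @param A Identified slope matrix (`D x IC`).
#' @param intercept_sd Intercept standard deviation (used only when
#'   `include_intercepts` is set).
#' @param include_intercepts Include the intercept contribution in the total.
#' @return Numeric vector of per-dimension fractions.
#' @export
tendency_variance_fractions <- function(A, intercept_sd = 1.5,
                                        include_intercepts = FALSE) {
  A <- as.matrix(A)
  v <- apply(A, 1L, function(x) mean((x - mean(x))^2))
  tot <- sum(v) + if (include_intercepts) intercept_sd^2 else 0
  v / tot
}
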