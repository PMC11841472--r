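# Post-identification transformations: orthogonal Procrustes alignment to a
# reference frame, exploratory bi-factor rotation for sparse interpretable
# slope vectors, and Spearman-based sign determination.  All of them act as
# Theta -> Theta Q, A -> Q^T A and therefore leave tendencies and category
# probabilities unchanged.

#' Orthogonal Procrustes alignment
#'
#' Finds the (partial) orthogonal matrix `Q` minimizing
#' \eqn{\|\Theta Q - \hat\Theta\|_F^2} via the classical singular value
#' decomposition solution: `Q = U V'` with `svd(Theta' Theta_hat) = U D V'`.
#' When the estimate retains fewer dimensions than the reference
#' (`D_hat < D`), `Q` is `D x D_hat` with orthonormal columns, mapping the
#' reference into the estimate's frame and restricting the analysis to the
#' extracted dimensions.  The SVD solution attains the global minimum.
#'
#' @param reference_theta Reference ability matrix, `S x D`.
#' @param estimated_theta Estimated ability matrix, `S x D_hat`.
#' @return The alignment matrix `Q` (`D x D_hat`, orthonormal columns).
#' @export
procrustes_align <- function(reference_theta, estimated_theta) {
  reference_theta <- as.matrix(reference_theta)
  estimated_theta <- as.matrix(estimated_theta)
  if (nrow(reference_theta) != nrow(estimated_theta))
    stop(sprintf("ability matrices have different numbers of rows (%d vs %d)",
                 nrow(reference_theta), nrow(estimated_theta)))
  if (ncol(estimated_theta) > ncol(reference_theta))
    stop("the estimate has more dimensions than the reference")
  s <- svd(crossprod(reference_theta, estimated_theta))
  s$u %*% t(s$v)
}

#' Apply an alignment to reference parameters
#'
#' Rotates a reference (e.g. synthesized truth) into the estimate frame:
#' `Theta* = Theta Q`, `A* = Q' A`.
#'
#' @param params Reference [mncm_params()].
#' @param Q Alignment matrix from [procrustes_align()].
#' @return List with rotated `Theta` and `A`.
#' @export
apply_alignment <- function(params, Q) {
  list(Theta = params$Theta %*% Q, A = t(Q) %*% params$A)
}

# Bi-quartimin rotation criterion and gradient for a loading matrix
# L (p x k): the quartimin criterion applied to all factors but the first,
# so the general factor may stay dense while group factors become sparse.
# Quartimin: f(L) = sum_i sum_{j != l} L_ij^2 L_il^2 / 4 (scaling immaterial).
rotation_criterion <- function(L, method) {
  k <- ncol(L)
  sub <- switch(method,
    bifactor = if (k >= 2) L[, -1L, drop = FALSE] else NULL,
    quartimin = L,
    varimax = NULL)
  if (method == "varimax") {
    # maximize varimax simplicity == minimize its negative
    L2 <- L^2
    v <- sum(apply(L2, 2L, function(x) mean(x^2) - mean(x)^2))
    return(-v)
  }
  if (is.null(sub) || ncol(sub) < 2) return(0)
  L2 <- sub^2
  N <- matrix(1, ncol(sub), ncol(sub)) - diag(ncol(sub))
  sum(L2 * (L2 %*% N)) / 4
}

rotation_gradient <- function(L, method) {
  k <- ncol(L)
  G <- matrix(0, nrow(L), k)
  if (method == "varimax") {
    L2 <- L^2
    Gm <- -L * sweep(L2, 2L, colMeans(L2)) * 4 / nrow(L)
    return(Gm)
  }
  idx <- if (method == "bifactor") seq_len(k)[-1L] else seq_len(k)
  if (length(idx) < 2) return(G)
  sub <- L[, idx, drop = FALSE]
  L2 <- sub^2
  N <- matrix(1, length(idx), length(idx)) - diag(length(idx))
  G[, idx] <- sub * (L2 %*% N)
  G
}

# Gradient-projection algorithm for orthogonal rotation (Jennrich 2001).
# A0: p x k initial loadings; Tmat: starting orthogonal k x k.
gpa_orth <- function(A0, Tmat, method, max_iter = 500L, tol = 1e-6) {
  al <- 1
  L <- A0 %*% Tmat
  f <- rotation_criterion(L, method)
  for (it in seq_len(max_iter)) {
    G <- crossprod(A0, rotation_gradient(L, method))
    M <- crossprod(Tmat, G)
    Gp <- G - Tmat %*% (M + t(M)) / 2
    s <- sqrt(sum(Gp^2))
    if (s < tol) break
    al <- 2 * al
    improved <- FALSE
    repeat {
      X <- Tmat - al * Gp
      sv <- svd(X)
      Tt <- sv$u %*% t(sv$v)
      Lt <- A0 %*% Tt
      ft <- rotation_criterion(Lt, method)
      if (ft < f - 0.5 * s^2 * al) { improved <- TRUE; break }
      if (al < 1e-10) break
      al <- al / 2
    }
    if (!improved) break
    Tmat <- Tt; L <- Lt; f <- ft
  }
  list(Tmat = Tmat, L = L, criterion = f)
}

random_orthogonal <- function(k) {
  qr_out <- qr(matrix(stats::rnorm(k * k), k))
  Q <- qr.Q(qr_out)
  Q %*% diag(sign(diag(qr.R(qr_out))), k)
}

#' Exploratory rotation of identified slopes
#'
#' Orthogonally rotates the slope matrix to maximize interpretability.  The
#' default bi-factor (bi-quartimin) criterion leaves one dense general
#' factor and drives the remaining group factors toward sparse loadings;
#' `varimax` and `quartimin` are also available.  Optimization uses the
#' gradient-projection algorithm with backtracking from `n_starts` random
#' orthogonal starts (plus the identity), keeping the best solution;
#' deterministic for a given seed.  Rotations act as `Theta -> Theta Q`,
#' `A -> Q' A`, preserving all tendencies.
#'
#' @param fit An `mncm_fit` (or a list with `A` and `Theta`).
#' @param method Rotation criterion: `"bifactor"` (default), `"varimax"`,
#'   `"quartimin"`.
#' @param n_starts Number of random orthogonal starts (default 10).
#' @param max_iter Maximum gradient-projection iterations per start.
#' @param tol Projected-gradient convergence tolerance.
#' @param seed Seed for the random starts.
#' @return An object of class `mncm_rotation` with `rotation_matrix`,
#'   `rotated_slopes`, `rotated_abilities`, `criterion_value`, `method`.
#' @export
bifactor_rotate <- function(fit, method = c("bifactor", "varimax", "quartimin"),
                            n_starts = 10L, max_iter = 500L, tol = 1e-6,
                            seed = 1L) {
  method <- match.arg(method)
  A <- fit$A; Theta <- fit$Theta
  D <- nrow(A)
  if (D < 2) {
    warning("fewer than two retained dimensions; returning the identity rotation")
    return(structure(list(rotation_matrix = diag(1, D),
                          rotated_slopes = A, rotated_abilities = Theta,
                          criterion_value = 0, method = method),
                     class = "mncm_rotation"))
  }
  L0 <- t(A)  # loadings: categories x dimensions
  starts <- list(diag(1, D))
  with_seed(seed, {
    for (k in seq_len(n_starts)) starts[[k + 1L]] <- random_orthogonal(D)
  })
  best <- NULL
  for (Tmat in starts) {
    res <- gpa_orth(L0, Tmat, method, max_iter, tol)
    if (is.null(best) || res$criterion < best$criterion) best <- res
  }
  Q <- best$Tmat
  structure(list(rotation_matrix = Q,
                 rotated_slopes = t(Q) %*% A,
                 rotated_abilities = Theta %*% Q,
                 criterion_value = best$criterion, method = method),
            class = "mncm_rotation")
}

#' @export
print.mncm_rotation <- function(x, ...) {
  cat(sprintf("MNCM %s rotation: %d dimensions, criterion %.6g\n",
              x$method, nrow(x$rotated_slopes), x$criterion_value))
  invisible(x)
}

#' Determine dimension signs by correlation with total score
#'
#' Flips each ability dimension (and its slope row) so that the Spearman
#' correlation between abilities and total test score is non-negative.
#' Zero-correlation ties keep the incoming sign; constant scores leave all
#' signs unchanged with a warning.  Dimensions with weak score correlation
#' (|rho| < 0.05) are reported via a message, since the rule is marginal
#' there.
#'
#' @param rotated_theta `S x D` ability matrix.
#' @param total_scores Numeric vector of respondent total scores.
#' @return Integer vector of signs (+1 / -1) per dimension.
#' @export
determine_signs <- function(rotated_theta, total_scores) {
  rotated_theta <- as.matrix(rotated_theta)
  if (stats::sd(total_scores) == 0) {
    warning("total scores are constant; keeping default signs")
    return(rep(1L, ncol(rotated_theta)))
  }
  rho <- apply(rotated_theta, 2L, function(col)
    suppressWarnings(stats::cor(col, total_scores, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  weak <- which(abs(rho) < 0.05)
  if (length(weak))
    message("weak score correlation for dimension(s) ",
            paste(weak, collapse = ", "), "; sign choice is marginal there")
  ifelse(rho < 0, -1L, 1L)
}

#' Spearman association of the general factor with total score
#'
#' Returns the Spearman rank correlation between the first (general)
#' dimension's abilities and the raw total scores — the standard sanity
#' check that the dense factor measures overall proficiency.
#'
#' @inheritParams determine_signs
#' @return Scalar Spearman correlation.
#' @export
general_factor_score_check <- function(rotated_theta, total_scores) {
  stats::cor(as.matrix(rotated_theta)[, 1L], total_scores, method = "spearman")
}

#' Total number-correct scores
#'
#' @param R Integer response matrix.
#' @param design An [mncm_design()] with an answer key.
#' @return Integer vector of number-correct scores.
#' @export
total_scores <- function(R, design) {
  if (is.null(design$correct)) stop("scoring requires an answer key")
  R <- validate_responses(R, design)
  rowSums(sweep(R, 2L, design$correct, "==") & !is.na(R))
}
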