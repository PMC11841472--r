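#' Test design for a nominal-response instrument
#'
#' Describes the fixed structure of a multiple-choice test: the number of
#' items `I`, the (constant) number of response categories per item `C`, and
#' optionally the index of the correct category for each item.  All items are
#' assumed to share the same number of categories; the flattened
#' item-by-category axis used throughout the package is item-major,
#' category-minor, i.e. column `(i - 1) * C + c` holds category `c` of item
#' `i` (1-based).
#'
#' @param I Number of items (positive integer).
#' @param C Number of response categories per item (integer, at least 2).
#' @param correct Optional integer vector of length `I` giving the correct
#'   category index (in `1..C`) of each item; `NULL` when the instrument has
#'   no keyed answer (e.g. attitude scales or synthetic studies).
#' @return An object of class `mncm_design`.
#' @export
mncm_design <- function(I, C, correct = NULL) {
  I <- as.integer(I); C <- as.integer(C)
  if (length(I) != 1L || is.na(I) || I < 1L) stop("I must be a positive integer")
  if (length(C) != 1L || is.na(C) || C < 2L) stop("C must be an integer >= 2")
  if (!is.null(correct)) {
    correct <- as.integer(correct)
    if (length(correct) != I) stop("correct must have one entry per item")
    if (anyNA(correct) || any(correct < 1L | correct > C))
      stop("correct category indices must lie in 1..C for every item")
  }
  structure(list(I = I, C = C, correct = correct), class = "mncm_design")
}

#' @export
print.mncm_design <- function(x, ...) {
  cat(sprintf("MNCM test design: %d items x %d categories (%s answer key)\n",
              x$I, x$C, if (is.null(x$correct)) "no" else "with"))
  invisible(x)
}

#' Bundle MNCM parameters
#'
#' Collects slope, intercept and ability arrays into a validated parameter
#' set.  Slopes `A` are `D x IC` (dimensions by flattened item-category
#' columns), intercepts `b` have length `IC`, abilities `Theta` are `S x D`.
#'
#' @param A Slope matrix, `D x IC`.
#' @param b Intercept vector, length `IC`.
#' @param Theta Ability matrix, `S x D`.
#' @param design An [mncm_design()].
#' @return An object of class `mncm_params`.
#' @export
mncm_params <- function(A, b, Theta, design) {
  A <- as.matrix(A); Theta <- as.matrix(Theta); b <- as.numeric(b)
  IC <- design$I * design$C
  if (ncol(A) != IC)
    stop(sprintf("slope matrix A has %d columns; design requires I*C = %d", ncol(A), IC))
  if (length(b) != IC)
    stop(sprintf("intercept vector b has length %d; design requires I*C = %d", length(b), IC))
  if (ncol(Theta) != nrow(A))
    stop(sprintf("ability matrix Theta has %d columns but A has %d rows (dimensions D must agree)",
                 ncol(Theta), nrow(A)))
  if (!all(is.finite(A))) stop("non-finite entries in slope matrix A")
  if (!all(is.finite(b))) stop("non-finite entries in intercept vector b")
  if (!all(is.finite(Theta))) stop("non-finite entries in ability matrix Theta")
  structure(list(A = A, b = b, Theta = Theta), class = "mncm_params")
}

#' Response tendencies
#'
#' Computes the latent log-preference ("tendency") of every respondent for
#' every category of every item: the inner product of the respondent's
#' ability vector with the category's slope vector, plus the category
#' intercept,
#' \deqn{t_s^{(i,c)} = \sum_d \theta_s^{(d)} a_d^{(i,c)} + b^{(i,c)}.}
#'
#' @param params An [mncm_params()] set.
#' @param design An [mncm_design()].
#' @return `S x IC` matrix of tendencies.
#' @export
mncm_tendencies <- function(params, design) {
  stopifnot(inherits(params, "mncm_params"))
  t <- params$Theta %*% params$A
  sweep(t, 2L, params$b, "+")
}

#' Category selection probabilities
#'
#' Applies a numerically stable softmax within every respondent-by-item block
#' of `C` tendencies: the per-block maximum is subtracted before
#' exponentiation, so arbitrarily shifted or large tendencies give identical,
#' finite probabilities.
#'
#' @param t Tendency matrix (`S x IC`), e.g. from [mncm_tendencies()].
#' @param design An [mncm_design()].
#' @return `S x IC` matrix of probabilities; each `C`-block sums to 1.
#' @export
mncm_probabilities <- function(t, design) {
  t <- as.matrix(t)
  if (ncol(t) != design$I * design$C)
    stop("tendency array has wrong number of columns for this design")
  if (!all(is.finite(t))) stop("non-finite tendencies")
  p <- t
  for (i in seq_len(design$I)) {
    cols <- ((i - 1L) * design$C + 1L):(i * design$C)
    blk <- t[, cols, drop = FALSE]
    blk <- blk - apply(blk, 1L, max)
    e <- exp(blk)
    p[, cols] <- e / rowSums(e)
  }
  p
}

#' Log-likelihood of observed responses
#'
#' Sums the log selection probability of every observed response; missing
#' responses (NA) contribute nothing.
#'
#' @param R Integer response matrix (`S x I`, entries in `1..C` or `NA`).
#' @param params An [mncm_params()] set.
#' @param design An [mncm_design()].
#' @return Scalar log-likelihood (<= 0).
#' @export
mncm_loglik <- function(R, params, design) {
  R <- validate_responses(R, design)
  if (nrow(R) != nrow(params$Theta))
    stop("response matrix and ability matrix disagree on the number of respondents")
  p <- mncm_probabilities(mncm_tendencies(params, design), design)
  ll <- 0
  for (i in seq_len(design$I)) {
    r <- R[, i]
    ok <- !is.na(r)
    if (!any(ok)) next
    cols <- (i - 1L) * design$C + r[ok]
    ll <- ll + sum(log(p[cbind(which(ok), cols)]))
  }
  ll
}

#' Sample nominal responses from the model
#'
#' Draws each response independently from the categorical distribution
#' implied by the model probabilities.  Reproducible for a given seed.
#'
#' @inheritParams mncm_loglik
#' @param seed Integer seed for the draw.
#' @return Integer `S x I` response matrix with entries in `1..C`.
#' @export
mncm_sample_responses <- function(params, design, seed) {
  p <- mncm_probabilities(mncm_tendencies(params, design), design)
  S <- nrow(p)
  R <- matrix(NA_integer_, S, design$I)
  with_seed(seed, {
    for (i in seq_len(design$I)) {
      cols <- ((i - 1L) * design$C + 1L):(i * design$C)
      cum <- t(apply(p[, cols, drop = FALSE], 1L, cumsum))
      u <- stats::runif(S)
      R[, i] <- 1L + rowSums(cum < u)
    }
  })
  storage.mode(R) <- "integer"
  R
}

# Validate a response matrix against a design; returns integer matrix.
validate_responses <- function(R, design) {
  R <- as.matrix(R)
  if (ncol(R) != design$I)
    stop(sprintf("response matrix has %d columns; design has I = %d items", ncol(R), design$I))
  storage.mode(R) <- "integer"
  bad <- which(!is.na(R) & (R < 1L | R > design$C), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("response out of range 1..%d at respondent %d, item %d",
                 design$C, bad[1, 1], bad[1, 2]))
  R
}

# Evaluate an expression under a temporary RNG seed, restoring prior state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% 2147483647))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  eval.parent(substitute(expr))
}

# Derive a bounded child seed from a base seed and a stream index.
child_seed <- function(base, k) {
  as.integer((as.double(base) * 48271 + 7919 * as.double(k)) %% 2147483629)
}
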