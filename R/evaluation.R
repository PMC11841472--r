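# Parameter-recovery metrics and the simulation harness: per-dimension
# coefficients of determination between Procrustes-aligned synthesized and
# recovered slopes, retained-dimension counts, and the study loop over
# (gamma, S) cells.

#' Coefficient of determination between slope vectors
#'
#' The squared centered Pearson correlation between an aligned true slope
#' row and its estimate.  It deliberately forgives affine rescaling of
#' either argument, which does not affect the interpretation of recovered
#' slopes.  Zero variance in either argument yields `NA` (undefined metric),
#' not 0 and not an error.
#'
#' @param a_star Aligned true slope row (length >= 2).
#' @param a_hat Estimated slope row of equal length.
#' @return Scalar in `[0, 1]`, or `NA` when undefined.
#' @export
r_squared <- function(a_star, a_hat) {
  a_star <- as.numeric(a_star); a_hat <- as.numeric(a_hat)
  if (length(a_star) != length(a_hat)) stop("slope vectors must have equal length")
  if (length(a_star) < 2) stop("slope vectors must have length >= 2")
  xs <- a_star - mean(a_star); ys <- a_hat - mean(a_hat)
  sx <- sum(xs^2); sy <- sum(ys^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum(xs * ys)^2 / (sx * sy)
}

#' Align truth to an identified fit and score slope recovery
#'
#' Solves the orthogonal Procrustes problem on abilities (mapping the
#' synthesized truth into the estimate frame, restricted to the `D_hat`
#' retained dimensions), rotates the true slopes accordingly, and computes
#' the per-dimension coefficient of determination against the estimates.
#'
#' @param truth An `mncm_synthetic` dataset.
#' @param fit An `mncm_fit`.
#' @param S Sample-size level of the fit (defaults to the fit's respondent
#'   count).
#' @param rmse Also report per-dimension root-mean-square error of the
#'   aligned slopes (off by default: the headline metric deliberately
#'   forgives scale, which RMSE does not).
#' @return A tibble with one row per extracted dimension: `dimension`,
#'   `r_squared`, `truth_dimension` (the dominant synthesized dimension in
#'   the alignment), `truth_sd` (its synthesized slope SD), and optionally
#'   `rmse`.  Zero retained dimensions give an empty tibble with a warning.
#' @export
align_and_score <- function(truth, fit, S = nrow(fit$Theta), rmse = FALSE) {
  if (fit$D_hat == 0L) {
    warning("fit retained zero dimensions; empty recovery report")
    return(tibble::tibble(dimension = integer(), r_squared = numeric(),
                          truth_dimension = integer(), truth_sd = numeric()))
  }
  theta_true <- truth$Theta[[as.character(S)]]
  if (is.null(theta_true))
    stop(sprintf("truth has no sample-size level S = %d", S))
  Q <- procrustes_align(theta_true, fit$Theta)
  A_star <- t(Q) %*% truth$A
  r2 <- vapply(seq_len(fit$D_hat), function(d)
    r_squared(A_star[d, ], fit$A[d, ]), numeric(1))
  truth_dim <- apply(abs(Q), 2L, which.max)
  out <- tibble::tibble(dimension = seq_len(fit$D_hat), r_squared = r2,
                        truth_dimension = as.integer(truth_dim),
                        truth_sd = dimension_sds(truth$spec$gamma,
                                                 truth$spec$D)[truth_dim])
  if (rmse)
    out$rmse <- vapply(seq_len(fit$D_hat), function(d)
      sqrt(mean((A_star[d, ] - fit$A[d, ])^2)), numeric(1))
  out
}

#' Retained-dimension count and smallest retained synthesized scale
#'
#' Reports `D_hat` and, when the synthesized truth is supplied, the
#' synthesized slope SD (geometric schedule) of the dimension that the
#' smallest retained estimate dimension aligns with.
#'
#' @param fit An `mncm_fit`.
#' @param truth Optional `mncm_synthetic`.
#' @param S Sample-size level used for the fit.
#' @return List with `D_hat` and (when truth is given) `smallest_sd` and
#'   `smallest_truth_dimension`.
#' @export
count_retained <- function(fit, truth = NULL, S = nrow(fit$Theta)) {
  out <- list(D_hat = fit$D_hat)
  if (!is.null(truth) && fit$D_hat > 0L) {
    scored <- align_and_score(truth, fit, S)
    last <- nrow(scored)
    out$smallest_truth_dimension <- scored$truth_dimension[last]
    out$smallest_sd <- scored$truth_sd[last]
  }
  out
}

#' Run a slope-recovery simulation study
#'
#' For every (gamma, S) cell and replication: synthesize a dataset, fit the
#' Bayesian model, identify and prune, Procrustes-align the truth, and score
#' per-dimension recovery.  Failed replications are recorded (with the error
#' message) and never silently dropped; summaries count successes.  All
#' seeds derive from `base_seed` and are logged per replication.  The
#' default scale is a reduced grid — the full headline design (6 sample
#' sizes x 2 gamma levels x 100 replications) is cluster-scale.
#'
#' @param gammas Gamma levels to cross.
#' @param S_values Sample sizes to cross.
#' @param n_replications Replications per cell.
#' @param D_fit Maximum dimensions for the fitted model (default 9).
#' @param control_fn Function `(seed) -> mncm_control` for each fit; default
#'   uses the reference settings with `D = D_fit`.
#' @param spec_fn Function `(gamma, S, base_seed) -> synthesis_spec`.
#' @param base_seed Master seed.
#' @param verbose Print per-fit progress.
#' @return List of class `recovery_report`: `results` (tibble, one row per
#'   gamma x S x replication x dimension), `failures` (tibble), and
#'   `summary` (per-cell/dimension medians, IQRs, retained counts).
#' @export
run_recovery_study <- function(gammas = c(0.8, 0.512), S_values = c(600, 2000),
                               n_replications = 5L, D_fit = 9L,
                               control_fn = NULL, spec_fn = NULL,
                               base_seed = 1L, verbose = interactive()) {
  if (is.null(control_fn))
    control_fn <- function(seed) mncm_control(D = D_fit, seed = seed)
  if (is.null(spec_fn))
    spec_fn <- function(gamma, S, seed)
      synthesis_spec(S_levels = S, gamma = gamma, base_seed = seed)
  rows <- list(); fails <- list(); k <- 0L
  for (g in gammas) for (S in S_values) for (rep_i in seq_len(n_replications)) {
    k <- k + 1L
    # seed depends on the cell's values, not grid positions, so any subset
    # of the grid reproduces the same cells (resumable by cell)
    cell_seed <- child_seed(base_seed, round(10000 * g) + S)
    res <- tryCatch({
      spec <- spec_fn(g, S, cell_seed)
      truth <- synthesize_dataset(spec, replication = rep_i)
      ctrl <- control_fn(child_seed(cell_seed, rep_i))
      post <- mncm_svi(truth$R[[as.character(S)]], truth$design,
                       mncm_prior(), ctrl)
      fit <- identify_fit(post, truth$design, mode = "deviation")
      scored <- align_and_score(truth, fit, S)
      tibble::tibble(gamma = g, S = S, replication = rep_i,
                     D_hat = fit$D_hat, seed = cell_seed,
                     dimension = scored$dimension, r_squared = scored$r_squared,
                     truth_dimension = scored$truth_dimension,
                     truth_sd = scored$truth_sd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <-
        tibble::tibble(gamma = g, S = S, replication = rep_i,
                       message = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
      if (verbose)
        message(sprintf("gamma=%g S=%d rep %d: D_hat=%d", g, S, rep_i,
                        res$D_hat[1]))
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    tibble::tibble(gamma = numeric(), S = integer(), replication = integer(),
                   D_hat = integer(), seed = integer(), dimension = integer(),
                   r_squared = numeric(), truth_dimension = integer(),
                   truth_sd = numeric())
  failures <- if (length(fails)) do.call(rbind, fails) else
    tibble::tibble(gamma = numeric(), S = integer(), replication = integer(),
                   message = character())
  summary <- summarize_recovery(results)
  structure(list(results = results, failures = failures, summary = summary,
                 base_seed = base_seed), class = "recovery_report")
}

summarize_recovery <- function(results) {
  if (nrow(results) == 0L)
    return(tibble::tibble(gamma = numeric(), S = integer(),
                          dimension = integer(), n = integer(),
                          median_r2 = numeric(), iqr_r2 = numeric(),
                          median_D_hat = numeric()))
  key <- interaction(results$gamma, results$S, results$dimension, drop = TRUE)
  parts <- split(results, key)
  do.call(rbind, lapply(parts, function(p) tibble::tibble(
    gamma = p$gamma[1], S = p$S[1], dimension = p$dimension[1],
    n = nrow(p),
    median_r2 = stats::median(p$r_squared, na.rm = TRUE),
    iqr_r2 = stats::IQR(p$r_squared, na.rm = TRUE),
    median_D_hat = stats::median(p$D_hat))))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("MNCM recovery study: %d scored fits, %d failures\n",
              length(unique(paste(x$results$gamma, x$results$S,
                                  x$results$replication))),
              nrow(x$failures)))
  print(x$summary)
  invisible(x)
}

#' Plot a recovery report
#'
#' Per-dimension recovery curves (median r-squared against dimension index,
#' one panel per gamma, colored by sample size).  Requires ggplot2.
#'
#' @param report A `recovery_report`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  s <- report$summary
  ggplot2::ggplot(s, ggplot2::aes(x = dimension, y = median_r2,
                                  color = factor(S))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~gamma, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "dimension", y = expression(median ~ r^2),
                  color = "S") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}
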