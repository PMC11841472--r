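#' Fit and identify a hierarchical Bayesian MNCM
#'
#' One-call pipeline: initialize the mean-field posterior, run stochastic
#' variational inference with the reference defaults (30,000 steps, learning
#' rate decaying from 0.05 to zero, posterior SDs initialized to 0.1,
#' half-Cauchy(5) scale priors), then impose the identification constraints
#' and prune inactive dimensions.
#'
#' @param R Integer response matrix (`S x I`, entries `1..C` or `NA`).
#' @param design An [mncm_design()].
#' @param D Maximum number of latent dimensions.
#' @param mode Category constraints: `"simple"` (requires an answer key;
#'   the natural choice for keyed tests) or `"deviation"`.  Defaults to
#'   `"simple"` when the design has a key, else `"deviation"`.
#' @param prior An [mncm_prior()].
#' @param control An [mncm_control()]; built from `D` and `seed` when
#'   omitted.
#' @param prune_threshold Slope-norm pruning cutoff (default 0.005).
#' @param seed Seed used when `control` is omitted.
#' @return An `mncm_fit` with the fitted `posterior` attached.
#' @examples
#' \donttest{
#' spec <- synthesis_spec(S_levels = 300, D = 2, base_seed = 7)
#' truth <- synthesize_dataset(spec)
#' fit <- mncm_fit(truth$R[["300"]], truth$design, D = 3,
#'                 control = mncm_control(D = 3, n_steps = 2000, seed = 7))
#' fit$D_hat
#' }
#' @export
mncm_fit <- function(R, design, D, mode = NULL, prior = mncm_prior(),
                     control = NULL, prune_threshold = 0.005, seed = 1L) {
  if (is.null(control)) control <- mncm_control(D = D, seed = seed)
  if (is.null(mode))
    mode <- if (!is.null(design$correct)) "simple" else "deviation"
  post <- mncm_svi(R, design, prior, control)
  fit <- identify_fit(post, design, mode = mode,
                      prune_threshold = prune_threshold)
  fit$posterior <- post
  fit
}
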