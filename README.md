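# mncmbayes

Hierarchical Bayesian estimation of the **Multidimensional Nominal Categories
Model** (MNCM) for multiple-choice response data, by stochastic mean-field
variational inference — with full model identification, automatic dimension
pruning, Procrustes alignment, exploratory bi-factor rotation, an exact
synthetic-data generator, and a slope-recovery simulation harness.

## Who this is for

Psychometricians and education researchers who want to analyze nominal
multiple-choice responses *at the level of individual distractors*.  Scoring
items right/wrong discards which wrong answer was chosen; on research-designed
concept tests, distractors encode common misconceptions, and different
distractors of the same item can encode different ones.  A model that is
multidimensional *within categories* can surface those patterns without any
manual labeling of content.

## The model

Respondent $s$ has a latent ability vector $\theta_s \in \mathbb{R}^D$; each
category $c$ of item $i$ has a slope vector $a^{(i,c)} \in \mathbb{R}^D$ and an
intercept $b^{(i,c)}$.  Response tendencies and probabilities are

$$t_s^{(i,c)} = \sum_{d} \theta_s^{(d)} a_d^{(i,c)} + b^{(i,c)}, \qquad
  P(r_s^{(i)} = c) = \frac{\exp t_s^{(i,c)}}{\sum_{c'} \exp t_s^{(i,c')}} .$$

Priors are hierarchical — $a_d^{(i,c)} \sim N(0, \alpha_d)$,
$b^{(i,c)} \sim N(0, \beta)$, $\theta_s^{(d)} \sim N(0,1)$, with learned
half-Cauchy(5) scales $\alpha_d, \beta$ — so unsupported dimensions are
switched off by the data itself ($\alpha_d \to 0$), giving strong robustness
to overfactoring.  Inference is SVI with a fully factorized normal posterior
(compiled Adam loop; 30,000 steps, learning rate 0.05 decaying linearly to
zero, posterior SDs initialized at 0.1).  Identification (ability centering,
category reference constraints, uncertainty-aware whitening with
variance-ordered dimensions) and pruning are applied as exact
probability-preserving post-processing.

## Worked example

Synthesize a 2-dimensional test world, fit an intentionally overfactored
4-dimensional model, and watch the surplus dimensions disappear:

```r
library(mncmbayes)

spec  <- synthesis_spec(S_levels = 500, I = 20, C = 5, D = 2,
                        gamma = 0.6, base_seed = 51)
truth <- synthesize_dataset(spec)
post  <- mncm_svi(truth$R[["500"]], truth$design, mncm_prior(),
                  mncm_control(D = 4, n_steps = 6000, seed = 13))
fit   <- identify_fit(post, truth$design)
fit
#> Identified MNCM fit: 2 retained dimension(s) (deviation constraints)
#>   slope SDs by dimension: 0.933, 0.543

align_and_score(truth, fit)
#> # A tibble: 2 x 4
#>   dimension r_squared truth_dimension truth_sd
#>       <int>     <dbl>           <int>    <dbl>
#> 1         1     0.942               1      1
#> 2         2     0.909               2      0.6
```

Two dimensions were synthesized (slope SDs 1 and 0.6); the fit retains
exactly those two — the other two collapse to the numerical noise floor and
are pruned — and the aligned slope $r^2$ of 0.94/0.91 says the recovered
slope patterns match the synthesized ones closely (the metric forgives
overall scale, which identification sets from the data).

For keyed real data the pipeline is `read_responses()` →
`mncm_fit(..., mode = "simple")` → `bifactor_rotate()` →
`report_distractor_vectors()`, and a command-line wrapper with
`simulate | fit | rotate | evaluate | report` subcommands is installed at
`inst/cli/mncm`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch (synthesis → fit → identification → alignment):
the median dimension-7 slope-recovery $r^2$ at $\gamma = 0.8$, $S = 2000$
over three replications; the dimension-1 recovery $r^2$ at $S = 10{,}000$;
and the synthesized slope SD of the smallest dimension retained at
$S = 600$, across both $\gamma$ conditions (five replications each).
Per-fit diagnostics are printed as messages and the results are written as
JSON.

## Layout

- `R/` — model core, priors + SVI driver, identification, rotation,
  synthesis, evaluation, I/O
- `src/` — the compiled SVI loop (RcppArmadillo)
- `vignettes/mncm-bayes-methods.Rmd` — methods and design notes
- `tests/testthat/` — unit, property and acceptance suites
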