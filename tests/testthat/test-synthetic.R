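test_that("the geometric slope-scale schedule matches its defining values", {
  expect_equal(round(dimension_sds(0.8, 9)[7], 3), 0.262)
  expect_equal(round(dimension_sds(0.512, 3)[3], 3), 0.262)
  expect_equal(dimension_sds(0.512, 3)[3], dimension_sds(0.8, 9)[7],
               tolerance = 1e-12)
  expect_equal(dimension_sds(0.3, 5)[1], 1)
})

test_that("ability blocks are exactly standardized and nested", {
  spec <- synthesis_spec(S_levels = c(50, 100, 200), D = 4, base_seed = 9)
  th <- synthesize_abilities(spec, seed = 123)
  for (lv in names(th)) {
    X <- th[[lv]]
    expect_lt(max(abs(colMeans(X))), 1e-10)
    expect_lt(max(abs(crossprod(X) / nrow(X) - diag(4))), 1e-8)
  }
  # nesting: each level's leading rows are the previous level
  expect_identical(th[["100"]][1:50, ], th[["50"]])
  expect_identical(th[["200"]][1:100, ], th[["100"]])
  # pooled blocks (each zero-mean, identity second moment) stay standardized
  expect_lt(max(abs(crossprod(th[["200"]]) / 200 - diag(4))), 1e-8)
  # an increment not exceeding D cannot be standardized
  expect_error(synthesize_abilities(
    synthesis_spec(S_levels = c(3, 6), D = 4), seed = 1), "increment")
})

test_that("item parameters have the specified scales and per-item zero means", {
  spec <- synthesis_spec(S_levels = 100, I = 30, C = 5, D = 9, gamma = 0.8,
                         intercept_sd = 1.5)
  it <- synthesize_items(spec, seed = 77)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  expect_equal(apply(it$A, 1, pop_sd), dimension_sds(0.8, 9), tolerance = 1e-8)
  expect_equal(pop_sd(it$b), 1.5, tolerance = 1e-8)
  item <- rep(1:30, each = 5)
  for (i in c(1, 13, 30)) {
    expect_lt(max(abs(rowMeans(it$A[, item == i]))), 1e-10)
    expect_lt(abs(mean(it$b[item == i])), 1e-10)
  }
  # whitening leaves no cross-column correlation in [A^T | b^T]
  M <- cbind(t(it$A), it$b)
  Cc <- crossprod(sweep(M, 2, colMeans(M))) / nrow(M)
  expect_lt(max(abs(Cc[upper.tri(Cc)])), 1e-8)
  expect_error(synthesize_items(synthesis_spec(S_levels = 100, I = 2, C = 2,
                                               D = 4), seed = 1), "exceed")
})

test_that("responses are nested, seeded, and uniform when the model is flat", {
  spec <- synthesis_spec(S_levels = c(100, 200), I = 4, C = 5, D = 2,
                         base_seed = 5)
  th <- synthesize_abilities(spec, seed = 11)
  A0 <- matrix(0, 2, 20); b0 <- rep(0, 20)
  R <- synthesize_responses(th, A0, b0, spec, seed = 13)
  expect_identical(R[["200"]][1:100, ], R[["100"]])
  freq <- tabulate(R[["200"]], 5) / length(R[["200"]])
  # 4 binomial SEs: five categories are checked simultaneously
  expect_true(all(abs(freq - 0.2) < 4 * sqrt(0.2 * 0.8 / 800)))
  R2 <- synthesize_responses(th, A0, b0, spec, seed = 13)
  expect_identical(R, R2)
})

test_that("full replications are reproducible with a logged seed ledger", {
  spec <- synthesis_spec(S_levels = c(60, 120), I = 6, C = 4, D = 3,
                         base_seed = 42)
  d1 <- synthesize_dataset(spec, replication = 2)
  d2 <- synthesize_dataset(spec, replication = 2)
  expect_identical(d1$A, d2$A)
  expect_identical(d1$R, d2$R)
  expect_named(d1$seeds, c("replication", "abilities", "items", "responses"))
  d3 <- synthesize_dataset(spec, replication = 3)
  expect_false(identical(d1$A, d3$A))
})

test_that("tendency variance fractions decompose the slope schedule", {
  spec <- synthesis_spec(S_levels = 100, D = 9, gamma = 0.8)
  it <- synthesize_items(spec, seed = 3)
  fr <- tendency_variance_fractions(it$A)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(fr, 0.8^(2 * (0:8)) / sum(0.8^(2 * (0:8))), tolerance = 1e-8)
  # unidimensional: the lone dimension carries everything (slopes-only mode)
  expect_equal(tendency_variance_fractions(it$A[1, , drop = FALSE]), 1,
               tolerance = 1e-12, ignore_attr = TRUE)
  # with intercepts included, fractions shrink by the intercept share
  fr_i <- tendency_variance_fractions(it$A, intercept_sd = 1.5,
                                      include_intercepts = TRUE)
  expect_lt(sum(fr_i), 1)
})

test_that("generator output already satisfies deviation-mode identification", {
  spec <- synthesis_spec(S_levels = 120, I = 10, C = 5, D = 3, gamma = 0.7,
                         base_seed = 8)
  truth <- synthesize_dataset(spec, 1)
  est <- list(params = mncm_params(truth$A, truth$b, truth$Theta[["120"]],
                                   truth$design), sds = NULL)
  fit <- identify_fit(est, truth$design, mode = "deviation",
                      prune_threshold = 0.005)
  expect_equal(fit$A, truth$A, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$b, truth$b, tolerance = 1e-8)
  expect_equal(fit$Theta, truth$Theta[["120"]], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$D_hat, 3L)
})

test_that("sampled category frequencies match model probabilities at large S", {
  # chi-square goodness of fit on pooled per-item category counts, S = 10,000
  spec <- synthesis_spec(S_levels = 10000, I = 10, C = 5, D = 3, gamma = 0.8,
                         base_seed = 31)
  truth <- synthesize_dataset(spec, 1)
  probs <- mncm_probabilities(
    mncm_tendencies(mncm_params(truth$A, truth$b, truth$Theta[["10000"]],
                                truth$design), truth$design), truth$design)
  stat <- 0
  for (i in 1:10) {
    cols <- ((i - 1) * 5 + 1):(i * 5)
    expected <- colSums(probs[, cols])
    observed <- tabulate(truth$R[["10000"]][, i], 5)
    stat <- stat + sum((observed - expected)^2 / expected)
  }
  expect_lt(stat, qchisq(0.99, df = 10 * 4))
})
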