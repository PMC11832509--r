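test_that("instruments have the requested shape and are reproducible", {
  sim <- make_instrument(24, 4, seed = 1)
  expect_equal(nrow(sim$items), 96)
  expect_equal(length(scales(sim$items)), 24)
  expect_equal(dim(sim$population_R), c(96, 96))
  expect_equal(diag(sim$population_R), setNames(rep(1, 96), sim$items$item_id))
  expect_gte(min(eigen(sim$population_R, symmetric = TRUE, only.values = TRUE)$values),
             -1e-10)
  sim2 <- make_instrument(24, 4, seed = 1)
  expect_identical(sim$population_R, sim2$population_R)
  expect_false(identical(make_instrument(24, 4, seed = 2)$population_R,
                         sim$population_R))
})

test_that("degenerate parameter ranges give the exact block structure", {
  sim <- make_instrument(3, 4, loading_range = c(0.8, 0.8),
                         factor_corr_range = c(0, 0), seed = 1)
  R <- sim$population_R
  within <- R[1:4, 1:4][lower.tri(diag(4))]
  expect_equal(within, rep(0.64, 6), tolerance = 1e-12)
  expect_equal(max(abs(R[1:4, 5:12])), 0, tolerance = 1e-12)
})

test_that("infeasible residual injections are rejected before return", {
  expect_error(
    make_instrument(2, 4, loading_range = c(0.8, 0.8), seed = 1,
                    injected_pairs = tibble::tibble(item_i = "q001",
                                                    item_j = "q002",
                                                    value = 0.9)),
    "non-PSD"
  )
})

test_that("latent sampling is consistent with the population matrix", {
  sim <- make_instrument(2, 4, seed = 6)
  resp <- sample_responses(sim, n = 100000, likert = NA, seed = 2)
  expect_lt(max(abs(resp$sample_R - sim$population_R)), 0.02)
})

test_that("symmetric Likert thresholds give centered responses", {
  sim <- make_instrument(2, 4, seed = 6)
  resp <- sample_responses(sim, n = 100000, seed = 3)
  expect_true(all(resp$responses >= 1 & resp$responses <= 5))
  expect_lt(max(abs(colMeans(resp$responses) - 3)), 0.05)
  same <- sample_responses(sim, n = 100000, seed = 3)
  expect_identical(resp$responses, same$responses)
  expect_error(sample_responses(sim, n = 100, thresholds = c(0, -1, 1, 2)),
               "increasing")
  expect_error(sample_responses(sim, n = 5), "at least 10")
})

test_that("pseudo-similarity hits its fidelity target and stays PSD", {
  sim <- make_instrument(24, 4, seed = 1)
  exact <- pseudo_similarity(sim$population_R, 1, seed = 7)
  expect_lt(max(abs(exact$matrix - sim$population_R)), 1e-12)
  expect_equal(exact$achieved_agreement, 1)

  ps <- pseudo_similarity(sim$population_R, 0.67, seed = 7)
  chk <- lower_triangle_correlation(ps$matrix, sim$population_R)
  expect_gte(chk$r, 0.64)
  expect_lte(chk$r, 0.70)
  expect_equal(ps$achieved_agreement, chk$r, tolerance = 1e-12)
  expect_gte(min(eigen(ps$matrix, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_equal(diag(ps$matrix), diag(sim$population_R))
  expect_error(pseudo_similarity(sim$population_R, 0), "target_agreement")
  expect_error(pseudo_similarity(sim$population_R, 1.2), "target_agreement")
})

test_that("population fits recover the generating loadings", {
  set.seed(33)
  for (rep in 1:5) {
    sim <- make_instrument(2, 4, seed = 100 + rep)
    ids <- sim$items$item_id[sim$items$scale_id == "scale_01"]
    fit <- fit_cfa(sim$population_R[ids, ids], cfa_model(ids))
    est <- tidy(fit)
    expect_lt(max(abs(est$estimate[est$kind == "loading"] -
                        sim$true_loadings[ids])), 1e-6)
  }
})

test_that("injected pairs are recovered as top modification index at population level", {
  set.seed(44)
  for (rep in 1:8) {
    l <- runif(4, 0.5, 0.8)
    val <- runif(1, 0.15, 0.3)
    pair <- sort(sample(4, 2))
    S <- pop_one_factor(l, inject = list(pair[1], pair[2], val))
    fit <- quiet_fit(S, cfa_model(rownames(S)))
    mi <- suppressWarnings(modification_indices(fit))
    expect_pair_attains_max(mi, pair[1], pair[2])
  }
})

test_that("a perfect proxy reproduces population verdicts exactly", {
  inj <- tibble::tibble(item_i = c("q001", "q009"), item_j = c("q002", "q011"),
                        value = c(0.25, 0.3))
  sim <- make_instrument(4, 4, seed = 13, injected_pairs = inj)
  out <- verdict_agreement_experiment(sim, target_agreement = 1, n_reps = 2, seed = 5)
  expect_equal(out$disagreement_rate, 0)
  expect_equal(out$confusion["adequate", "misfit"] + out$confusion["misfit", "adequate"], 0)

  clean <- make_instrument(3, 4, seed = 14)
  out2 <- verdict_agreement_experiment(clean, target_agreement = 0.8, n_reps = 3, seed = 6)
  expect_true(all(out2$per_rep$population == "adequate"))
})
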