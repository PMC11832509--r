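test_that("implied matrix follows the factor structure", {
  S <- implied_matrix(c(0.8, 0.7, 0.6))
  expect_equal(S[lower.tri(S)], c(0.56, 0.48, 0.42))
  expect_equal(diag(S), rep(1, 3))

  expect_equal(implied_matrix(c(0, 0, 0)), diag(3))

  Lambda <- rbind(c(0.8, 0), c(0.8, 0), c(0, 0.8), c(0, 0.8))
  Phi <- matrix(c(1, 0.5, 0.5, 1), 2)
  S2 <- implied_matrix(Lambda, Phi)
  expect_equal(S2[1, 3], 0.8 * 0.5 * 0.8)
})

test_that("model degrees of freedom and identification checks are right", {
  m <- cfa_model(paste0("q", 1:4))
  expect_equal(m$df, 2)
  expect_equal(cfa_model(paste0("q", 1:3))$df, 0)
  expect_error(cfa_model(paste0("q", 1:3), residual_pairs = cbind("q1", "q2")),
               "not identified")
  expect_error(cfa_model(paste0("q", 1:4), factors = list(f1 = c("q1", "q9"))),
               "q9")
  expect_error(cfa_model(paste0("q", 1:4), factors = list(f1 = c("q1", "q2", "q3"))),
               "q4")
})

test_that("a just-identified triad is solved in closed form", {
  S <- named_matrix(matrix(c(1, .56, .48, .56, 1, .42, .48, .42, 1), 3), paste0("q", 1:3))
  fit <- fit_cfa(S, cfa_model(paste0("q", 1:3)))
  est <- tidy(fit)
  expect_equal(est$estimate[est$kind == "loading"], c(0.8, 0.7, 0.6), tolerance = 1e-7)
  expect_lt(fit$chisq, 1e-8)
  expect_equal(fit$df, 0)
  expect_true(is.na(fit$rmsea)) # undefined at df = 0, never reported as 0
  expect_true(is.na(fit$tli))
})

test_that("fitting a population-implied matrix recovers truth exactly", {
  set.seed(101)
  for (rep in 1:20) {
    case <- random_spec_case(two_factor = rep %% 3 == 0)
    fit <- fit_cfa(case$S, case$model)
    expect_lt(fit$f_ml, 1e-10)
    est <- tidy(fit)
    lam <- est$estimate[est$kind == "loading"]
    expect_lt(max(abs(sort(abs(lam)) - sort(case$loadings))), 1e-6)
    expect_true(fit$converged)
    expect_lt(fit$grad_norm, 1e-7)
  }
})

test_that("chi-square is (N-1) F and scales linearly in pseudo-N", {
  set.seed(5)
  S <- perturbed_one_factor(5)
  m <- cfa_model(rownames(S))
  f1 <- fit_cfa(S, m, n_pseudo = 10000)
  expect_equal(f1$chisq, (f1$n_pseudo - 1) * f1$f_ml, tolerance = 1e-9)
  f2 <- fit_cfa(S, m, n_pseudo = 2 * (10000 - 1) + 1)
  expect_equal(f2$chisq, 2 * f1$chisq, tolerance = 1e-6)
  # CFI/TLI are near-invariant in N (the df corrections do not scale)
  expect_equal(f2$cfi, f1$cfi, tolerance = 1e-3)
  expect_equal(f2$tli, f1$tli, tolerance = 1e-3)
  expect_equal(f2$srmr, f1$srmr, tolerance = 1e-10)
  # at the formula level, doubling N-1 at fixed T scales RMSEA by exactly
  # 1/sqrt(2)
  i1 <- fit_indices(300, 2, 1000, 6, 10000, S, S)
  i2 <- fit_indices(300, 2, 1000, 6, 2 * 9999 + 1, S, S)
  expect_equal(i2$rmsea, i1$rmsea / sqrt(2), tolerance = 1e-12)
})

test_that("the engine matches an independent ML factor-analysis fit", {
  set.seed(42)
  for (rep in 1:20) {
    p <- sample(4:8, 1)
    S <- perturbed_one_factor(p)
    fit <- fit_cfa(S, cfa_model(rownames(S)))
    fa <- factanal(covmat = S, factors = 1, n.obs = 10000, rotation = "none",
                   control = list(lower = 1e-4))
    N <- 10000
    T1 <- (N - 1) * as.numeric(fa$criteria["objective"])
    df1 <- p * (p + 1) / 2 - 2 * p
    # independence baseline has the closed form F_b = -log det S on a
    # unit-diagonal matrix
    Tb <- (N - 1) * (-as.numeric(determinant(S, logarithm = TRUE)$modulus))
    dfb <- p * (p - 1) / 2
    cfi_o <- 1 - max(T1 - df1, 0) / max(Tb - dfb, T1 - df1, 0)
    tli_o <- ((Tb / dfb) - (T1 / df1)) / ((Tb / dfb) - 1)
    rmsea_o <- sqrt(max(T1 - df1, 0) / (df1 * (N - 1)))
    lam_o <- as.numeric(fa$loadings)
    Sig_o <- tcrossprod(lam_o) + diag(fa$uniquenesses)
    res_o <- S - Sig_o
    srmr_o <- sqrt(mean(res_o[lower.tri(res_o, diag = TRUE)]^2))

    expect_equal(fit$chisq, T1, tolerance = 1e-3)
    expect_equal(fit$cfi, cfi_o, tolerance = 1e-3)
    expect_equal(fit$tli, tli_o, tolerance = 1e-3)
    expect_equal(fit$rmsea, rmsea_o, tolerance = 1e-3)
    expect_equal(fit$srmr, srmr_o, tolerance = 1e-3)
    est <- tidy(fit)
    expect_equal(sort(abs(est$estimate[est$kind == "loading"])), sort(abs(lam_o)),
                 tolerance = 1e-3)
  }
})

test_that("Heywood solutions are bounded, flagged and still produce indices", {
  # triad with r12 r13 / r23 > 1: the implied communality of q1 exceeds 1,
  # so its residual variance is driven to the lower bound
  S <- named_matrix(matrix(c(1, 0.9, 0.8, 0.9, 1, 0.5, 0.8, 0.5, 1), 3),
                    paste0("q", 1:3))
  fit <- quiet_fit(S, cfa_model(paste0("q", 1:3)))
  expect_true(length(fit$heywood) >= 1)
  expect_true(is.finite(fit$cfi) && is.finite(fit$srmr))
  est <- tidy(fit)
  expect_true(all(est$estimate[est$kind == "resid_var"] >= 1e-4 - 1e-12))
})

test_that("near-singular input is ridge-repaired and recorded", {
  l <- c(0.8, 0.7, 0.6, 0.5)
  S <- pop_one_factor(l)
  S[2, ] <- S[1, ]; S[, 2] <- S[, 1]; S[2, 2] <- 1; S[1, 2] <- S[2, 1] <- 1 # duplicate item
  fit <- quiet_fit(S, cfa_model(rownames(S)))
  expect_gt(fit$ridge, 0)
  expect_true(all(is.finite(c(fit$cfi, fit$srmr, fit$rmsea))))

  expect_error(fit_cfa(named_matrix(diag(c(2, 1, 1, 1)), paste0("q", 1:4)),
                       cfa_model(paste0("q", 1:4))), "unit diagonal")
})
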