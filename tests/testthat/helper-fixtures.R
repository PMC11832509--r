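# shared fixture builders; everything is generated in code

two_scale_items <- function() {
  item_set(tibble::tibble(
    item_id = paste0("q", 1:8),
    scale_id = rep(c("hope", "zest"), each = 4),
    text = c(
      "I expect good things to happen", "My future looks bright to me",
      "I usually find a way forward", "I stay hopeful in hard times",
      "I feel full of energy", "I approach each day with excitement",
      "I rarely feel worn out", "I bring enthusiasm to what I do"
    )
  ))
}

named_matrix <- function(M, ids) {
  dimnames(M) <- list(ids, ids)
  M
}

# population correlation matrix of a one-factor model, optionally with one
# injected residual correlation
pop_one_factor <- function(loadings, inject = NULL, ids = paste0("q", seq_along(loadings))) {
  Theta <- diag(1 - loadings^2)
  if (!is.null(inject)) {
    Theta[inject[[1]], inject[[2]]] <- Theta[inject[[2]], inject[[1]]] <- inject[[3]]
  }
  named_matrix(implied_matrix(loadings, theta = Theta), ids)
}

# block population: two factors with correlation phi, same loadings
pop_two_factor <- function(l1, l2, phi, ids = paste0("q", seq_len(length(l1) + length(l2)))) {
  Lambda <- rbind(cbind(l1, 0), cbind(0, l2))
  Phi <- matrix(c(1, phi, phi, 1), 2)
  named_matrix(implied_matrix(Lambda, Phi), ids)
}

# random identified spec + its population matrix, for recovery properties
random_spec_case <- function(p = NULL, two_factor = FALSE) {
  if (is.null(p)) p <- sample(4:8, 1)
  ids <- paste0("q", seq_len(p))
  if (two_factor && p >= 6) {
    p1 <- floor(p / 2)
    l1 <- runif(p1, 0.5, 0.85)
    l2 <- runif(p - p1, 0.5, 0.85)
    phi <- runif(1, 0.1, 0.6)
    S <- pop_two_factor(l1, l2, phi, ids)
    model <- cfa_model(ids, factors = list(f1 = ids[1:p1], f2 = ids[(p1 + 1):p]))
    truth <- c(l1, l2)
  } else {
    l <- runif(p, 0.5, 0.85)
    S <- pop_one_factor(l, ids = ids)
    model <- cfa_model(ids)
    truth <- l
  }
  list(S = S, model = model, loadings = truth, ids = ids)
}

# near-one-factor matrix with a symmetric perturbation, interior solution
# (used where an oracle comparison needs a non-degenerate misfit)
perturbed_one_factor <- function(p, noise_sd = 0.04) {
  L <- runif(p, 0.4, 0.8)
  R0 <- tcrossprod(L) + diag(1 - L^2)
  E <- matrix(rnorm(p * p, 0, noise_sd), p)
  E <- (E + t(E)) / 2
  diag(E) <- 0
  named_matrix(cov2cor(R0 + E), paste0("q", 1:p))
}

quiet_fit <- function(...) suppressWarnings(fit_cfa(...))

# MI value attached to a specific unordered item pair
mi_at_pair <- function(mi, i, j) {
  ids <- paste0("q", sort(c(i, j)))
  mi$mi[mi$lhs == ids[1] & mi$rhs == ids[2]]
}

# in a 4-item one-factor model an injected residual pair is statistically
# indistinguishable from its complement pair, so "top" means attaining the
# maximal MI, allowing for that exact tie
expect_pair_attains_max <- function(mi, i, j) {
  expect_equal(mi_at_pair(mi, i, j), max(mi$mi), tolerance = 1e-6)
}
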