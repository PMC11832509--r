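#' Simulate a multi-scale instrument
#'
#' Builds a synthetic questionnaire shaped like the instruments this
#' package screens: `n_scales` scales of `items_per_scale` items, each
#' scale a one-factor population with loadings drawn uniformly from
#' `loading_range` and between-factor correlations drawn from
#' `factor_corr_range`. Local misfit can be injected as residual
#' correlations between chosen item pairs — the mechanism by which
#' redundantly worded items break unidimensionality. The population
#' correlation matrix is `Lambda Phi Lambda' + Theta` with unit diagonal.
#' Item texts are synthetic.
#'
#' Defaults emulate a 24-scale, 4-items-per-scale character-strengths style
#' inventory with moderately strong items (loadings 0.5-0.85) and modestly
#' correlated traits (0.1-0.5).
#'
#' @param n_scales Number of scales (factors).
#' @param items_per_scale Items per scale (default 4).
#' @param loading_range Range for uniform loading draws.
#' @param factor_corr_range Range for uniform between-factor correlation
#'   draws; the drawn matrix is shrunk toward the identity if it is not
#'   positive definite.
#' @param injected_pairs Optional data frame with columns `item_i`,
#'   `item_j` (item ids or 1-based positions) and `value`: residual
#'   correlations to inject. An injection that makes the residual matrix
#'   non-PSD is an error.
#' @param seed Integer seed; the instrument is reproducible for a fixed
#'   seed.
#' @return An object of class `sembed_instrument`: `items`
#'   (`sembed_items`), `true_loadings` (named vector), `factor_corr`,
#'   `population_R`, `injected_pairs`, `seed`.
#' @export
make_instrument <- function(n_scales, items_per_scale = 4,
                            loading_range = c(0.5, 0.85),
                            factor_corr_range = c(0.1, 0.5),
                            injected_pairs = NULL, seed = 1) {
  stopifnot(n_scales >= 1, items_per_scale >= 1)
  if (loading_range[1] <= 0 || loading_range[2] >= 1 ||
      loading_range[1] > loading_range[2]) {
    abort("loading_range must be within (0, 1) and increasing")
  }
  set.seed(seed)
  p <- n_scales * items_per_scale
  scale_ids <- sprintf("scale_%02d", seq_len(n_scales))
  items <- item_set(tibble::tibble(
    item_id = sprintf("q%03d", seq_len(p)),
    scale_id = rep(scale_ids, each = items_per_scale),
    text = synth_item_texts(n_scales, items_per_scale)
  ))
  lambda <- runif(p, loading_range[1], loading_range[2])
  names(lambda) <- items$item_id
  Phi <- diag(n_scales)
  if (n_scales >= 2) {
    off <- runif(n_scales * (n_scales - 1) / 2,
                 factor_corr_range[1], factor_corr_range[2])
    Phi[lower.tri(Phi)] <- off
    Phi <- Phi + t(Phi) - diag(diag(Phi))
    # shrink toward identity until PD (a draw of uniform correlations need
    # not be a valid correlation matrix for many factors)
    while (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
      Phi <- 0.9 * Phi + 0.1 * diag(n_scales)
    }
  }
  dimnames(Phi) <- list(scale_ids, scale_ids)
  Lambda <- matrix(0, p, n_scales, dimnames = list(items$item_id, scale_ids))
  for (s in seq_len(n_scales)) {
    members <- items$item_id[items$scale_id == scale_ids[s]]
    Lambda[members, s] <- lambda[members]
  }
  Theta <- diag(1 - lambda^2)
  dimnames(Theta) <- list(items$item_id, items$item_id)
  inj <- normalize_injection(injected_pairs, items$item_id)
  if (!is.null(inj)) {
    for (k in seq_len(nrow(inj))) {
      Theta[inj$item_i[k], inj$item_j[k]] <- inj$value[k]
      Theta[inj$item_j[k], inj$item_i[k]] <- inj$value[k]
    }
    if (min(eigen(Theta, symmetric = TRUE, only.values = TRUE)$values) < 0) {
      abort("injected residual correlations make the residual matrix non-PSD")
    }
  }
  R <- implied_matrix(Lambda, Phi, Theta)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort("population matrix is not PSD") # cannot happen if Phi, Theta are PSD
  }
  structure(
    list(items = items, true_loadings = lambda, factor_corr = Phi,
         true_lambda = Lambda, true_theta = Theta,
         injected_pairs = inj, population_R = R, seed = seed),
    class = "sembed_instrument"
  )
}

normalize_injection <- function(injected_pairs, item_ids) {
  if (is.null(injected_pairs) || NROW(injected_pairs) == 0) return(NULL)
  inj <- tibble::as_tibble(injected_pairs)
  if (!all(c("item_i", "item_j", "value") %in% names(inj))) {
    abort("injected_pairs needs columns item_i, item_j, value")
  }
  to_id <- function(x) if (is.numeric(x)) item_ids[x] else as.character(x)
  inj$item_i <- to_id(inj$item_i)
  inj$item_j <- to_id(inj$item_j)
  if (anyNA(inj$item_i) || anyNA(inj$item_j) ||
      !all(c(inj$item_i, inj$item_j) %in% item_ids)) {
    abort("injected_pairs reference unknown items")
  }
  inj
}

# deterministic filler texts; real instruments embed real wording, these
# only need to be distinct and scale-tagged
synth_item_texts <- function(n_scales, items_per_scale) {
  stems <- c("I often", "I always", "People say I", "I tend to",
             "In daily life I", "Whenever possible I", "I genuinely",
             "Even under pressure I")
  acts <- c("approach tasks related to", "enjoy situations involving",
            "show the qualities of", "act in ways that express",
            "seek out opportunities for", "feel energized by",
            "stay committed to", "value moments of")
  unlist(lapply(seq_len(n_scales), function(s) {
    vapply(seq_len(items_per_scale), function(i) {
      sprintf("%s %s trait area %02d (form %d).",
              stems[(i - 1) %% length(stems) + 1],
              acts[(s + i - 2) %% length(acts) + 1], s, i)
    }, character(1))
  }))
}

#' @export
print.sembed_instrument <- function(x, ...) {
  cat(sprintf("<synthetic instrument: %d items, %d scales, %d injected residual pair(s), seed %d>\n",
              nrow(x$items), length(scales(x$items)),
              if (is.null(x$injected_pairs)) 0L else nrow(x$injected_pairs), x$seed))
  invisible(x)
}

#' Sample Likert responses from an instrument population
#'
#' Draws latent multivariate-normal scores with correlation matrix
#' `population_R` and, for `likert = 5`, discretizes them into 1-5
#' categories at the given standard-normal thresholds (default:
#' equal-probability quintile cuts, a symmetric choice giving mean response
#' 3).
#'
#' @param sim A `sembed_instrument`.
#' @param n Number of respondents (at least 10).
#' @param likert `5` for 5-point discretization or `NA`/`"none"` for raw
#'   continuous scores.
#' @param thresholds Increasing cut points on the latent scale.
#' @param seed Integer seed.
#' @return A list: `responses` (tibble, one row per respondent) and
#'   `sample_R` (Pearson correlation matrix of the responses).
#' @export
sample_responses <- function(sim, n, likert = 5,
                             thresholds = qnorm(c(0.2, 0.4, 0.6, 0.8)),
                             seed = 1) {
  stopifnot(inherits(sim, "sembed_instrument"))
  if (n < 10) abort("n must be at least 10")
  use_likert <- !(is.na(likert) || identical(likert, "none"))
  if (use_likert) {
    if (!identical(as.numeric(likert), 5)) abort("only 5-point Likert is supported")
    if (is.unsorted(thresholds, strictly = TRUE)) {
      abort("thresholds must be strictly increasing")
    }
  }
  set.seed(seed)
  R <- sim$population_R
  p <- nrow(R)
  L <- chol(R + diag(1e-12, p))
  Z <- matrix(rnorm(n * p), n, p) %*% L
  colnames(Z) <- sim$items$item_id
  X <- if (use_likert) {
    apply(Z, 2, function(z) findInterval(z, thresholds) + 1L)
  } else {
    Z
  }
  colnames(X) <- sim$items$item_id
  list(
    responses = tibble::as_tibble(X),
    sample_R = cor(X)
  )
}

#' Degrade a population matrix into a pseudo-similarity matrix
#'
#' Emulates an embedding-derived similarity matrix of controlled fidelity:
#' seeded Gaussian noise is added to the off-diagonal entries and its scale
#' is tuned iteratively so that the lower-triangle Pearson correlation with
#' the source matrix hits `target_agreement` (within 0.03); the result is
#' then projected to the nearest unit-diagonal PSD matrix by eigenvalue
#' clipping and renormalization, and the achieved agreement is recomputed
#' on the final matrix. `target_agreement = 1` returns the source matrix
#' unchanged.
#'
#' @param R Symmetric unit-diagonal source matrix (e.g. `population_R`).
#' @param target_agreement Desired lower-triangle correlation, in (0, 1].
#' @param seed Integer seed.
#' @param tol Acceptable |achieved - target| (default 0.03).
#' @return A list of class `sembed_pseudo_sim`: `matrix`,
#'   `target_agreement`, `achieved_agreement`, `seed`.
#' @export
pseudo_similarity <- function(R, target_agreement, seed = 1, tol = 0.03) {
  check_square(R, "R")
  if (!(target_agreement > 0 && target_agreement <= 1)) {
    abort("target_agreement must be in (0, 1]")
  }
  if (target_agreement == 1) {
    return(structure(list(matrix = R, target_agreement = 1,
                          achieved_agreement = 1, seed = seed),
                     class = "sembed_pseudo_sim"))
  }
  set.seed(seed)
  p <- nrow(R)
  n_off <- p * (p - 1) / 2
  r_off <- R[lower.tri(R)]
  noise <- rnorm(n_off)
  # starting scale from the closed form cor(r + e, r) = sd_r/sqrt(sd_r^2+s^2)
  s <- sd(r_off) * sqrt(1 / target_agreement^2 - 1)
  build <- function(s) {
    M <- R
    M[lower.tri(M)] <- r_off + s * noise
    M <- t(M)
    M[lower.tri(M)] <- r_off + s * noise
    psd_correlation(M)
  }
  achieved <- function(M) cor(M[lower.tri(M)], r_off)
  M <- build(s)
  a <- achieved(M)
  for (iter in seq_len(25)) {
    if (abs(a - target_agreement) <= tol) break
    # PSD repair attenuates noise; rescale s by the implied-variance ratio
    ratio <- sqrt((1 / target_agreement^2 - 1) / max(1 / a^2 - 1, 1e-12))
    s <- s * ratio
    M <- build(s)
    a <- achieved(M)
  }
  structure(list(matrix = M, target_agreement = target_agreement,
                 achieved_agreement = a, seed = seed),
            class = "sembed_pseudo_sim")
}

# nearest-in-spirit unit-diagonal PSD repair: clip eigenvalues, renormalize
psd_correlation <- function(M, floor = 1e-7) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  M2 <- e$vectors %*% diag(vals) %*% t(e$vectors)
  M2 <- cov2cor(M2)
  M2 <- (M2 + t(M2)) / 2
  dimnames(M2) <- dimnames(M)
  M2
}

#' @export
print.sembed_pseudo_sim <- function(x, ...) {
  cat(sprintf("<pseudo-similarity: %d items, target %.2f, achieved %.3f, seed %d>\n",
              nrow(x$matrix), x$target_agreement, x$achieved_agreement, x$seed))
  invisible(x)
}

#' Verdict agreement between the similarity arm and the population arm
#'
#' The central validation experiment for pre-data screening: how often does
#' screening on an imperfect similarity proxy reach the same
#' adequate/misfit verdict as screening on the true population correlation
#' matrix? For each replicate a fresh pseudo-similarity matrix of the given
#' fidelity is generated and both arms are screened scale by scale; the
#' cross-classification is accumulated over replicates.
#'
#' @param sim A `sembed_instrument`.
#' @param target_agreement Fidelity of the proxy, in (0, 1].
#' @param n_reps Number of replicates (each with its own derived seed).
#' @param seed Integer master seed; replicate r uses `seed + r`.
#' @param n_pseudo,cutoffs Passed to [unidimensional_screen()].
#' @return A list of class `sembed_verdict_agreement`: `confusion` (2x2
#'   table proxy x population), `disagreement_rate`, `sensitivity` and
#'   `specificity` of the proxy for population misfit (NA when undefined),
#'   `n_reps`, `target_agreement`, `per_rep` tibble.
#' @export
verdict_agreement_experiment <- function(sim, target_agreement, n_reps,
                                         seed = 1, n_pseudo = 10000,
                                         cutoffs = c(incremental = 0.90, absolute = 0.08)) {
  stopifnot(inherits(sim, "sembed_instrument"), n_reps >= 1)
  pop_screen <- unidimensional_screen(sim$population_R, sim$items,
                                      n_pseudo = n_pseudo, cutoffs = cutoffs)
  pop_verdict <- setNames(pop_screen$verdict, pop_screen$scale_id)
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(r) {
    ps <- pseudo_similarity(sim$population_R, target_agreement, seed = seed + r)
    prox <- unidimensional_screen(ps$matrix, sim$items,
                                  n_pseudo = n_pseudo, cutoffs = cutoffs)
    tibble::tibble(
      rep = r, scale_id = prox$scale_id,
      proxy = prox$verdict,
      population = unname(pop_verdict[prox$scale_id])
    )
  })
  confusion <- table(proxy = factor(per_rep$proxy, c("adequate", "misfit")),
                     population = factor(per_rep$population, c("adequate", "misfit")))
  pop_mis <- sum(confusion[, "misfit"])
  pop_ok <- sum(confusion[, "adequate"])
  structure(
    list(
      confusion = confusion,
      disagreement_rate = mean(per_rep$proxy != per_rep$population),
      sensitivity = if (pop_mis > 0) confusion["misfit", "misfit"] / pop_mis else NA_real_,
      specificity = if (pop_ok > 0) confusion["adequate", "adequate"] / pop_ok else NA_real_,
      n_reps = n_reps, target_agreement = target_agreement,
      per_rep = per_rep
    ),
    class = "sembed_verdict_agreement"
  )
}

#' @export
print.sembed_verdict_agreement <- function(x, ...) {
  cat(sprintf("<verdict agreement: fidelity %.2f, %d reps, disagreement %.3f>\n",
              x$target_agreement, x$n_reps, x$disagreement_rate))
  print(x$confusion)
  invisible(x)
}
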