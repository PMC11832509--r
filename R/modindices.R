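#' Modification indices for a fitted CFA
#'
#' Estimates, for every currently fixed residual covariance (and, in
#' multi-factor models, every fixed cross-loading), the chi-square
#' improvement expected from freeing that one parameter. Large values point
#' to local misfit — typically pairs of items whose wording makes them
#' correlate beyond what the common factor explains.
#'
#' Two routes are provided. `method = "refit"` actually refits the model
#' with the candidate freed and reports the exact nested chi-square
#' difference `T_restricted - T_freed`. `method = "score"` is the classical
#' univariate score (Lagrange multiplier) test from the expected
#' information, `MI = (N-1)/2 * g_k^2 / (d_kk - d_kf d_ff^-1 d_fk)` with
#' `d_ab = tr(Sigma^-1 dSigma_a Sigma^-1 dSigma_b)` and `g_k` the
#' discrepancy gradient at the solution; it needs no refitting and
#' converges to the refit value as the freed estimate goes to zero.
#'
#' @param fit A converged `sembed_cfa` object.
#' @param method `"score"` (default) or `"refit"`.
#' @return A tibble of class `sembed_mi`, sorted by decreasing `mi`, with
#'   columns `param` (`residual_cov` or `cross_loading`), `lhs`, `rhs`,
#'   `mi`, `rank` and, for refits, `converged` (non-convergent candidate
#'   refits are flagged, not dropped).
#' @export
modification_indices <- function(fit, method = c("score", "refit")) {
  stopifnot(inherits(fit, "sembed_cfa"))
  method <- match.arg(method)
  if (!fit$converged) {
    warn("modification indices computed on a non-converged fit")
  }
  cand <- mi_candidates(fit$model)
  if (nrow(cand) == 0) {
    return(structure(
      tibble::tibble(param = character(), lhs = character(), rhs = character(),
                     mi = numeric(), rank = integer()),
      class = c("sembed_mi", class(tibble::tibble()))
    ))
  }
  out <- if (method == "score") mi_score(fit, cand) else mi_refit(fit, cand)
  out <- dplyr::arrange(out, dplyr::desc(.data$mi))
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("sembed_mi", class(tibble::tibble())))
}

# every fixed-to-zero residual covariance and (for m >= 2) cross-loading
mi_candidates <- function(model) {
  p <- length(model$item_ids)
  pairs <- which(upper.tri(diag(p)), arr.ind = TRUE)
  free <- rep(FALSE, nrow(pairs))
  if (nrow(model$resid_pairs) > 0) {
    key_free <- paste(model$resid_pairs[, 1], model$resid_pairs[, 2])
    free <- paste(pairs[, 1], pairs[, 2]) %in% key_free
  }
  res <- data.frame(
    param = "residual_cov",
    kind = "theta_od",
    row = pairs[!free, 1], col = pairs[!free, 2]
  )
  out <- res
  if (length(model$factor_ids) >= 2) {
    fixedl <- which(!model$pattern, arr.ind = TRUE)
    if (nrow(fixedl) > 0) {
      out <- rbind(out, data.frame(
        param = "cross_loading", kind = "lambda",
        row = fixedl[, 1], col = fixedl[, 2]
      ))
    }
  }
  out
}

cand_labels <- function(model, cand) {
  lhs <- ifelse(cand$kind == "lambda",
                model$factor_ids[cand$col], model$item_ids[cand$row])
  rhs <- ifelse(cand$kind == "lambda",
                model$item_ids[cand$row], model$item_ids[cand$col])
  list(lhs = lhs, rhs = rhs)
}

mi_score <- function(fit, cand) {
  model <- fit$model
  S <- fit$S
  mats <- fit$estimates
  Sigma <- fit$Sigma
  Siginv <- chol2inv(chol(Sigma))
  G <- Siginv - Siginv %*% S %*% Siginv
  idx <- param_index(model)
  derivs_free <- lapply(seq_len(nrow(idx)), function(k) {
    param_deriv(model, mats, idx$kind[k], idx$row[k], idx$col[k])
  })
  M_free <- lapply(derivs_free, function(D) Siginv %*% D)
  q <- length(M_free)
  Dff <- matrix(0, q, q)
  for (a in seq_len(q)) {
    for (b in a:q) {
      Dff[a, b] <- Dff[b, a] <- sum(M_free[[a]] * t(M_free[[b]]))
    }
  }
  Dff_inv <- pinv(Dff)
  mi <- numeric(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    Dk <- param_deriv(model, mats, cand$kind[k], cand$row[k], cand$col[k])
    Mk <- Siginv %*% Dk
    gk <- sum(G * Dk)
    dkk <- sum(Mk * t(Mk))
    dkf <- vapply(M_free, function(Ma) sum(Mk * t(Ma)), numeric(1))
    denom <- dkk - as.numeric(t(dkf) %*% Dff_inv %*% dkf)
    mi[k] <- if (denom <= .Machine$double.eps) 0 else
      (fit$n_pseudo - 1) / 2 * gk^2 / denom
  }
  lab <- cand_labels(model, cand)
  tibble::tibble(param = cand$param, lhs = lab$lhs, rhs = lab$rhs,
                 mi = pmax(mi, 0))
}

mi_refit <- function(fit, cand) {
  model <- fit$model
  mi <- numeric(nrow(cand))
  conv <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    freed <- free_candidate(model, cand$kind[k], cand$row[k], cand$col[k])
    refit <- fit_cfa(fit$S, freed, n_pseudo = fit$n_pseudo, fit_baseline = FALSE)
    mi[k] <- max(fit$chisq - refit$chisq, 0)
    conv[k] <- refit$converged
  }
  lab <- cand_labels(model, cand)
  tibble::tibble(param = cand$param, lhs = lab$lhs, rhs = lab$rhs,
                 mi = mi, converged = conv)
}

free_candidate <- function(model, kind, row, col) {
  if (kind == "theta_od") {
    rp <- rbind(model$resid_pairs, c(row, col))
    factors <- pattern_to_factors(model)
    cfa_model(model$item_ids, factors = factors,
              residual_pairs = matrix(model$item_ids[t(rp)], ncol = 2, byrow = TRUE))
  } else {
    pattern <- model$pattern
    pattern[row, col] <- TRUE
    factors <- lapply(seq_len(ncol(pattern)), function(f) model$item_ids[pattern[, f]])
    names(factors) <- model$factor_ids
    rp <- model$resid_pairs
    rpm <- if (nrow(rp) > 0) matrix(model$item_ids[t(rp)], ncol = 2, byrow = TRUE) else NULL
    cfa_model(model$item_ids, factors = factors, residual_pairs = rpm)
  }
}

pattern_to_factors <- function(model) {
  factors <- lapply(seq_len(ncol(model$pattern)), function(f) {
    model$item_ids[model$pattern[, f]]
  })
  names(factors) <- model$factor_ids
  factors
}

# Moore-Penrose pseudoinverse via SVD (information matrices can be singular
# at boundary solutions)
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 1)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
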