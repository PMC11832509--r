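#' Fit a CFA by maximum likelihood to a (pseudo-)correlation matrix
#'
#' Minimizes the normal-theory ML discrepancy
#' `F = log det(Sigma) - log det(S) + tr(S Sigma^-1) - p`
#' over the free parameters of `model`, where `S` is either an empirical
#' correlation matrix or an embedding cosine-similarity matrix used as a
#' pseudo-correlation matrix. Because similarity matrices are not estimated
#' from respondents, a nominal sample size `n_pseudo` (default 10000) is
#' supplied so that the chi-square statistic `T = (N - 1) F` and the usual
#' fit indices are computable.
#'
#' Optimization is quasi-Newton (`nlminb`) with the analytic gradient
#' `dF/dt = tr[(Sigma^-1 - Sigma^-1 S Sigma^-1) dSigma/dt]`. Residual
#' variances are box-bounded below at `1e-4`; estimates at that bound are
#' reported as Heywood items and the fit is still returned (badly
#' misspecified models must yield indices, not errors). Nearly singular
#' input is repaired by a recorded diagonal ridge followed by
#' renormalization to unit diagonal.
#'
#' @param S Symmetric matrix with unit diagonal, dimnames covering the
#'   model's item ids.
#' @param model A `sembed_model` (see [cfa_model()]).
#' @param n_pseudo Nominal sample size for the chi-square scale.
#' @param fit_baseline Fit the independence baseline (needed for CFI/TLI);
#'   set `FALSE` to skip when only the discrepancy is needed.
#' @param control Optimizer overrides passed to [stats::nlminb()].
#' @return An object of class `sembed_cfa`; see [glance.sembed_cfa()] and
#'   [tidy.sembed_cfa()] for tibble views.
#' @examples
#' S <- implied_matrix(c(0.8, 0.7, 0.6, 0.5))
#' dimnames(S) <- list(paste0("q", 1:4), paste0("q", 1:4))
#' fit <- fit_cfa(S, cfa_model(paste0("q", 1:4)))
#' glance(fit)
#' @export
fit_cfa <- function(S, model, n_pseudo = 10000, fit_baseline = TRUE,
                    control = list()) {
  stopifnot(inherits(model, "sembed_model"))
  check_square(S, "input matrix")
  if (is.null(rownames(S))) {
    if (nrow(S) != length(model$item_ids)) abort("unnamed matrix of wrong dimension")
    dimnames(S) <- list(model$item_ids, model$item_ids)
  }
  if (!all(model$item_ids %in% rownames(S))) {
    abort("matrix does not cover all model items")
  }
  S <- sub_matrix(S, model$item_ids)
  if (max(abs(diag(S) - 1)) > 1e-6) {
    abort("input matrix must have unit diagonal (correlation scale)")
  }
  rep <- repair_matrix(S)
  S <- rep$S
  p <- nrow(S)

  fit <- ml_minimize(S, model, start_values(S, model), control)
  Sigma <- implied_sigma(model, fit$par)
  mats <- par_to_matrices(model, fit$par)
  heywood <- model$item_ids[diag(mats$Theta) <= theta_lb() + 1e-10]

  chisq <- (n_pseudo - 1) * fit$objective
  if (fit_baseline) {
    base <- fit_baseline_model(S, model, control)
    baseline_chisq <- (n_pseudo - 1) * base$objective
    baseline_df <- p * (p + 1) / 2 - p
  } else {
    baseline_chisq <- NA_real_
    baseline_df <- NA_real_
  }
  idx <- if (fit_baseline) {
    fit_indices(chisq, model$df, baseline_chisq, baseline_df, n_pseudo, S, Sigma)
  } else {
    tibble::tibble(cfi = NA_real_, tli = NA_real_, srmr = srmr_value(S, Sigma),
                   rmsea = NA_real_)
  }
  if (!fit$converged) {
    warn(sprintf("CFA did not converge (projected gradient norm %.2e)", fit$grad_norm))
  }
  structure(
    list(
      model = model, estimates = mats, par = fit$par,
      f_ml = fit$objective, chisq = chisq, df = model$df,
      n_pseudo = n_pseudo,
      baseline_chisq = baseline_chisq, baseline_df = baseline_df,
      cfi = idx$cfi, tli = idx$tli, srmr = idx$srmr, rmsea = idx$rmsea,
      converged = fit$converged, n_iter = fit$n_iter,
      grad_norm = fit$grad_norm, heywood = heywood,
      ridge = rep$ridge, S = S, Sigma = Sigma
    ),
    class = "sembed_cfa"
  )
}

theta_lb <- function() 1e-4

# ridge-repair a near-singular pseudo-correlation matrix, then renormalize
repair_matrix <- function(S, min_eig = 1e-8) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ridge <- 0
  if (min(ev) < min_eig) {
    ridge <- (min_eig - min(ev)) + min_eig
    S <- cov2cor(S + diag(ridge, nrow(S)))
    S <- (S + t(S)) / 2
    ev2 <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev2) < 0) abort("matrix remains non-positive-definite after ridge repair")
  }
  list(S = S, ridge = ridge)
}

start_values <- function(S, model) {
  idx <- param_index(model)
  p <- length(model$item_ids)
  lam0 <- numeric(p)
  for (f in seq_along(model$factor_ids)) {
    members <- which(model$pattern[, f])
    if (length(members) >= 2) {
      rbar <- mean(S[members, members][lower.tri(diag(length(members)))])
    } else {
      rbar <- 0.25
    }
    lam0[members] <- sqrt(max(rbar, 0.04))
  }
  par <- numeric(nrow(idx))
  for (k in seq_len(nrow(idx))) {
    par[k] <- switch(idx$kind[k],
      lambda = lam0[idx$row[k]],
      phi = 0,
      theta_d = max(1 - lam0[idx$row[k]]^2, 0.1),
      theta_od = 0
    )
  }
  par
}

param_bounds <- function(model) {
  idx <- param_index(model)
  lower <- vapply(idx$kind, function(k) switch(k,
    lambda = -5, phi = -0.999, theta_d = theta_lb(), theta_od = -0.999), numeric(1))
  upper <- vapply(idx$kind, function(k) switch(k,
    lambda = 5, phi = 0.999, theta_d = 10, theta_od = 0.999), numeric(1))
  list(lower = lower, upper = upper)
}

ml_objective <- function(S, model, logdetS) {
  force(S); force(logdetS)
  function(par) {
    Sigma <- implied_sigma(model, par)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Siginv <- chol2inv(R)
    2 * sum(log(diag(R))) - logdetS + sum(S * Siginv) - nrow(S)
  }
}

ml_gradient <- function(S, model) {
  idx <- param_index(model)
  function(par) {
    mats <- par_to_matrices(model, par)
    Sigma <- implied_matrix(mats$Lambda, mats$Phi, mats$Theta)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) return(numeric(nrow(idx)))
    Siginv <- chol2inv(R)
    G <- Siginv - Siginv %*% S %*% Siginv
    GLP <- if (ncol(mats$Lambda) > 0) G %*% mats$Lambda %*% mats$Phi else NULL
    LGL <- if (ncol(mats$Lambda) > 0) t(mats$Lambda) %*% G %*% mats$Lambda else NULL
    g <- numeric(nrow(idx))
    for (k in seq_len(nrow(idx))) {
      g[k] <- switch(idx$kind[k],
        lambda = 2 * GLP[idx$row[k], idx$col[k]],
        phi = 2 * LGL[idx$row[k], idx$col[k]],
        theta_d = G[idx$row[k], idx$row[k]],
        theta_od = 2 * G[idx$row[k], idx$col[k]]
      )
    }
    g
  }
}

ml_minimize <- function(S, model, start, control = list()) {
  logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  obj <- ml_objective(S, model, logdetS)
  grd <- ml_gradient(S, model)
  b <- param_bounds(model)
  ctrl <- utils::modifyList(
    list(iter.max = 500, eval.max = 2000, rel.tol = 1e-14, abs.tol = 0,
         x.tol = 1.5e-12),
    control
  )
  proj_gnorm <- function(par) {
    g <- grd(par)
    # project out gradient components held by an active box bound
    at_lo <- par <= b$lower + 1e-12
    at_hi <- par >= b$upper - 1e-12
    g[at_lo & g > 0] <- 0
    g[at_hi & g < 0] <- 0
    if (length(g) > 0) max(abs(g)) else 0
  }
  res <- nlminb(start, obj, gradient = grd, lower = b$lower, upper = b$upper,
                control = ctrl)
  gnorm <- proj_gnorm(res$par)
  # polish: restart from the solution; cheap and tightens the gradient norm
  for (try in 1:3) {
    if (gnorm < 1e-7) break
    res2 <- nlminb(res$par, obj, gradient = grd, lower = b$lower, upper = b$upper,
                   control = ctrl)
    g2 <- proj_gnorm(res2$par)
    if (res2$objective <= res$objective || g2 < gnorm) {
      res <- res2; gnorm <- g2
    } else break
  }
  if (gnorm >= 1e-7) {
    # Fisher-scoring polish: Newton steps on the expected information,
    # the standard SEM refinement when a quasi-Newton run stalls
    fp <- fisher_polish(S, model, res$par, obj, grd, b, gnorm, proj_gnorm)
    if (fp$gnorm < gnorm) {
      res$par <- fp$par; res$objective <- fp$objective; gnorm <- fp$gnorm
    }
  }
  list(
    par = res$par,
    objective = max(res$objective, 0),
    converged = gnorm < 1e-6,
    grad_norm = gnorm,
    n_iter = res$iterations
  )
}

fisher_polish <- function(S, model, par, obj, grd, b, gnorm, proj_gnorm,
                          max_steps = 5) {
  idx <- param_index(model)
  fval <- obj(par)
  for (step in seq_len(max_steps)) {
    if (gnorm < 1e-9) break
    mats <- par_to_matrices(model, par)
    Sigma <- implied_matrix(mats$Lambda, mats$Phi, mats$Theta)
    R <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(R)) break
    Siginv <- chol2inv(R)
    M <- lapply(seq_len(nrow(idx)), function(k) {
      Siginv %*% param_deriv(model, mats, idx$kind[k], idx$row[k], idx$col[k])
    })
    q <- length(M)
    D <- matrix(0, q, q)
    for (a in seq_len(q)) for (bb in a:q) {
      D[a, bb] <- D[bb, a] <- sum(M[[a]] * t(M[[bb]]))
    }
    g <- grd(par)
    dir <- tryCatch(-solve(D + diag(1e-10, q), g), error = function(e) NULL)
    if (is.null(dir)) break
    improved <- FALSE
    for (t in c(1, 0.5, 0.25, 0.1)) {
      cand <- pmin(pmax(par + t * dir, b$lower), b$upper)
      fc <- obj(cand)
      gc <- proj_gnorm(cand)
      if (fc <= fval + 1e-14 && gc < gnorm) {
        par <- cand; fval <- fc; gnorm <- gc; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(par = par, objective = fval, gnorm = gnorm)
}

# independence baseline: zero factors, free residual variances, same engine
fit_baseline_model <- function(S, model, control = list()) {
  base_model <- structure(
    list(item_ids = model$item_ids, factor_ids = character(0),
         pattern = matrix(FALSE, length(model$item_ids), 0,
                          dimnames = list(model$item_ids, NULL)),
         resid_pairs = matrix(integer(0), 0, 2),
         n_free = length(model$item_ids),
         df = length(model$item_ids) * (length(model$item_ids) + 1) / 2 -
              length(model$item_ids)),
    class = "sembed_model"
  )
  base_model$pidx <- param_index_build(base_model)
  ml_minimize(S, base_model, diag(S), control)
}

#' Fit indices for a covariance-structure model
#'
#' Computes CFI, TLI, SRMR and RMSEA from the chi-square statistics of the
#' target and independence-baseline models:
#' `CFI = 1 - max(T - df, 0) / max(Tb - dfb, T - df, 0)`;
#' `TLI = ((Tb/dfb) - (T/df)) / ((Tb/dfb) - 1)`, uncapped (it may exceed 1
#' or go negative);
#' `RMSEA = sqrt(max(T - df, 0) / (df (N - 1)))`;
#' `SRMR` is the root mean square of the standardized residuals
#' `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the lower triangle including
#' the diagonal. For saturated models (`df = 0`), TLI and RMSEA are
#' undefined and reported as `NA`, never as 0.
#'
#' @param chisq,df Target-model chi-square and degrees of freedom.
#' @param baseline_chisq,baseline_df Independence-model chi-square and df.
#' @param n_pseudo Nominal sample size.
#' @param S Observed (pseudo-)correlation matrix.
#' @param Sigma Model-implied matrix.
#' @return One-row tibble with columns `cfi`, `tli`, `srmr`, `rmsea`.
#' @export
fit_indices <- function(chisq, df, baseline_chisq, baseline_df, n_pseudo,
                        S, Sigma) {
  num <- max(chisq - df, 0)
  den <- max(baseline_chisq - baseline_df, chisq - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  tli <- if (df <= 0 || baseline_df <= 0) {
    NA_real_
  } else {
    rb <- baseline_chisq / baseline_df
    if (abs(rb - 1) < .Machine$double.eps^0.5) NA_real_
    else (rb - chisq / df) / (rb - 1)
  }
  rmsea <- if (df <= 0) NA_real_ else sqrt(max(chisq - df, 0) / (df * (n_pseudo - 1)))
  tibble::tibble(cfi = cfi, tli = tli, srmr = srmr_value(S, Sigma), rmsea = rmsea)
}

srmr_value <- function(S, Sigma) {
  d <- sqrt(diag(S))
  Rres <- (S - Sigma) / tcrossprod(d)
  vals <- Rres[lower.tri(Rres, diag = TRUE)]
  sqrt(mean(vals^2))
}

#' Classify a fit as adequate or misfit
#'
#' Applies the screening rule used throughout the package: an index is
#' "poor" when CFI or TLI falls below the incremental cutoff (default 0.90)
#' or SRMR or RMSEA rises above the absolute cutoff (default 0.08); a model
#' is declared a misfit when two or more of the four indices are poor. An
#' undefined index (saturated model) counts as not-poor and is listed in
#' `na_indices`.
#'
#' @param fit A `sembed_cfa` object, or anything with elements `cfi`,
#'   `tli`, `srmr`, `rmsea`.
#' @param cutoffs Named numeric vector `c(incremental = , absolute = )`.
#' @return A list of class `sembed_verdict`: `poor` (named logical),
#'   `n_poor`, `verdict` (`"adequate"` or `"misfit"`), `na_indices`.
#' @export
classify_fit <- function(fit, cutoffs = c(incremental = 0.90, absolute = 0.08)) {
  vals <- c(cfi = as.numeric(fit$cfi), tli = as.numeric(fit$tli),
            srmr = as.numeric(fit$srmr), rmsea = as.numeric(fit$rmsea))
  c1 <- cutoffs[["incremental"]]; c2 <- cutoffs[["absolute"]]
  if (!(c1 > 0 && c1 < 1) || !(c2 > 0)) abort("invalid cutoffs")
  poor <- c(
    cfi = !is.na(vals["cfi"]) && vals[["cfi"]] < c1,
    tli = !is.na(vals["tli"]) && vals[["tli"]] < c1,
    srmr = !is.na(vals["srmr"]) && vals[["srmr"]] > c2,
    rmsea = !is.na(vals["rmsea"]) && vals[["rmsea"]] > c2
  )
  n_poor <- sum(poor)
  structure(
    list(poor = poor, n_poor = n_poor,
         verdict = if (n_poor >= 2) "misfit" else "adequate",
         na_indices = names(vals)[is.na(vals)]),
    class = "sembed_verdict"
  )
}

#' @export
print.sembed_verdict <- function(x, ...) {
  cat(sprintf("<fit verdict: %s (%d poor: %s)>\n", x$verdict, x$n_poor,
              if (x$n_poor > 0) paste(names(x$poor)[x$poor], collapse = ", ") else "-"))
  invisible(x)
}

#' @export
print.sembed_cfa <- function(x, ...) {
  cat(sprintf(
    "<CFA fit: %d items, %d factor(s)>\n  chisq = %.3f, df = %d (N = %d)\n  CFI = %.3f, TLI = %s, SRMR = %.3f, RMSEA = %s\n  converged: %s%s\n",
    length(x$model$item_ids), length(x$model$factor_ids),
    x$chisq, x$df, x$n_pseudo, x$cfi,
    ifelse(is.na(x$tli), "NA", sprintf("%.3f", x$tli)), x$srmr,
    ifelse(is.na(x$rmsea), "NA", sprintf("%.3f", x$rmsea)),
    x$converged,
    if (length(x$heywood) > 0) paste0("; Heywood: ", paste(x$heywood, collapse = ", ")) else ""
  ))
  invisible(x)
}

#' Tidy the parameter estimates of a CFA fit
#'
#' @param x A `sembed_cfa` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `kind` (`loading`,
#'   `factor_cor`, `resid_var`, `resid_cov`), `lhs`, `rhs`, `estimate`.
#' @export
tidy.sembed_cfa <- function(x, ...) {
  idx <- param_index(x$model)
  kind_map <- c(lambda = "loading", phi = "factor_cor",
                theta_d = "resid_var", theta_od = "resid_cov")
  tibble::tibble(
    kind = unname(kind_map[idx$kind]),
    lhs = ifelse(idx$kind == "lambda", x$model$factor_ids[idx$col],
          ifelse(idx$kind == "phi", x$model$factor_ids[idx$row],
                 x$model$item_ids[idx$row])),
    rhs = ifelse(idx$kind == "lambda", x$model$item_ids[idx$row],
          ifelse(idx$kind == "phi", x$model$factor_ids[idx$col],
                 x$model$item_ids[ifelse(idx$kind == "theta_d", idx$row, idx$col)])),
    estimate = x$par
  )
}

#' One-row summary of a CFA fit
#'
#' @param x A `sembed_cfa` object.
#' @param ... Unused.
#' @return A one-row tibble: discrepancy, chi-square, df, fit indices,
#'   convergence diagnostics and Heywood count.
#' @export
glance.sembed_cfa <- function(x, ...) {
  tibble::tibble(
    f_ml = x$f_ml, chisq = x$chisq, df = x$df, n_pseudo = x$n_pseudo,
    cfi = x$cfi, tli = x$tli, srmr = x$srmr, rmsea = x$rmsea,
    converged = x$converged, n_iter = x$n_iter, grad_norm = x$grad_norm,
    n_heywood = length(x$heywood), ridge = x$ridge
  )
}
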