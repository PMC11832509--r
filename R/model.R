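#' Specify a CFA measurement model
#'
#' Defines the loading pattern, factor covariances and residual structure of
#' a confirmatory factor model. Identification follows the correlation-scale
#' convention: factor variances are fixed to 1 and all patterned loadings
#' are free, so factor covariances are correlations. Residual variances are
#' always free; selected residual covariances can be freed via
#' `residual_pairs`.
#'
#' @param items Either a `sembed_items` tibble (each scale becomes one
#'   factor) or a character vector of item ids (combined with `factors`).
#' @param factors Named list mapping factor id to the item ids loading on
#'   it. Defaults to the scale structure when `items` is a `sembed_items`
#'   tibble, or to a single factor `"f1"` over all items when `items` is a
#'   character vector.
#' @param residual_pairs Optional two-column matrix or data frame of item id
#'   pairs whose residual covariance is free.
#' @return An object of class `sembed_model`.
#' @examples
#' m <- cfa_model(c("q1", "q2", "q3", "q4"))
#' m$df  # p(p+1)/2 - q = 10 - 8 = 2
#' @export
cfa_model <- function(items, factors = NULL, residual_pairs = NULL) {
  if (inherits(items, "sembed_items")) {
    item_ids <- items$item_id
    if (is.null(factors)) {
      factors <- lapply(scales(items), function(s) scale_items(items, s))
      names(factors) <- scales(items)
    }
  } else {
    item_ids <- as.character(items)
    if (is.null(factors)) factors <- list(f1 = item_ids)
  }
  if (is.null(names(factors)) || any(names(factors) == "")) {
    abort("factors must be a named list of item-id vectors")
  }
  p <- length(item_ids)
  m <- length(factors)
  pattern <- matrix(FALSE, p, m, dimnames = list(item_ids, names(factors)))
  for (f in names(factors)) {
    unknown <- setdiff(factors[[f]], item_ids)
    if (length(unknown) > 0) {
      abort(paste0("factor ", f, " references unknown item(s): ",
                   paste(unknown, collapse = ", ")))
    }
    pattern[factors[[f]], f] <- TRUE
  }
  if (any(rowSums(pattern) == 0)) {
    orphans <- item_ids[rowSums(pattern) == 0]
    abort(paste0("item(s) load on no factor: ", paste(orphans, collapse = ", ")))
  }
  rp <- normalize_residual_pairs(residual_pairs, item_ids)
  q <- sum(pattern) + m * (m - 1) / 2 + p + nrow(rp)
  df <- p * (p + 1) / 2 - q
  if (df < 0) abort(sprintf("model not identified: %d free parameters, %d moments", q, p * (p + 1) / 2))
  out <- structure(
    list(item_ids = item_ids, factor_ids = names(factors),
         pattern = pattern, resid_pairs = rp, n_free = q, df = df),
    class = "sembed_model"
  )
  out$pidx <- param_index_build(out)
  out
}

normalize_residual_pairs <- function(residual_pairs, item_ids) {
  if (is.null(residual_pairs) || NROW(residual_pairs) == 0) {
    return(matrix(integer(0), 0, 2))
  }
  rp <- as.matrix(as.data.frame(residual_pairs)[, 1:2])
  idx <- matrix(match(as.character(rp), item_ids), ncol = 2)
  if (anyNA(idx)) abort("residual_pairs reference unknown item ids")
  idx <- t(apply(idx, 1, sort))
  if (any(idx[, 1] == idx[, 2])) abort("residual_pairs must pair distinct items")
  idx <- unique(idx)
  idx
}

#' @export
print.sembed_model <- function(x, ...) {
  cat(sprintf("<CFA model: %d items, %d factor(s), %d free residual pair(s), df = %d>\n",
              length(x$item_ids), length(x$factor_ids), nrow(x$resid_pairs), x$df))
  invisible(x)
}

# single factor over a set of items (the screening workhorse)
one_factor_model <- function(item_ids, factor_id = "f1", residual_pairs = NULL) {
  cfa_model(item_ids, factors = setNames(list(item_ids), factor_id),
            residual_pairs = residual_pairs)
}

# --- parameter packing -----------------------------------------------------
# order: free loadings (column-major), factor correlations (lower triangle,
# column-major), residual variances (item order), residual covariances
# (resid_pairs order)

param_index <- function(model) {
  if (!is.null(model$pidx)) return(model$pidx)
  param_index_build(model)
}

# built once per model and cached in the object: this sits inside the
# optimizer's objective/gradient loop
param_index_build <- function(model) {
  p <- length(model$item_ids); m <- length(model$factor_ids)
  lam <- which(model$pattern, arr.ind = TRUE)
  out <- list()
  if (nrow(lam) > 0) {
    out$lambda <- data.frame(kind = "lambda", row = lam[, 1], col = lam[, 2])
  }
  if (m >= 2) {
    lt <- which(lower.tri(matrix(0, m, m)), arr.ind = TRUE)
    out$phi <- data.frame(kind = "phi", row = lt[, 1], col = lt[, 2])
  }
  out$theta_d <- data.frame(kind = "theta_d", row = seq_len(p), col = seq_len(p))
  if (nrow(model$resid_pairs) > 0) {
    out$theta_od <- data.frame(kind = "theta_od",
                               row = model$resid_pairs[, 1],
                               col = model$resid_pairs[, 2])
  }
  do.call(rbind, out)
}

par_to_matrices <- function(model, par) {
  p <- length(model$item_ids); m <- length(model$factor_ids)
  idx <- param_index(model)
  Lambda <- matrix(0, p, m, dimnames = list(model$item_ids, model$factor_ids))
  Phi <- diag(m)
  dimnames(Phi) <- list(model$factor_ids, model$factor_ids)
  Theta <- matrix(0, p, p, dimnames = list(model$item_ids, model$item_ids))
  for (k in seq_len(nrow(idx))) {
    v <- par[k]
    switch(idx$kind[k],
      lambda = { Lambda[idx$row[k], idx$col[k]] <- v },
      phi = { Phi[idx$row[k], idx$col[k]] <- v; Phi[idx$col[k], idx$row[k]] <- v },
      theta_d = { Theta[idx$row[k], idx$row[k]] <- v },
      theta_od = { Theta[idx$row[k], idx$col[k]] <- v; Theta[idx$col[k], idx$row[k]] <- v }
    )
  }
  list(Lambda = Lambda, Phi = Phi, Theta = Theta)
}

#' Model-implied correlation/covariance matrix
#'
#' Computes the factor-model structure Sigma = Lambda Phi Lambda' + Theta.
#'
#' @param lambda Loading matrix (items x factors); a vector is treated as a
#'   single-factor column.
#' @param phi Factor covariance matrix with unit diagonal; defaults to the
#'   identity.
#' @param theta Residual covariance matrix; a vector is treated as its
#'   diagonal; defaults to `diag(1 - diag(lambda phi lambda'))`, which puts
#'   the result on the correlation scale.
#' @return Symmetric p x p numeric matrix.
#' @examples
#' implied_matrix(c(0.8, 0.7, 0.6))  # off-diagonals 0.56, 0.48, 0.42
#' @export
implied_matrix <- function(lambda, phi = NULL, theta = NULL) {
  Lambda <- if (is.matrix(lambda)) lambda else matrix(lambda, ncol = 1)
  m <- ncol(Lambda)
  Phi <- if (is.null(phi)) diag(m) else as.matrix(phi)
  common <- Lambda %*% Phi %*% t(Lambda)
  if (is.null(theta)) {
    theta <- 1 - diag(common)
    if (any(theta < 0)) abort("default theta negative: loadings imply variance > 1")
  }
  Theta <- if (is.matrix(theta)) theta else diag(theta, nrow(Lambda))
  S <- common + Theta
  if (!is.null(rownames(Lambda))) {
    dimnames(S) <- list(rownames(Lambda), rownames(Lambda))
  }
  (S + t(S)) / 2
}

implied_sigma <- function(model, par) {
  mats <- par_to_matrices(model, par)
  implied_matrix(mats$Lambda, mats$Phi, mats$Theta)
}

# derivative of Sigma with respect to one parameter (dense p x p)
param_deriv <- function(model, mats, kind, row, col) {
  p <- length(model$item_ids)
  D <- matrix(0, p, p)
  if (kind == "lambda") {
    u <- as.numeric(mats$Lambda %*% mats$Phi[, col])
    D[row, ] <- u
    D[, row] <- D[, row] + u
  } else if (kind == "phi") {
    lf <- mats$Lambda[, row]; lg <- mats$Lambda[, col]
    D <- tcrossprod(lf, lg) + tcrossprod(lg, lf)
  } else if (kind == "theta_d") {
    D[row, row] <- 1
  } else if (kind == "theta_od") {
    D[row, col] <- 1; D[col, row] <- 1
  }
  D
}
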