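#' Screen every scale for unidimensionality
#'
#' Fits one single-factor CFA per scale on that scale's submatrix of the
#' similarity (or correlation) matrix and classifies each fit with the
#' two-or-more-poor-indices rule. Modification indices are attached for
#' misfitting scales so the offending item pairs can be inspected before
#' any data collection.
#'
#' @param S Symmetric unit-diagonal matrix with item-id dimnames.
#' @param items A `sembed_items` tibble. Scales with fewer than 3 items are
#'   skipped with a warning (a 2-item factor model is not identified).
#' @param n_pseudo Nominal sample size (default 10000).
#' @param cutoffs Verdict cutoffs, see [classify_fit()].
#' @param mi_method Method for the attached modification indices.
#' @param mi_top How many top modification indices to keep per misfitting
#'   scale.
#' @return A tibble of class `sembed_screen`, one row per screened scale,
#'   with index columns, `verdict`, and list-columns `fit` (`sembed_cfa`)
#'   and `mi` (a `sembed_mi` head, `NULL` for adequate scales).
#' @export
unidimensional_screen <- function(S, items, n_pseudo = 10000,
                                  cutoffs = c(incremental = 0.90, absolute = 0.08),
                                  mi_method = c("score", "refit"),
                                  mi_top = 5) {
  stopifnot(inherits(items, "sembed_items"))
  mi_method <- match.arg(mi_method)
  check_square(S, "input matrix")
  check_axis_ids(rownames(S), colnames(S), items)
  S <- sub_matrix(S, items$item_id)
  sc <- scales(items)
  sizes <- vapply(sc, function(s) sum(items$scale_id == s), integer(1))
  skipped <- sc[sizes < 3]
  if (length(skipped) > 0) {
    warn(paste0("skipping scale(s) with < 3 items: ", paste(skipped, collapse = ", ")))
  }
  rows <- purrr::map(sc[sizes >= 3], function(s) {
    ids <- scale_items(items, s)
    screen_one(sub_matrix(S, ids), one_factor_model(ids, factor_id = s),
               n_pseudo, cutoffs, mi_method, mi_top,
               tibble::tibble(scale_id = s, n_items = length(ids)))
  })
  as_screen(dplyr::bind_rows(rows), kind = "unidimensional")
}

#' Wrong-model battery over all scale pairs
#'
#' For every unordered pair of scales, deliberately fits the wrong model —
#' a single latent variable loading on the union of both scales' items,
#' where a two-factor model would be appropriate — and records whether the
#' fit indices flag the misspecification. With k scales this yields
#' k(k-1)/2 models (276 for a 24-scale instrument).
#'
#' @inheritParams unidimensional_screen
#' @param attach_mi Attach modification indices for misfitting pairs
#'   (default `FALSE`: the battery is a detection experiment, not a
#'   diagnosis step).
#' @return A tibble of class `sembed_screen`, one row per scale pair
#'   (`scale_a`, `scale_b`).
#' @export
wrong_model_battery <- function(S, items, n_pseudo = 10000,
                                cutoffs = c(incremental = 0.90, absolute = 0.08),
                                mi_method = c("score", "refit"),
                                mi_top = 5, attach_mi = FALSE) {
  stopifnot(inherits(items, "sembed_items"))
  mi_method <- match.arg(mi_method)
  check_square(S, "input matrix")
  check_axis_ids(rownames(S), colnames(S), items)
  S <- sub_matrix(S, items$item_id)
  sc <- scales(items)
  if (length(sc) < 2) abort("battery needs at least 2 scales")
  pairs <- combn(sc, 2)
  rows <- purrr::map(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    ids <- c(scale_items(items, a), scale_items(items, b))
    screen_one(sub_matrix(S, ids),
               one_factor_model(ids, factor_id = paste0(a, "+", b)),
               n_pseudo, cutoffs, if (attach_mi) mi_method else NA, mi_top,
               tibble::tibble(scale_a = a, scale_b = b, n_items = length(ids)))
  })
  as_screen(dplyr::bind_rows(rows), kind = "battery")
}

screen_one <- function(Ssub, model, n_pseudo, cutoffs, mi_method, mi_top, id_cols) {
  fit <- withCallingHandlers(
    fit_cfa(Ssub, model, n_pseudo = n_pseudo),
    warning = function(w) invokeRestart("muffleWarning")
  )
  verdict <- classify_fit(fit, cutoffs)
  mi <- NULL
  if (!is.na(mi_method) && (verdict$verdict == "misfit") && fit$converged) {
    mi <- head(suppressWarnings(modification_indices(fit, method = mi_method)), mi_top)
  }
  dplyr::bind_cols(
    id_cols,
    tibble::tibble(
      converged = fit$converged, chisq = fit$chisq, df = fit$df,
      cfi = fit$cfi, tli = fit$tli, srmr = fit$srmr, rmsea = fit$rmsea,
      n_poor = verdict$n_poor, verdict = verdict$verdict,
      n_heywood = length(fit$heywood),
      fit = list(fit), mi = list(mi)
    )
  )
}

as_screen <- function(df, kind) {
  structure(df, screen_kind = kind,
            class = c("sembed_screen", class(tibble::tibble())))
}

#' Summarize a screening battery
#'
#' @param results A `sembed_screen` tibble.
#' @param srmr_cutoff Cutoff used for the SRMR detection-failure fraction.
#' @return A list: `n_models`, `index_ranges` (tibble of per-index min/max),
#'   `misfit_fraction` (non-convergent fits count as misfit and are also
#'   reported separately), `srmr_below_cutoff_fraction`, `n_nonconverged`.
#' @export
battery_summary <- function(results, srmr_cutoff = 0.08) {
  if (!inherits(results, "sembed_screen") || nrow(results) == 0) {
    abort("battery_summary needs a non-empty sembed_screen")
  }
  idx <- c("cfi", "tli", "srmr", "rmsea")
  ranges <- purrr::map(idx, function(i) {
    v <- results[[i]]
    tibble::tibble(index = i, min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE))
  })
  list(
    n_models = nrow(results),
    index_ranges = dplyr::bind_rows(ranges),
    misfit_fraction = mean(results$verdict == "misfit" | !results$converged),
    srmr_below_cutoff_fraction = mean(results$srmr < srmr_cutoff, na.rm = TRUE),
    n_nonconverged = sum(!results$converged)
  )
}

#' Render a screening report
#'
#' Produces a deterministic plain-text report: one block per screened model
#' with its indices and verdict, and — for misfitting models — the top
#' modification indices with both item texts spelled out verbatim, so the
#' researcher can judge whether a suggested residual correlation reflects
#' redundant wording.
#'
#' @param results A `sembed_screen` tibble.
#' @param items The `sembed_items` tibble the screen was run on (source of
#'   the item texts).
#' @return Character vector of report lines (class `sembed_report`),
#'   printable and writable via [write_report()].
#' @export
screen_report <- function(results, items) {
  stopifnot(inherits(results, "sembed_screen"), inherits(items, "sembed_items"))
  texts <- setNames(items$text, items$item_id)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  lines <- character(0)
  for (i in seq_len(nrow(results))) {
    r <- results[i, ]
    label <- if ("scale_id" %in% names(r)) r$scale_id else paste(r$scale_a, "+", r$scale_b)
    lines <- c(lines,
      sprintf("== %s ==", label),
      sprintf("  chisq = %.3f (df = %d)  CFI = %s  TLI = %s  SRMR = %s  RMSEA = %s",
              r$chisq, r$df, fmt(r$cfi), fmt(r$tli), fmt(r$srmr), fmt(r$rmsea)),
      sprintf("  verdict: %s (%d poor)%s", r$verdict, r$n_poor,
              if (!r$converged) " [NON-CONVERGED]" else "")
    )
    mi <- r$mi[[1]]
    if (!is.null(mi) && nrow(mi) > 0) {
      lines <- c(lines, "  top modification indices:")
      for (k in seq_len(nrow(mi))) {
        lines <- c(lines,
          sprintf("    %d. %s %s ~~ %s  (MI = %.2f)", mi$rank[k], mi$param[k],
                  mi$lhs[k], mi$rhs[k], mi$mi[k]))
        if (mi$param[k] == "residual_cov") {
          lines <- c(lines,
            sprintf("       %s: \"%s\"", mi$lhs[k], texts[[mi$lhs[k]]]),
            sprintf("       %s: \"%s\"", mi$rhs[k], texts[[mi$rhs[k]]]))
        } else {
          lines <- c(lines,
            sprintf("       %s: \"%s\"", mi$rhs[k], texts[[mi$rhs[k]]]))
        }
      }
    }
    lines <- c(lines, "")
  }
  structure(lines, class = "sembed_report")
}

#' @export
print.sembed_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
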