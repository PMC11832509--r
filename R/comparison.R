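#' Agreement between two item matrices
#'
#' Correlates the lower triangles (diagonal excluded) of two square
#' matrices over the same items — the summary used to ask how well
#' embedding cosine similarities predict empirical item correlations.
#'
#' @param A,B Symmetric matrices with identical item-id dimnames (order may
#'   differ; B is reindexed to A's order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r` and `n_pairs` = p(p-1)/2.
#' @export
lower_triangle_correlation <- function(A, B, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  check_square(A, "A"); check_square(B, "B")
  if (nrow(A) != nrow(B)) abort("matrices have different dimensions")
  if (nrow(A) < 3) abort("need at least 3 items for a lower-triangle correlation")
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B))) abort("matrix axis ids differ")
    B <- B[rownames(A), rownames(A)]
  }
  a <- lower_tri_values(A); b <- lower_tri_values(B)
  tibble::tibble(r = cor(a, b, method = method), n_pairs = length(a))
}

#' Compare two sets of fit indices model-by-model
#'
#' Given the same models fitted under two conditions (e.g. on a cosine
#' similarity matrix and on an empirical correlation matrix), computes per
#' index the medians and SDs under each condition, the Pearson correlation
#' across models, and the median, SD and maximum of the absolute
#' differences. Differences are signed a - b (first condition minus
#' second).
#'
#' @param fits_a,fits_b Lists of `sembed_cfa` objects, or data frames with
#'   columns `cfi`, `tli`, `srmr`, `rmsea`, in identical model order.
#' @return A tibble with one row per index: `index`, `median_a`, `sd_a`,
#'   `median_b`, `sd_b`, `correlation`, `median_diff`, `median_abs_diff`,
#'   `sd_abs_diff`, `max_abs_diff`.
#' @export
compare_fit_sets <- function(fits_a, fits_b) {
  a <- fits_to_index_df(fits_a)
  b <- fits_to_index_df(fits_b)
  if (nrow(a) != nrow(b)) abort("fit sets have different lengths")
  purrr::map_dfr(c("cfi", "tli", "srmr", "rmsea"), function(i) {
    va <- a[[i]]; vb <- b[[i]]
    d <- va - vb
    ok <- !is.na(d)
    tibble::tibble(
      index = i,
      median_a = median(va, na.rm = TRUE), sd_a = sd(va, na.rm = TRUE),
      median_b = median(vb, na.rm = TRUE), sd_b = sd(vb, na.rm = TRUE),
      correlation = if (sum(ok) >= 3 && sd(va[ok]) > 0 && sd(vb[ok]) > 0)
        cor(va[ok], vb[ok]) else NA_real_,
      median_diff = median(d, na.rm = TRUE),
      median_abs_diff = median(abs(d), na.rm = TRUE),
      sd_abs_diff = sd(abs(d), na.rm = TRUE),
      max_abs_diff = max(abs(d), na.rm = TRUE)
    )
  })
}

fits_to_index_df <- function(fits) {
  if (is.data.frame(fits)) {
    need <- c("cfi", "tli", "srmr", "rmsea")
    if (!all(need %in% names(fits))) abort("fit data frame lacks index columns")
    return(tibble::as_tibble(fits[need]))
  }
  purrr::map_dfr(fits, function(f) {
    stopifnot(inherits(f, "sembed_cfa"))
    tibble::tibble(cfi = f$cfi, tli = f$tli, srmr = f$srmr, rmsea = f$rmsea)
  })
}
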