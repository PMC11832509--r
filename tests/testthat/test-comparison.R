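test_that("lower-triangle agreement hits the closed-form anchors", {
  set.seed(17)
  A <- cov2cor(crossprod(matrix(rnorm(36), 6)))
  dimnames(A) <- list(paste0("q", 1:6), paste0("q", 1:6))
  expect_equal(lower_triangle_correlation(A, A)$r, 1)
  B <- -A; diag(B) <- 1
  expect_equal(lower_triangle_correlation(A, B)$r, -1)
  expect_equal(lower_triangle_correlation(A, B)$n_pairs, 15)
})

test_that("agreement is symmetric and invariant to joint reindexing", {
  set.seed(18)
  A <- cov2cor(crossprod(matrix(rnorm(49), 7)))
  B <- cov2cor(crossprod(matrix(rnorm(49), 7)))
  ids <- paste0("q", 1:7)
  dimnames(A) <- dimnames(B) <- list(ids, ids)
  expect_equal(lower_triangle_correlation(A, B)$r,
               lower_triangle_correlation(B, A)$r, tolerance = 1e-12)
  perm <- sample(7)
  expect_equal(lower_triangle_correlation(A[perm, perm], B[perm, perm])$r,
               lower_triangle_correlation(A, B)$r, tolerance = 1e-12)
  # B permuted alone is realigned through its axis ids
  expect_equal(lower_triangle_correlation(A, B[perm, perm])$r,
               lower_triangle_correlation(A, B)$r, tolerance = 1e-12)
})

test_that("agreement rejects mismatched or too-small input", {
  A <- named_matrix(diag(4), paste0("q", 1:4))
  B <- named_matrix(diag(4), paste0("x", 1:4))
  expect_error(lower_triangle_correlation(A, B), "ids")
  expect_error(lower_triangle_correlation(A, named_matrix(diag(5), paste0("q", 1:5))),
               "dimensions")
  small <- named_matrix(diag(2), paste0("q", 1:2))
  expect_error(lower_triangle_correlation(small, small), "3 items")
})

test_that("fit-set comparison reproduces hand-computed statistics", {
  mk <- function(cfi) list(cfi = cfi, tli = cfi - 0.1, srmr = 0.05, rmsea = 0.05)
  a <- tibble::tibble(cfi = c(0.9, 0.8, 0.7), tli = c(0.8, 0.7, 0.6),
                      srmr = c(0.05, 0.06, 0.07), rmsea = c(0.05, 0.08, 0.1))
  b <- tibble::tibble(cfi = c(0.8, 0.8, 0.6), tli = c(0.7, 0.7, 0.5),
                      srmr = c(0.05, 0.06, 0.07), rmsea = c(0.05, 0.08, 0.1))
  cmp <- compare_fit_sets(a, b)
  cfi_row <- cmp[cmp$index == "cfi", ]
  expect_equal(cfi_row$median_abs_diff, 0.1)
  expect_equal(cfi_row$max_abs_diff, 0.1)
  expect_equal(cfi_row$median_diff, 0.1) # signed a - b
  expect_equal(cfi_row$median_a, 0.8)

  same <- compare_fit_sets(a, a)
  expect_true(all(same$max_abs_diff == 0))
  expect_true(all(same$correlation[!is.na(same$correlation)] == 1))
  expect_error(compare_fit_sets(a, b[1:2, ]), "length")
})

test_that("delta statistics keep their ordering invariant", {
  set.seed(19)
  for (rep in 1:10) {
    d <- rnorm(20, 0.02, 0.05)
    expect_lte(abs(median(d)), median(abs(d)) + 1e-12)
    expect_lte(median(abs(d)), max(abs(d)) + 1e-12)
  }
})

test_that("population and large-sample fits of the same models correlate", {
  # graded residual injections so the per-scale indices actually vary
  inj <- tibble::tibble(
    item_i = c("q001", "q005", "q009", "q013"),
    item_j = c("q002", "q006", "q010", "q014"),
    value = c(0.25, 0.18, 0.12, 0.06)
  )
  sim <- make_instrument(6, 4, seed = 23, loading_range = c(0.55, 0.75),
                         injected_pairs = inj)
  resp <- sample_responses(sim, n = 5000, likert = NA, seed = 5)
  fits_pop <- suppressWarnings(unidimensional_screen(sim$population_R, sim$items))
  fits_smp <- suppressWarnings(unidimensional_screen(resp$sample_R, sim$items))
  cmp <- compare_fit_sets(
    fits_smp[c("cfi", "tli", "srmr", "rmsea")],
    fits_pop[c("cfi", "tli", "srmr", "rmsea")]
  )
  srmr_row <- cmp[cmp$index == "srmr", ]
  expect_gt(srmr_row$correlation, 0)
})
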