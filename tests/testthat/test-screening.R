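test_that("unidimensional screen fits one model per scale and finds injected misfit", {
  sim <- make_instrument(4, 4, seed = 3,
                         injected_pairs = tibble::tibble(item_i = "q001",
                                                         item_j = "q002",
                                                         value = 0.25))
  res <- unidimensional_screen(sim$population_R, sim$items)
  expect_s3_class(res, "sembed_screen")
  expect_equal(nrow(res), 4)
  expect_equal(res$scale_id, scales(sim$items))
  clean <- res[res$scale_id != "scale_01", ]
  expect_true(all(clean$verdict == "adequate"))
  expect_true(all(clean$chisq < 1e-6))
  # the corrupted scale carries its injected pair as the top index
  bad <- res[res$scale_id == "scale_01", ]
  if (bad$verdict == "misfit") {
    expect_setequal(c(bad$mi[[1]]$lhs[1], bad$mi[[1]]$rhs[1]), c("q001", "q002"))
  }
})

test_that("a clean population screens adequate everywhere", {
  sim <- make_instrument(6, 4, seed = 8)
  res <- unidimensional_screen(sim$population_R, sim$items)
  expect_true(all(res$verdict == "adequate"))
  expect_true(all(res$converged))
})

test_that("scales with fewer than three items are skipped with a warning", {
  items <- item_set(tibble::tibble(
    item_id = paste0("q", 1:6),
    scale_id = c(rep("a", 4), "tiny", "tiny"),
    text = paste("t", 1:6)
  ))
  S <- named_matrix(diag(6) * 0 + 0.3, items$item_id); diag(S) <- 1
  expect_warning(res <- unidimensional_screen(S, items), "tiny")
  expect_equal(res$scale_id, "a")
})

test_that("the battery enumerates every unordered scale pair", {
  sim4 <- make_instrument(4, 3, seed = 2)
  b4 <- suppressWarnings(wrong_model_battery(sim4$population_R, sim4$items))
  expect_equal(nrow(b4), 6)
  expect_equal(nrow(unique(b4[c("scale_a", "scale_b")])), 6)

  sim2 <- make_instrument(2, 4, seed = 2)
  b2 <- suppressWarnings(wrong_model_battery(sim2$population_R, sim2$items))
  expect_equal(nrow(b2), 1)
})

test_that("battery fit degrades monotonically as factors separate", {
  l <- rep(0.75, 4)
  cfis <- vapply(c(1, 0.8, 0.5, 0.2, 0), function(phi) {
    S <- pop_two_factor(l, l, phi)
    fit <- quiet_fit(S, cfa_model(rownames(S)))
    fit$cfi
  }, numeric(1))
  expect_true(all(diff(cfis) <= 1e-8)) # CFI falls as phi drops
  expect_gt(cfis[1], 0.999)            # shared factor: perfect fit
  S0 <- pop_two_factor(l, l, 0)
  v <- classify_fit(quiet_fit(S0, cfa_model(rownames(S0))))
  expect_equal(v$verdict, "misfit")
})

test_that("screen verdicts are invariant to item order within scales", {
  sim <- make_instrument(3, 4, seed = 9,
                         injected_pairs = tibble::tibble(item_i = "q005",
                                                         item_j = "q006",
                                                         value = 0.3))
  res1 <- unidimensional_screen(sim$population_R, sim$items)
  perm <- c(2, 1, 4, 3, 7, 8, 5, 6, 12, 11, 10, 9)
  items2 <- item_set(tibble::as_tibble(sim$items[perm, c("item_id", "scale_id", "text")]))
  res2 <- unidimensional_screen(sim$population_R[items2$item_id, items2$item_id], items2)
  expect_equal(setNames(res2$verdict, res2$scale_id),
               setNames(res1$verdict, res1$scale_id))
  expect_equal(res2$chisq, res1$chisq, tolerance = 1e-6)
})

test_that("battery summaries aggregate ranges, fractions and convergence", {
  sim <- make_instrument(3, 4, seed = 12, factor_corr_range = c(0.1, 0.3))
  b <- suppressWarnings(wrong_model_battery(sim$population_R, sim$items))
  s <- battery_summary(b)
  expect_equal(s$n_models, 3)
  expect_equal(s$misfit_fraction, mean(b$verdict == "misfit"))
  expect_equal(s$index_ranges$min[s$index_ranges$index == "cfi"], min(b$cfi))

  single <- b[1, ]
  s1 <- battery_summary(single)
  expect_equal(s1$index_ranges$min, s1$index_ranges$max)
  expect_error(battery_summary(b[0, ]), "non-empty")
})

test_that("an orthogonal-factor population makes every battery model misfit", {
  sim <- make_instrument(3, 4, seed = 21, loading_range = c(0.7, 0.8),
                         factor_corr_range = c(0, 0))
  b <- suppressWarnings(wrong_model_battery(sim$population_R, sim$items))
  expect_equal(battery_summary(b)$misfit_fraction, 1)
})

test_that("reports pair modification indices with verbatim item texts", {
  sim <- make_instrument(2, 4, seed = 4,
                         injected_pairs = tibble::tibble(item_i = "q001",
                                                         item_j = "q003",
                                                         value = 0.3))
  res <- unidimensional_screen(sim$population_R, sim$items)
  rep1 <- screen_report(res, sim$items)
  rep2 <- screen_report(unidimensional_screen(sim$population_R, sim$items), sim$items)
  expect_identical(rep1, rep2) # byte-identical across runs

  txt <- paste(rep1, collapse = "\n")
  bad <- res[res$verdict == "misfit", ]
  if (nrow(bad) > 0) {
    expect_match(txt, "top modification indices", fixed = TRUE)
    top <- bad$mi[[1]]
    expect_match(txt, sim$items$text[sim$items$item_id == top$lhs[1]], fixed = TRUE)
    expect_match(txt, sim$items$text[sim$items$item_id == top$rhs[1]], fixed = TRUE)
  }
  ok <- res[res$verdict == "adequate", ]
  for (i in seq_len(nrow(ok))) {
    block_start <- which(rep1 == sprintf("== %s ==", ok$scale_id[i]))
    expect_false(grepl("modification", rep1[block_start + 2]))
  }
})
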