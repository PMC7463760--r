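test_that("curveball randomization preserves both marginals exactly", {
  # two-cell toy: only two fixed-marginal states exist
  g <- grid_from_sets(list(c("A"), c("B")), c("A", "B"))
  r <- randomize_occurrences(g, seed = 4)
  m <- occ_matrix(r)
  expect_equal(rowSums(m), rowSums(occ_matrix(g)))
  expect_equal(colSums(m), colSums(occ_matrix(g)))

  # all-ones matrix: unique state, returned unchanged with a warning
  gall <- grid_from_sets(list(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_warning(r2 <- randomize_occurrences(gall, seed = 1), "degenerate")
  expect_identical(occ_matrix(r2), occ_matrix(gall))

  # moderately sized random matrix, many trades
  inst <- random_instance(31)
  r3 <- randomize_occurrences(inst$grid, seed = 9, n_swaps = 1e4)
  expect_identical(rowSums(occ_matrix(r3)), rowSums(occ_matrix(inst$grid)))
  expect_identical(colSums(occ_matrix(r3)), colSums(occ_matrix(inst$grid)))
  expect_identical(occ_matrix(randomize_occurrences(inst$grid, seed = 9)),
                   occ_matrix(randomize_occurrences(inst$grid, seed = 9)))
})

test_that("percentile and SES behave at the rank extremes and under degeneracy", {
  # degenerate null (all-ones): every draw equals the observed grid
  gall <- grid_from_sets(list(c("A", "B", "C", "D"), c("A", "B", "C", "D")),
                         c("A", "B", "C", "D"))
  sig <- null_significance(gall, balanced_tree(), n_rand = 49, seed = 2)
  expect_equal(sig$pct_pe, rep(0.5, 2))
  expect_equal(sig$ses_pd, rep(0, 2))
  expect_true(all(sig$ses_pd_zero_sd))

  # percentiles are proper two-tailed probabilities on a live landscape
  land <- simulate_landscape(landscape_config(seed = 6))
  sig2 <- null_significance(land$current, land$tree, n_rand = 99, seed = 3)
  ok <- !is.na(sig2$pct_pe)
  expect_true(all(sig2$pct_pe[ok] >= 0 & sig2$pct_pe[ok] <= 1))
  expect_identical(sig2$n_rand[1], 99L)
})

test_that("CANAPE rules classify the quoted configurations", {
  sig <- tibble::tibble(
    cell = sprintf("r0_c%d", 0:5),
    pct_pe = c(0.99, 0.98, 0.995, 0.5, 0.99, NA),
    pct_pe_comp = c(0.99, 0.99, 0.995, 0.5, 0.5, NA),
    pct_rpe = c(0.99, 0.01, 0.50, 0.5, 0.5, NA)
  )
  cm <- canape_classify(sig)
  expect_equal(as.character(cm$category),
               c("paleo", "neo", "super", "not_significant", "not_significant",
                 "no_data"))
  # mixed: both high at 0.975 but not at the stricter super threshold
  sig2 <- tibble::tibble(cell = "r0_c0", pct_pe = 0.98, pct_pe_comp = 0.985,
                         pct_rpe = 0.5)
  expect_equal(as.character(canape_classify(sig2)$category), "mixed")
  expect_error(canape_classify(sig[, c("cell", "pct_pe")]), "missing percentile")
})

test_that("categories are exclusive and exhaustive over non-empty cells", {
  land <- simulate_landscape(recovery_config(2))
  sig <- null_significance(land$current, land$tree, n_rand = 99, seed = 12)
  cm <- canape_classify(sig)
  expect_equal(nrow(cm), nrow(land$current))
  expect_false(anyNA(cm$category))
  expect_identical(cm$category == "no_data", sig$richness == 0)
})

test_that("elevation test matches hand-ranked Kruskal-Wallis and handles ties", {
  canape <- tibble::tibble(
    cell = sprintf("r0_c%d", 0:8),
    category = factor(rep(c("neo", "paleo", "mixed"), each = 3),
                      levels = c("neo", "paleo", "mixed", "super",
                                 "not_significant", "no_data")))
  cov <- tibble::tibble(cell = canape$cell, elevation = 1:9)
  out <- center_elevation_test(canape, cov)
  expect_equal(out$statistic, 7.2, tolerance = 1e-12)   # hand rank computation
  expect_equal(out$df, 2)

  cov2 <- cov; cov2$elevation <- rep(5, 9)   # all ties
  out2 <- center_elevation_test(canape, cov2)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p_value, 1)

  one <- canape; one$category[] <- "neo"
  expect_error(center_elevation_test(one, cov), "degenerate")
})

test_that("confident categories at 99 randomizations persist at 999", {
  land <- simulate_landscape(recovery_config(3))
  s99 <- null_significance(land$current, land$tree, n_rand = 99, seed = 21)
  s999 <- null_significance(land$current, land$tree, n_rand = 999, seed = 22)
  c99 <- canape_classify(s99); c999 <- canape_classify(s999)
  confident <- !is.na(s99$pct_rpe) &
    (s99$pct_pe >= 0.995 | s99$pct_pe <= 0.005) &
    (s99$pct_rpe >= 0.995 | s99$pct_rpe <= 0.005)
  expect_gt(sum(confident), 0)
  expect_identical(c99$category[confident], c999$category[confident])
})

test_that("center counting distinguishes cells from connected components", {
  canape <- tibble::tibble(
    cell = c("r0_c0", "r0_c1", "r5_c5", "r1_c1", "r3_c3"),
    category = factor(c("paleo", "paleo", "paleo", "neo", "no_data"),
                      levels = c("neo", "paleo", "mixed", "super",
                                 "not_significant", "no_data")))
  geom <- grid_geometry(6, 6)
  cc <- canape_counts(canape, geom)
  paleo <- cc[cc$category == "paleo", ]
  expect_equal(paleo$n_cells, 3)
  expect_equal(paleo$n_components, 2)   # (0,0)-(0,1) joined, (5,5) apart
  expect_equal(cc[cc$category == "neo", ]$n_components, 1)
  expect_equal(cc[cc$category == "mixed", ]$n_cells, 0)
})
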