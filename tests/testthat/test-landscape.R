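test_that("phylogeny generator: shape, determinism, planted-clade scaling", {
  tr <- simulate_phylogeny(4, seed = 3)
  expect_equal(ape::Ntip(tr), 4)
  expect_equal(nrow(tr$edge), 6)           # 2n - 2 edges
  expect_true(all(tr$edge.length > 0))

  expect_identical(write_newick(simulate_phylogeny(17, seed = 9)),
                   write_newick(simulate_phylogeny(17, seed = 9)))
  expect_error(simulate_phylogeny(3), "n_species")

  sig <- planted_signal(c(0, 2), c(0, 2), "paleo", 5, branch_scale = 10)
  sig1 <- planted_signal(c(0, 2), c(0, 2), "paleo", 5, branch_scale = 1)
  t10 <- simulate_phylogeny(20, seed = 4, planted = list(sig))
  t1 <- simulate_phylogeny(20, seed = 4, planted = list(sig1))
  clade_sum <- function(tr) {
    tips <- tr$tip.label[grepl("^paleo", tr$tip.label)]
    expect_true(ape::is.monophyletic(tr, tips))
    sum(ape::extract.clade(tr, ape::getMRCA(tr, tips))$edge.length)
  }
  expect_equal(clade_sum(t10), 10 * clade_sum(t1), tolerance = 1e-12)
})

test_that("covariate generator: cardinality, degenerate relief, low collinearity", {
  cfg <- landscape_config(n_rows = 10, n_cols = 10, n_species = 20, seed = 2)
  cov <- simulate_covariates(cfg)
  expect_equal(nrow(cov), 100)
  expect_true(all(cov$stability >= 0 & cov$stability <= 1))

  flat <- simulate_covariates(landscape_config(n_rows = 6, n_cols = 6,
                                               elevation_relief = 0, seed = 2))
  expect_equal(sd(flat$elevation), 0)

  # default config passes the multicollinearity screen by construction
  for (sd in 1:3) {
    cov <- simulate_covariates(landscape_config(seed = sd))
    v <- vif_screen(cov, c("elevation", "ph", "diurnal_range", "stability"))
    expect_true(all(v$vif < 2), label = sprintf("VIF < 2 at seed %d", sd))
  }
})

test_that("range generator: forced marginals, containment, trait coupling", {
  cfg1 <- landscape_config(n_rows = 6, n_cols = 6, n_species = 10, seed = 5,
                           range_size = list(fixed = 1))
  land1 <- simulate_landscape(cfg1)
  expect_true(all(colSums(occ_matrix(land1$current)) == 1))

  cfg <- recovery_config(11)
  land <- simulate_landscape(cfg)
  m <- occ_matrix(land$current)
  expect_true(all(colSums(m) >= 1))               # every species somewhere
  expect_true(all(m %in% c(0L, 1L)))
  for (slice in list(land$current, land$future)) {
    d <- slice
    for (i in seq_along(cfg$planted_signals)) {
      sig <- cfg$planted_signals[[i]]
      sp <- grep(sprintf("^%s%02d", sig$signal_type, i), occ_species(d), value = TRUE)
      outside <- !in_region(d, sig$rows, sig$cols)
      expect_true(all(occ_matrix(d)[outside, sp] == 0),
                  label = sprintf("%s taxa confined (signal %d)", sig$signal_type, i))
    }
  }
  expect_gt(cor(land$traits$range_size, land$traits$niche_breadth,
                method = "spearman"), 0)

  tiny <- landscape_config(n_rows = 6, n_cols = 6, n_species = 10, seed = 5,
                           planted_signals = list(
                             planted_signal(c(0, 0), c(0, 1), "neo", 4)))
  tr <- simulate_phylogeny(tiny$n_species, tiny$seed, tiny$planted_signals)
  cov <- simulate_covariates(tiny)
  expect_error(simulate_ranges(tr, cov, tiny), "impossible placement")
})

test_that("future projection: identity, total contraction, range decline", {
  cfg0 <- landscape_config(seed = 8, future_shift = 0)
  land0 <- simulate_landscape(cfg0)
  expect_identical(land0$future, land0$current)

  cfg1 <- landscape_config(seed = 8, future_shift = 1)
  land1 <- simulate_landscape(cfg1)
  specialists <- land1$traits$species[land1$traits$niche_breadth < 0.5]
  expect_true(all(colSums(occ_matrix(land1$future)[, specialists]) == 0))
  expect_setequal(intersect(extinct_species(land1$current, land1$future),
                            specialists), specialists)

  land <- simulate_landscape(landscape_config(seed = 8))
  expect_lt(mean(colSums(occ_matrix(land$future))),
            mean(colSums(occ_matrix(land$current))))
})

test_that("mask generator covers the requested fraction", {
  cov <- simulate_covariates(landscape_config(n_rows = 10, n_cols = 10, seed = 3))
  expect_true(all(simulate_masks(cov, pa_fraction = 1)$protected))
  expect_false(any(simulate_masks(cov, pa_fraction = 0)$protected))
  frac <- mean(simulate_masks(cov, pa_fraction = 0.4, seed = 3)$protected)
  expect_lt(abs(frac - 0.4), 0.05)
  # high-elevation bias
  mk <- simulate_masks(cov, pa_fraction = 0.4, seed = 3)
  expect_gt(mean(cov$elevation[mk$protected]), mean(cov$elevation[!mk$protected]))
})

test_that("generators are deterministic per config and write/read config round-trips", {
  cfg <- recovery_config(21)
  a <- simulate_landscape(cfg); b <- simulate_landscape(cfg)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  expect_identical(a$current, b$current)
  expect_identical(a$future, b$future)
  expect_identical(a$covariates, b$covariates)

  p <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, p)
  cfg2 <- read_config(p)
  expect_identical(write_newick(simulate_landscape(cfg2)$tree), write_newick(a$tree))
})
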