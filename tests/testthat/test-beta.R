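test_that("pairwise decomposition handles identical, disjoint and nested pairs", {
  tr <- balanced_tree()
  same <- phylo_beta_pair(c("A", "B"), c("A", "B"), tr)
  expect_equal(same$beta_sim, 0)
  expect_equal(same$beta_sor, 0)

  disj <- phylo_beta_pair(c("A", "B"), c("C", "D"), tr)   # share no edges
  expect_equal(disj$a, 0)
  expect_equal(disj$beta_sim, 1)

  nest <- phylo_beta_pair("A", c("A", "B"), tr)
  expect_equal(nest$beta_sim, 0)
  expect_gt(nest$beta_sne, 0)
  expect_equal(nest$beta_sne, nest$beta_sor, tolerance = 1e-15)

  expect_error(phylo_beta_pair(character(0), character(0), tr), "undefined pair")
})

test_that("Sorensen identity and symmetry hold across random pairs", {
  tree <- withr::with_seed(40, ape::rphylo(24, 1, 0))
  tips <- tree$tip.label
  withr::with_seed(41, {
    for (i in 1:200) {
      sa <- sample(tips, sample(24, 1))
      sb <- sample(tips, sample(24, 1))
      p <- phylo_beta_pair(sa, sb, tree)
      q <- phylo_beta_pair(sb, sa, tree)
      expect_equal(p$beta_sor, p$beta_sim + p$beta_sne, tolerance = 1e-12)
      expect_true(all(c(p$a, p$b, p$c, p$beta_sim, p$beta_sne) >= -1e-15))
      expect_equal(p$beta_sim, q$beta_sim, tolerance = 1e-15)
      expect_equal(p$beta_sor, q$beta_sor, tolerance = 1e-15)
    }
  })
})

test_that("turnover map: degenerate landscapes and brute-force window oracle", {
  tr <- balanced_tree()
  # uniform composition -> 0 everywhere
  uni <- grid_from_sets(rep(list(c("A", "C")), 9), c("A", "B", "C", "D"), n_rows = 3)
  expect_equal(beta_map(uni, tr)$beta_sim, rep(0, 9))

  # alternating strip of phylogenetically disjoint assemblages: every
  # neighbor is disjoint, so turnover is 1 everywhere
  sets <- lapply(1:8, function(i) if (i %% 2) c("A", "B") else c("C", "D"))
  chk <- grid_from_sets(sets, c("A", "B", "C", "D"), n_rows = 1)
  expect_equal(beta_map(chk, tr)$beta_sim, rep(1, 8))

  for (seed in 1:20) {
    inst <- random_instance(seed)
    bm <- beta_map(inst$grid, inst$tree)
    expect_equal(bm$beta_sim, naive_beta_map(inst$grid, inst$tree),
                 tolerance = 1e-12, label = sprintf("window oracle (seed %d)", seed))
    expect_true(all(bm$beta_sim >= 0 & bm$beta_sim <= 1, na.rm = TRUE))
  }
})

test_that("delta surfaces: fixed point, arithmetic, two-route richness", {
  land <- simulate_landscape(landscape_config(seed = 13, future_shift = 0))
  d0 <- compute_deltas(land$current, land$future, land$tree, land$traits)
  expect_true(all(d0$d_sr[!is.na(d0$d_sr)] == 0))
  expect_true(all(abs(d0$d_eg) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(d0$d_bd) < 1e-12, na.rm = TRUE))

  # hand-computed niche-breadth change: {0.2, 0.4} -> {0.4}
  tr <- balanced_tree()
  cur <- grid_from_sets(list(c("A", "B"), c("C", "D")), c("A", "B", "C", "D"))
  fut <- grid_from_sets(list(c("B"), c("C", "D")), c("A", "B", "C", "D"))
  traits <- tibble::tibble(species = c("A", "B", "C", "D"),
                           niche_breadth = c(0.2, 0.4, 0.5, 0.7))
  d <- compute_deltas(cur, fut, tr, traits)
  expect_equal(d$d_eg[1], 0.4 - 0.3, tolerance = 1e-12)
  expect_equal(d$d_sr[1], -1L)

  # two routes to delta-SR: column stacking vs row sums
  land2 <- simulate_landscape(landscape_config(seed = 13))
  d2 <- compute_deltas(land2$current, land2$future, land2$tree, land2$traits)
  alt <- unname(rowSums(occ_matrix(land2$future)) - rowSums(occ_matrix(land2$current)))
  ok <- !is.na(d2$d_sr)
  expect_equal(as.numeric(d2$d_sr[ok]), alt[ok])
})

test_that("specialist loss raises mean generalism where it happens", {
  land <- simulate_landscape(landscape_config(seed = 17))
  d <- compute_deltas(land$current, land$future, land$tree, land$traits)
  lost <- extinct_species(land$current, land$future)
  spec_lost <- intersect(lost, land$traits$species[land$traits$niche_breadth < 0.5])
  had_spec <- rowSums(occ_matrix(land$current)[, spec_lost, drop = FALSE]) > 0
  sel <- had_spec & !is.na(d$d_eg)
  expect_gt(mean(d$d_eg[sel]), 0)
})

test_that("AICc closed form and driver selection recover a planted response", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_error(aicc(-10, 19, 20), "insufficient data")

  withr::with_seed(50, {
    d <- tibble::tibble(d_sr = rnorm(80), d_eg = rnorm(80), d_pd = rnorm(80),
                        elevation = rnorm(80))
    d$y <- 2 * d$d_sr - 0.8 * d$d_sr^2 + rnorm(80, sd = 1e-8)
  })
  tab <- driver_model_selection(d, "y", c("d_eg", "d_pd", "d_sr", "elevation"))
  expect_equal(nrow(tab), 16)                  # all subsets + intercept-only
  expect_match(tab$terms[1], "d_sr")
  expect_equal(tab$d_aicc[1], 0)
  expect_gt(tab$deviance_explained[1], 0.999)
  expect_true(all(diff(tab$aicc) >= -1e-9))    # ranked

  # pure noise: the intercept-only model stays competitive
  hits <- 0
  for (s in 1:60) {
    withr::with_seed(700 + s, {
      dn <- tibble::tibble(d_sr = rnorm(60), d_eg = rnorm(60), y = rnorm(60))
    })
    tb <- driver_model_selection(dn, "y", c("d_sr", "d_eg"), basis_degree = 2)
    hits <- hits + (tb$d_aicc[tb$terms == "(intercept)"] < 2)
  }
  expect_gte(hits / 60, 0.9)
})
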