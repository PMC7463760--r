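two_group_grid <- function() {
  tr <- balanced_tree()
  sets <- c(rep(list(c("A", "B")), 5), rep(list(c("C", "D")), 5))
  list(tree = tr, grid = grid_from_sets(sets, c("A", "B", "C", "D"), n_rows = 2))
}

test_that("embedding separates disjoint groups and preserves dissimilarity order", {
  tg <- two_group_grid()
  emb <- compositional_embedding(tg$grid, tg$tree, n_axes = 3)
  ax1 <- emb$axis1
  expect_equal(sd(ax1[1:5]), 0, tolerance = 1e-9)     # identical cells coincide
  expect_equal(sd(ax1[6:10]), 0, tolerance = 1e-9)
  expect_gt(abs(mean(ax1[1:5]) - mean(ax1[6:10])), 0.5)

  expect_error(compositional_embedding(tg$grid, tg$tree, n_axes = 0), "n_axes")
  uni <- grid_from_sets(rep(list(c("A")), 5), c("A", "B", "C", "D"))
  expect_error(compositional_embedding(uni, balanced_tree()), "zero dissimilarity")

  land <- simulate_landscape(landscape_config(seed = 19))
  d <- beta_dissimilarity(land$current, land$tree)
  lw <- lower.tri(d)
  # min-based turnover is non-metric: the uncorrected embedding is lossy but
  # must still track the input ordering
  emb2 <- compositional_embedding(land$current, land$tree, n_axes = 1000)
  e <- as.matrix(dist(as.matrix(emb2[, -1])))
  expect_gt(cor(d[lw], e[lw], method = "spearman"), 0.6)
  expect_true(attr(emb2, "variance_represented") > 0 &&
              attr(emb2, "variance_represented") <= 1 + 1e-12)
  # with the additive-constant correction the full embedding is essentially
  # exact (the corrected spectrum is flat, so all axes are needed)
  embc <- compositional_embedding(land$current, land$tree, n_axes = 1000,
                                  correction = "cailliez")
  ec <- as.matrix(dist(as.matrix(embc[, -1])))
  expect_gt(cor(d[lw], ec[lw], method = "spearman"), 0.9)
})

test_that("k-means recovers separable clouds; multi-start never hurts", {
  withr::with_seed(5, {
    pts <- rbind(cbind(rnorm(20, 0, 0.1), rnorm(20, 0, 0.1)),
                 cbind(rnorm(20, 5, 0.1), rnorm(20, 5, 0.1)))
  })
  coords <- tibble::tibble(cell = sprintf("r0_c%d", 0:39),
                           axis1 = pts[, 1], axis2 = pts[, 2])
  reg <- kmeans_regionalize(coords, 2, seed = 1)
  expect_length(unique(reg$cluster[1:20]), 1)
  expect_length(unique(reg$cluster[21:40]), 1)
  expect_false(reg$cluster[1] == reg$cluster[21])

  # k = number of distinct points -> every point its own cluster, WCSS 0
  cd <- tibble::tibble(cell = sprintf("r0_c%d", 0:4),
                       axis1 = c(0, 0, 2, 3, 4.5), axis2 = 0)
  regd <- kmeans_regionalize(cd, 4, seed = 2)
  expect_equal(attr(regd, "wcss"), 0, tolerance = 1e-12)
  expect_error(kmeans_regionalize(cd, 5, seed = 2), "config error")

  w10 <- attr(kmeans_regionalize(coords, 3, seed = 7, n_starts = 10), "wcss")
  w1 <- attr(kmeans_regionalize(coords, 3, seed = 7, n_starts = 1), "wcss")
  expect_lte(w10, w1 + 1e-9)
})

test_that("clara equals plain PAM when the sample is the whole set", {
  tg <- two_group_grid()
  d <- beta_dissimilarity(tg$grid, tg$tree)
  cl <- clara_regionalize(d, 2, seed = 3, sample_size = nrow(d))
  pm <- cluster::pam(as.dist(d), k = 2, diss = TRUE)
  expect_equal(unname(cl$cluster), unname(pm$clustering[cl$cell]))
  # two disjoint compositional groups recovered exactly
  expect_length(unique(cl$cluster[1:5]), 1)
  expect_length(unique(cl$cluster[6:10]), 1)
  expect_false(cl$cluster[1] == cl$cluster[6])
  expect_error(clara_regionalize(d, 5, seed = 1, sample_size = 3), "sample_size")

  # subsampled run still scores medoids over all cells
  land <- simulate_landscape(landscape_config(seed = 23))
  dd <- beta_dissimilarity(land$current, land$tree)
  cs <- clara_regionalize(dd, 4, seed = 5, n_samples = 4, sample_size = 30)
  med <- attr(cs, "medoids")
  expect_equal(attr(cs, "total_dissimilarity"),
               sum(apply(dd[, med, drop = FALSE], 1, min)), tolerance = 1e-12)
})

test_that("silhouette: hand-computed value and optimal-k recovery", {
  cd <- tibble::tibble(cell = sprintf("r0_c%d", 0:3),
                       axis1 = c(0, 0.1, 10, 10.1))
  reg <- kmeans_regionalize(cd, 2, seed = 1)
  # outer points: a=0.1, b=(10+10.1)/2; inner points: a=0.1, b=(9.9+10)/2
  hand <- ((1 - 0.1 / 10.05) + (1 - 0.1 / 9.95)) / 2
  expect_equal(attr(reg, "mean_silhouette"), hand, tolerance = 1e-9)

  withr::with_seed(8, {
    pts <- rbind(cbind(rnorm(15, 0, 0.2), rnorm(15, 0, 0.2)),
                 cbind(rnorm(15, 8, 0.2), rnorm(15, 0, 0.2)),
                 cbind(rnorm(15, 4, 0.2), rnorm(15, 7, 0.2)))
  })
  coords <- tibble::tibble(cell = sprintf("r0_c%d", 0:44),
                           axis1 = pts[, 1], axis2 = pts[, 2])
  best <- silhouette_optimal_k(coords, 2:6, "kmeans", seed = 2)
  expect_identical(attr(best, "k"), 3L)
  expect_false(attr(best, "weak_structure"))
  expect_true(all(attr(best, "sweep")$mean_silhouette >= -1 &
                  attr(best, "sweep")$mean_silhouette <= 1))

  # a single diffuse cloud never rises above the weak-structure band
  withr::with_seed(9, {
    blob <- tibble::tibble(cell = sprintf("r0_c%d", 0:59),
                           axis1 = rnorm(60), axis2 = rnorm(60))
  })
  flagged <- silhouette_optimal_k(blob, 2:5, "kmeans", seed = 3)
  expect_true(attr(flagged, "weak_structure"))
  expect_error(silhouette_optimal_k(coords, integer(0)), "k_range")
})

test_that("V-measure: fixed points, permutation invariance, independence", {
  reg <- function(labels) tibble::tibble(cell = sprintf("c%d", seq_along(labels)),
                                         cluster = labels)
  a <- reg(c(1, 1, 2, 2, 3, 3))
  expect_equal(v_measure(a, a)$v_measure, 1)
  perm <- reg(c(3, 3, 1, 1, 2, 2))          # same partition, relabeled
  expect_equal(v_measure(a, perm)$v_measure, 1)

  u <- reg(c(1, 1, 2, 2)); w <- reg(c(1, 2, 1, 2))
  vm <- v_measure(u, w)
  expect_equal(vm$homogeneity, 0, tolerance = 1e-12)
  expect_equal(vm$completeness, 0, tolerance = 1e-12)
  expect_equal(vm$v_measure, 0, tolerance = 1e-12)

  expect_error(v_measure(a, reg(1:2)), "alignment")

  # h and c swap roles when the arguments swap; V is symmetric
  x <- reg(c(1, 1, 1, 2, 2, 3)); y <- reg(c(1, 2, 2, 2, 3, 3))
  expect_equal(v_measure(x, y)$homogeneity, v_measure(y, x)$completeness)
  expect_equal(v_measure(x, y)$v_measure, v_measure(y, x)$v_measure)
})
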