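default_swaps <- function(m) max(5L * sum(m), 1L)

curveball_draws <- function(m, n_draws, seed, n_swaps = NULL) {
  n_swaps <- n_swaps %||% default_swaps(m)
  nm <- vegan::nullmodel(m, "curveball")
  sims <- stats::simulate(nm, nsim = n_draws, thin = n_swaps, burnin = 0,
                          seed = seed)
  sims
}

#' Fixed-marginal randomization of an occurrence grid
#'
#' One draw of the curveball trade algorithm: a Markov chain on binary
#' matrices whose stationary distribution is uniform over all matrices with
#' the observed row sums (cell richness) and column sums (species range
#' sizes). Both marginals are preserved exactly on every draw, so the null
#' controls for richness and range size — the inference the randomization is
#' meant to support. Degenerate matrices (all ones or all zeros) have a
#' single fixed-marginal state and are returned unchanged with a warning.
#'
#' @param grid occurrence tibble.
#' @param seed integer seed (deterministic per seed).
#' @param n_swaps trades before the draw is taken; default 5 x the number of
#'   presences, a common mixing heuristic.
#' @return a randomized occurrence tibble with identical marginals.
#' @export
randomize_occurrences <- function(grid, seed = 1, n_swaps = NULL) {
  m <- occ_matrix(grid)
  if (all(m == 1L) || all(m == 0L)) {
    warn("degenerate matrix: unique fixed-marginal state, returned unchanged")
    return(grid)
  }
  sims <- curveball_draws(m, 1L, seed, n_swaps)
  out <- sims[, , 1]
  dimnames(out) <- dimnames(m)
  as_occurrence_grid(out, grid[, geometry_cols])
}

#' Null distributions and significance surfaces
#'
#' Recomputes the metric surfaces of [phylo_metrics()] on `n_rand`
#' fixed-marginal randomizations of the grid and summarises, per cell:
#' two-tailed percentiles for PE, PE_comp, PD (and its comparison value),
#' RPD and RPE, and the standardized effect size of PD. The percentile is
#' `(#null < obs + 0.5 * #null == obs) / n_rand`, so a cell identical to its
#' null sits at 0.5; SES is `(obs - null mean) / null sd`, set to 0 (and
#' flagged) where the null sd is 0.
#'
#' @param grid occurrence tibble.
#' @param tree `phylo` containing every grid species.
#' @param n_rand number of randomizations (999 for inference-grade runs;
#'   smaller values are useful for smoke tests).
#' @param seed integer seed.
#' @param n_swaps curveball trades between successive draws (default 5 x
#'   presences).
#' @return a tibble keyed by `cell`: observed `richness`, `pe`, `pe_comp`,
#'   `rpd`, `rpe`, percentiles `pct_pd`, `pct_pe`, `pct_pe_comp`, `pct_rpd`,
#'   `pct_rpe`, `ses_pd`, `ses_pd_zero_sd`, `n_rand`. Empty cells carry `NA`.
#' @export
null_significance <- function(grid, tree, n_rand = 999, seed = 1, n_swaps = NULL) {
  if (n_rand < 1) abort("n_rand must be >= 1")
  validate_tree(tree)
  te <- tip_edge_matrix(tree)
  m <- occ_matrix(grid)
  obs <- metric_mat(m, te)
  metrics <- colnames(obs)

  degenerate <- all(m == 1L) || all(m == 0L)
  if (degenerate) {
    sims <- array(m, dim = c(nrow(m), ncol(m), n_rand))
  } else {
    sims <- curveball_draws(m, n_rand, seed, n_swaps)
  }

  n_cell <- nrow(m)
  n_less <- matrix(0, n_cell, length(metrics), dimnames = list(NULL, metrics))
  n_eq <- n_less
  s1 <- numeric(n_cell); s2 <- numeric(n_cell)
  tol <- 1e-12
  for (r in seq_len(n_rand)) {
    sim <- sims[, , r]
    dimnames(sim) <- dimnames(m)
    nullv <- metric_mat(sim, te)
    for (k in metrics) {
      d <- nullv[, k] - obs[, k]
      n_less[, k] <- n_less[, k] + (d < -tol)
      n_eq[, k] <- n_eq[, k] + (abs(d) <= tol)
    }
    s1 <- s1 + nullv[, "pd"]
    s2 <- s2 + nullv[, "pd"]^2
  }
  pct <- (n_less + 0.5 * n_eq) / n_rand
  mu <- s1 / n_rand
  sdv <- sqrt(pmax(s2 / n_rand - mu^2, 0))
  zero_sd <- sdv <= 1e-7 * (abs(mu) + 1)   # catastrophic-cancellation floor
  ses <- ifelse(zero_sd, 0, (obs[, "pd"] - mu) / ifelse(zero_sd, 1, sdv))

  richness <- as.integer(rowSums(m))
  empty <- richness == 0
  na_empty <- function(x) ifelse(empty, NA_real_, x)
  tibble::tibble(
    cell = grid$cell, richness = richness,
    pe = na_empty(obs[, "pe"]), pe_comp = na_empty(obs[, "pe_comp"]),
    rpd = na_empty(obs[, "rpd"]), rpe = na_empty(obs[, "rpe"]),
    pct_pd = na_empty(pct[, "pd"]), pct_pe = na_empty(pct[, "pe"]),
    pct_pe_comp = na_empty(pct[, "pe_comp"]),
    pct_rpd = na_empty(pct[, "rpd"]), pct_rpe = na_empty(pct[, "rpe"]),
    ses_pd = na_empty(ses), ses_pd_zero_sd = !empty & zero_sd,
    n_rand = as.integer(n_rand)
  )
}

# fast per-cell metric matrix used inside the randomization loop
metric_mat <- function(m, te) {
  B <- cell_edge_incidence(m, te)
  rng <- colSums(B)
  len <- te$lengths / sum(te$lengths)
  len_comp <- rep(1 / length(len), length(len))
  pe_w <- function(l) ifelse(rng > 0, l / pmax(rng, 1), 0)
  pd <- as.vector(B %*% len)
  pd_comp <- as.vector(B %*% len_comp)
  pe <- as.vector(B %*% pe_w(len))
  pe_comp <- as.vector(B %*% pe_w(len_comp))
  cbind(pd = pd, pe = pe, pe_comp = pe_comp,
        rpd = ifelse(pd_comp > 0, pd / pd_comp, 0),
        rpe = ifelse(pe_comp > 0, pe / pe_comp, 0))
}

#' CANAPE classification of endemism centers
#'
#' Two-step categorical analysis of neo- and paleo-endemism. Step 1 gates on
#' endemism: a cell is considered only if its PE percentile or its
#' comparison-tree PE percentile exceeds `1 - alpha`. Step 2 reads the RPE
#' percentile: significantly high (`> 1 - alpha`) is a paleo-endemism
#' center, significantly low (`< alpha`) a neo-endemism center; otherwise a
#' cell significantly high in both PE and PE_comp taken alone is a mixed
#' center, upgraded to super-endemism when both exceed `1 - alpha_super`.
#' Everything else is `not_significant`; empty cells are `no_data`.
#'
#' @param sig significance tibble from [null_significance()].
#' @param alpha one-tail probability of the two-tailed rule (default 0.025,
#'   i.e. the 0.975/0.025 cutoffs).
#' @param alpha_super stricter tail for the super upgrade (default 0.01).
#' @return a tibble keyed by `cell` with a `category` factor with levels
#'   `neo`, `paleo`, `mixed`, `super`, `not_significant`, `no_data`.
#' @export
canape_classify <- function(sig, alpha = 0.025, alpha_super = 0.01) {
  need <- c("pct_pe", "pct_pe_comp", "pct_rpe")
  miss <- setdiff(need, names(sig))
  if (length(miss)) abort(paste0("missing percentile layers: ", paste(miss, collapse = ", ")))
  hi <- 1 - alpha; hi_s <- 1 - alpha_super
  cat <- dplyr::case_when(
    is.na(sig$pct_pe) ~ "no_data",
    !(sig$pct_pe > hi | sig$pct_pe_comp > hi) ~ "not_significant",
    sig$pct_rpe > hi ~ "paleo",
    sig$pct_rpe < alpha ~ "neo",
    sig$pct_pe > hi_s & sig$pct_pe_comp > hi_s ~ "super",
    sig$pct_pe > hi & sig$pct_pe_comp > hi ~ "mixed",
    TRUE ~ "not_significant"
  )
  tibble::tibble(
    cell = sig$cell,
    category = factor(cat, levels = canape_levels)
  )
}

canape_levels <- c("neo", "paleo", "mixed", "super", "not_significant", "no_data")

#' Count endemism centers by category
#'
#' Reports, per CANAPE category, both the number of cells and the number of
#' connected components (queen adjacency) — two readings of what counts as
#' one "area" of endemism.
#'
#' @param canape tibble from [canape_classify()].
#' @param geometry a [grid_geometry()] tibble (or any tibble with `cell`,
#'   `row`, `col`) covering the same cells.
#' @return a tibble: `category`, `n_cells`, `n_components`.
#' @export
canape_counts <- function(canape, geometry) {
  d <- dplyr::inner_join(canape, geometry[, c("cell", "row", "col")], by = "cell")
  n_rows <- max(d$row) + 1L; n_cols <- max(d$col) + 1L
  purrr::map_dfr(canape_levels, function(lv) {
    sel <- d[d$category == lv, ]
    tibble::tibble(category = lv, n_cells = nrow(sel),
                   n_components = count_components(sel$row, sel$col))
  }) |> dplyr::mutate(category = factor(.data$category, levels = canape_levels))
}

count_components <- function(rows, cols) {
  n <- length(rows)
  if (n == 0) return(0L)
  key <- paste(rows, cols)
  idx <- seq_len(n)
  parent <- idx
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pos <- setNames(idx, key)
  for (i in idx) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- pos[paste(rows[i] + dr, cols[i] + dc)]
      if (!is.na(j)) { a <- find(i); b <- find(j); if (a != b) parent[a] <- b }
    }
  }
  length(unique(vapply(idx, find, 0L)))
}

#' Do endemism-center types sit at different elevations?
#'
#' Kruskal-Wallis rank test of cell elevation across CANAPE categories
#' (including `not_significant`; `no_data` cells are excluded), with the
#' usual tie correction and chi-square approximation.
#'
#' @param canape tibble from [canape_classify()].
#' @param covariates covariates tibble with `cell` and `elevation`.
#' @return a one-row tibble: `statistic` (H), `df`, `p_value`, `n_groups`, `n`.
#' @export
center_elevation_test <- function(canape, covariates) {
  d <- dplyr::inner_join(canape, covariates[, c("cell", "elevation")], by = "cell")
  d <- d[d$category != "no_data", ]
  d$category <- droplevels(d$category)
  if (nlevels(d$category) < 2) abort("degenerate test: fewer than 2 categories present")
  kt <- kruskal.test(elevation ~ category, data = d)
  h <- unname(kt$statistic); p <- kt$p.value
  if (!is.finite(h)) { h <- 0; p <- 1 }   # every elevation tied: no evidence
  tibble::tibble(statistic = h, df = unname(kt$parameter),
                 p_value = p, n_groups = nlevels(d$category), n = nrow(d))
}
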