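# Independent oracles and fixture builders shared across test files.

# the worked 4-tip balanced tree used in several hand-computed examples
balanced_tree <- function() read_newick("((A:1,B:1):1,(C:1,D:1):1);")

# occurrence tibble from a named list of character species sets
grid_from_sets <- function(sets, species, n_rows = 1) {
  n <- length(sets)
  n_cols <- ceiling(n / n_rows)
  geom <- grid_geometry(n_rows, n_cols)[seq_len(n), ]
  m <- matrix(0L, n, length(species), dimnames = list(geom$cell, species))
  for (i in seq_len(n)) m[i, sets[[i]]] <- 1L
  as_occurrence_grid(m, geom)
}

# naive per-cell metric oracle: rebuilds each cell's edge set by walking
# every present tip's path to the root (independent of the package's
# postorder incidence computation)
naive_metrics <- function(grid, tree) {
  m <- occ_matrix(grid)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  pedge <- integer(max(tree$edge))
  pedge[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  path_edges <- lapply(seq_len(n_tip), function(t) {
    es <- integer(); node <- t
    while (node != root) { es <- c(es, pedge[node]); node <- parent[node] }
    es
  })
  names(path_edges) <- tree$tip.label
  cell_edges <- lapply(seq_len(nrow(m)), function(i) {
    sp <- colnames(m)[m[i, ] == 1]
    sort(unique(unlist(path_edges[sp])))
  })
  n_edge <- nrow(tree$edge)
  rng <- vapply(seq_len(n_edge), function(e) {
    sum(vapply(cell_edges, function(es) e %in% es, TRUE))
  }, 0)
  len_raw <- tree$edge.length
  len <- len_raw / sum(len_raw)
  len_comp <- rep(1 / n_edge, n_edge)
  one_cell <- function(es) {
    if (length(es) == 0) {
      return(c(pd = NA, pd_comp = NA, pe = NA, pe_comp = NA,
               rpd = NA, rpe = NA, pe_raw = NA))
    }
    pd <- sum(len[es]); pdc <- sum(len_comp[es])
    pe <- sum(len[es] / rng[es]); pec <- sum(len_comp[es] / rng[es])
    c(pd = pd, pd_comp = pdc, pe = pe, pe_comp = pec,
      rpd = pd / pdc, rpe = pe / pec, pe_raw = sum(len_raw[es] / rng[es]))
  }
  do.call(rbind, lapply(cell_edges, one_cell))
}

# random tree + random occupancy instance for property sweeps
random_instance <- function(seed) {
  withr::with_seed(seed, {
    n_tip <- sample(4:32, 1)
    n_cell <- sample(5:100, 1)
    tree <- ape::rphylo(n_tip, 1, 0)
    tree$tip.label <- sprintf("s%02d", seq_len(n_tip))
    p <- runif(1, 0.05, 0.4)
    n_rows <- sample(1:5, 1)
    geom <- grid_geometry(n_rows, ceiling(n_cell / n_rows))[seq_len(n_cell), ]
    m <- matrix(rbinom(n_cell * n_tip, 1, p), n_cell, n_tip,
                dimnames = list(geom$cell, tree$tip.label))
    list(tree = tree, grid = as_occurrence_grid(m, geom))
  })
}

# brute-force moving-window turnover oracle built on phylo_beta_pair
naive_beta_map <- function(grid, tree, window = 1) {
  m <- occ_matrix(grid)
  vapply(seq_len(nrow(m)), function(i) {
    if (sum(m[i, ]) == 0) return(NA_real_)
    vals <- c()
    for (j in seq_len(nrow(m))) {
      if (j == i || sum(m[j, ]) == 0) next
      if (abs(grid$row[j] - grid$row[i]) <= window &&
          abs(grid$col[j] - grid$col[i]) <= window) {
        sa <- colnames(m)[m[i, ] == 1]; sb <- colnames(m)[m[j, ] == 1]
        vals <- c(vals, phylo_beta_pair(sa, sb, tree)$beta_sim)
      }
    }
    if (length(vals)) mean(vals) else NA_real_
  }, 0)
}

# planted-signal demo configuration used by recovery tests
recovery_config <- function(seed) {
  landscape_config(seed = seed, planted_signals = list(
    planted_signal(c(1, 3), c(1, 3), "paleo", 4, branch_scale = 10),
    planted_signal(c(8, 10), c(8, 10), "neo", 4, branch_scale = 0.1)
  ))
}

in_region <- function(d, rows, cols) {
  d$row >= rows[1] & d$row <= rows[2] & d$col >= cols[1] & d$col <= cols[2]
}

# 300-cell lattice with SAR(lambda) errors, shared by the recovery tests
sar_sim <- function(seed, lambda, n_rows = 15, n_cols = 20, k = 6,
                    beta = c(1, -0.5), sigma = 0.7) {
  geom <- grid_geometry(n_rows, n_cols)
  w <- build_knn_weights(geom, k)
  n <- nrow(geom)
  withr::with_seed(seed, {
    X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
    eps <- rnorm(n, sd = sigma)
  })
  u <- as.vector(solve(diag(n) - lambda * w$W, eps))
  y <- as.vector(X %*% beta + u)
  list(data = tibble::tibble(cell = geom$cell, y = y, x1 = X[, 1], x2 = X[, 2]),
       weights = w, geom = geom, beta = beta)
}
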