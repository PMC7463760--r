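#' Configuration for a synthetic island landscape
#'
#' Bundles every knob of the synthetic generator: grid geometry, species
#' pool, the right-skewed range-size distribution, the niche-breadth bounds,
#' the severity of the future upslope shift, and any planted endemism
#' signals. The defaults describe the study conditions used throughout the
#' package's tests: a mountainous island grid with a W-E ridge, a strongly
#' right-skewed range-size distribution, and a moderate future contraction.
#'
#' @param n_rows,n_cols grid dimensions (`n_rows * n_cols >= 4`).
#' @param n_species number of species (>= 4, including planted taxa).
#' @param seed integer seed; all generator randomness derives from it.
#' @param elevation_relief peak height of the synthetic ridge (m); 0 gives a
#'   flat island.
#' @param range_size parameters of the range-size distribution: either
#'   `list(mu=, size=)` for a shifted negative binomial (1 + NB(size, mu-1)),
#'   or `list(fixed=)` to force every species to the same range size.
#' @param niche_breadth_range ordered pair inside \[0,1\]; generated niche
#'   breadths fall in this interval and correlate positively with range size.
#' @param future_shift fraction in \[0,1\] of each species' climatic envelope
#'   lost/displaced in the future slice; specialists (niche breadth < 0.5)
#'   lose proportionally more and are extirpated when `future_shift = 1`.
#' @param planted_signals list of [planted_signal()] objects.
#' @param cell_size cell edge length (m).
#' @return a `landscape_config` list.
#' @export
landscape_config <- function(n_rows = 12, n_cols = 12, n_species = 40,
                             seed = 1,
                             elevation_relief = 2400,
                             range_size = list(mu = 24, size = 1.3),
                             niche_breadth_range = c(0.05, 0.95),
                             future_shift = 0.35,
                             planted_signals = list(),
                             cell_size = 1000) {
  if (n_rows * n_cols < 4) abort("invalid config: grid must have at least 4 cells")
  if (n_species < 4) abort("invalid config: n_species must be >= 4")
  nbr <- niche_breadth_range
  if (length(nbr) != 2 || nbr[1] > nbr[2] || nbr[1] < 0 || nbr[2] > 1) {
    abort("invalid config: niche_breadth_range must be ordered and inside [0,1]")
  }
  if (future_shift < 0 || future_shift > 1) abort("invalid config: future_shift must be in [0,1]")
  for (ps in planted_signals) {
    if (!inherits(ps, "planted_signal")) abort("planted_signals must be built with planted_signal()")
    if (max(ps$rows) >= n_rows || max(ps$cols) >= n_cols) {
      abort("invalid config: planted signal region outside grid")
    }
  }
  n_planted <- sum(vapply(planted_signals, function(p) p$n_taxa, 0L))
  if (n_planted > n_species - 2L) abort("invalid config: planted taxa leave fewer than 2 free species")
  structure(list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_species = as.integer(n_species), seed = as.integer(seed),
    elevation_relief = elevation_relief, range_size = range_size,
    niche_breadth_range = nbr, future_shift = future_shift,
    planted_signals = planted_signals, cell_size = cell_size
  ), class = "landscape_config")
}

#' A planted endemism signal
#'
#' Describes a rectangular block of cells in which a monophyletic clade of
#' `n_taxa` range-restricted species is confined, with the clade's branch
#' lengths multiplied by `branch_scale`: values much greater than 1 plant a
#' paleo-endemism signal (long, old branches — a diversity "museum"), values
#' much smaller than 1 a neo-endemism signal (short, young branches — a
#' "cradle"). Recovery of these planted centers is the generator's main
#' acceptance handle.
#'
#' @param rows,cols 0-based inclusive index ranges (length-2 integer vectors)
#'   of the rectangular region.
#' @param signal_type `"paleo"` or `"neo"`.
#' @param n_taxa clade size (>= 2).
#' @param branch_scale positive multiplier on the clade's branch lengths; if
#'   `NULL`, defaults to 10 for paleo and 0.1 for neo.
#' @return a `planted_signal` list.
#' @export
planted_signal <- function(rows, cols, signal_type = c("paleo", "neo"),
                           n_taxa = 4, branch_scale = NULL) {
  signal_type <- match.arg(signal_type)
  if (n_taxa < 2) abort("invalid config: planted signal needs n_taxa >= 2")
  branch_scale <- branch_scale %||% if (signal_type == "paleo") 10 else 0.1
  if (branch_scale <= 0) abort("invalid config: branch_scale must be positive")
  rows <- as.integer(range(rows)); cols <- as.integer(range(cols))
  if (min(rows) < 0 || min(cols) < 0) abort("invalid config: region indices are 0-based and non-negative")
  structure(list(rows = rows, cols = cols, signal_type = signal_type,
                 n_taxa = as.integer(n_taxa), branch_scale = branch_scale),
            class = "planted_signal")
}

planted_labels <- function(planted) {
  if (length(planted) == 0) return(list())
  lapply(seq_along(planted), function(i) {
    sprintf("%s%02d_s%02d", planted[[i]]$signal_type, i, seq_len(planted[[i]]$n_taxa))
  })
}

region_cells <- function(signal, geometry) {
  geometry$cell[geometry$row >= signal$rows[1] & geometry$row <= signal$rows[2] &
                geometry$col >= signal$cols[1] & geometry$col <= signal$cols[2]]
}

#' Simulate a dated phylogeny with optional planted clades
#'
#' A Yule (pure-birth, rate 1) tree via [ape::rphylo()]; each planted signal
#' replaces one randomly chosen tip with a Yule subclade whose depth is set
#' to 30% of the base-tree height and whose branch lengths are then
#' multiplied by the signal's `branch_scale`. Planted clades are therefore
#' monophyletic by construction and keep deterministic labels
#' (`paleo01_s01`, ...). Identical seeds give identical Newick strings.
#'
#' @param n_species total number of tips (>= 4, including planted taxa).
#' @param seed integer seed.
#' @param planted list of [planted_signal()] objects.
#' @return an `phylo` object with `n_species` tips.
#' @export
simulate_phylogeny <- function(n_species, seed = 1, planted = list()) {
  if (n_species < 4) abort("invalid config: n_species must be >= 4")
  n_taxa <- vapply(planted, function(p) p$n_taxa, 0L)
  n_base <- n_species - sum(n_taxa) + length(planted)
  if (n_base < 2) abort("invalid config: planted taxa leave fewer than 2 free lineages")
  labels <- planted_labels(planted)
  withr::with_seed(seed, {
    tree <- ape::rphylo(n_base, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(n_base))
    hosts <- if (length(planted)) sample(tree$tip.label, length(planted)) else character()
    height <- max(ape::node.depth.edgelength(tree))
    for (i in seq_along(planted)) {
      sub <- ape::rphylo(planted[[i]]$n_taxa, birth = 1, death = 0)
      sub_h <- max(ape::node.depth.edgelength(sub))
      sub$edge.length <- sub$edge.length / sub_h * (0.3 * height)
      sub$edge.length <- sub$edge.length * planted[[i]]$branch_scale
      sub$tip.label <- labels[[i]]
      tree <- ape::bind.tree(tree, sub, where = which(tree$tip.label == hosts[i]))
    }
    tree
  })
}

# separable gaussian blur with edge clamping; z is a matrix
smooth_field <- function(z, sigma = 2) {
  if (sigma <= 0) return(z)
  r <- ceiling(3 * sigma)
  w <- exp(-((-r:r)^2) / (2 * sigma^2)); w <- w / sum(w)
  blur <- function(m) {
    n <- ncol(m); out <- matrix(0, nrow(m), n)
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(n) + o, 1L), n)
      out <- out + w[o + r + 1] * m[, idx, drop = FALSE]
    }
    out
  }
  t(blur(t(blur(z))))
}

std0 <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Simulate grid geometry and per-cell covariates
#'
#' Elevation is a W-E ridge with four massif-like peaks (height set by
#' `elevation_relief`); soil pH, mean diurnal range and long-term climate
#' stability are smooth random fields with deliberately weak couplings to
#' elevation (|r| kept well below 0.5) so that a variance-inflation screen
#' of the four covariates passes.
#'
#' @param config a [landscape_config()].
#' @return a tibble: [grid_geometry()] columns plus `elevation` (m), `ph`,
#'   `diurnal_range` (deg C), `stability` (\[0,1\]).
#' @export
simulate_covariates <- function(config) {
  geom <- grid_geometry(config$n_rows, config$n_cols, config$cell_size)
  u <- (geom$col + 0.5) / config$n_cols
  v <- (geom$row + 0.5) / config$n_rows
  ridge_row <- 0.5 + 0.12 * sin(2 * pi * 2 * u)
  peaks <- rowSums(sapply(c(0.12, 0.40, 0.65, 0.88), function(p) {
    exp(-(u - p)^2 / (2 * 0.07^2))
  }))
  ridge <- pmin(peaks, 1) * exp(-(v - ridge_row)^2 / (2 * 0.18^2))
  withr::with_seed(config$seed + 11L, {
    nz <- function(sigma) std0(as.vector(t(smooth_field(
      matrix(rnorm(config$n_rows * config$n_cols), config$n_rows, config$n_cols), sigma))))
    elevation <- config$elevation_relief * pmax(0.9 * ridge + 0.1 * nz(1.5) * 0.3, 0)
    ez <- std0(elevation)
    # noise fields orthogonalized against elevation and each other, so the
    # only covariate correlations are the small designed couplings below
    ortho <- function(f, basis) std0(resid(lm.fit(cbind(1, basis), f)))
    f1 <- ortho(nz(1.2), ez)
    f2 <- ortho(nz(1.2), cbind(ez, f1))
    f3 <- ortho(nz(1.5), cbind(ez, f1, f2))
    ph <- pmin(pmax(7 + 0.8 * f1 - 0.25 * ez, 4), 9)
    diurnal_range <- 10 + 1.5 * f2 + 0.35 * ez
    stability <- stats::pnorm(0.9 * f3 + 0.30 * ez)
  })
  dplyr::mutate(geom, elevation = elevation, ph = ph,
                diurnal_range = diurnal_range, stability = stability)
}

queen_adjacency <- function(n_rows, n_cols) {
  idx <- matrix(seq_len(n_rows * n_cols), n_rows, n_cols, byrow = TRUE)
  lapply(seq_len(n_rows * n_cols), function(i) {
    r <- (i - 1L) %/% n_cols; cc <- (i - 1L) %% n_cols
    rr <- pmax(r - 1L, 0L):pmin(r + 1L, n_rows - 1L)
    ccs <- pmax(cc - 1L, 0L):pmin(cc + 1L, n_cols - 1L)
    nb <- as.vector(outer(rr, ccs, function(a, b) a * n_cols + b + 1L))
    nb[nb != i]
  })
}

# region-growing placement around an elevational optimum; seed_gamma /
# grow_gamma sharpen the suitability kernel (1 = proportional sampling)
grow_range <- function(size, allowed, suit, adj, seed_gamma = 1, grow_gamma = 1) {
  ps <- suit[allowed]^seed_gamma
  start <- if (length(allowed) == 1) allowed else sample(allowed, 1, prob = ps)
  occ <- start
  ok <- logical(length(suit)); ok[allowed] <- TRUE
  while (length(occ) < size) {
    frontier <- setdiff(unique(unlist(adj[occ])), occ)
    frontier <- frontier[ok[frontier]]
    if (length(frontier) == 0) break
    nxt <- if (length(frontier) == 1) frontier else {
      sample(frontier, 1, prob = suit[frontier]^grow_gamma)
    }
    occ <- c(occ, nxt)
  }
  occ
}

#' Simulate species ranges and traits on the landscape
#'
#' Each species receives a range size drawn from the configured right-skewed
#' distribution, a niche breadth positively tied to that range size, and an
#' elevational optimum; its range is placed by seeding a cell from an
#' elevational-suitability kernel and region-growing to the drawn size
#' (queen adjacency), which yields the spatially cohesive ranges stacked
#' species distribution models produce. Planted taxa are confined to their
#' signal region, and every species occupies at least one cell.
#'
#' @param tree phylogeny from [simulate_phylogeny()] (tip labels define the
#'   species set).
#' @param covariates tibble from [simulate_covariates()].
#' @param config the [landscape_config()].
#' @return a list with `grid` (occurrence tibble, current slice) and
#'   `traits` (tibble: `species`, `niche_breadth`, `range_size`, `elev_opt`,
#'   `planted`).
#' @export
simulate_ranges <- function(tree, covariates, config) {
  species <- tree$tip.label
  n_sp <- length(species)
  n_cells <- nrow(covariates)
  elev <- covariates$elevation
  erange <- diff(range(elev))
  adj <- queen_adjacency(config$n_rows, config$n_cols)

  labels <- planted_labels(config$planted_signals)
  allowed_idx <- rep(list(seq_len(n_cells)), n_sp)
  names(allowed_idx) <- species
  planted_of <- setNames(rep(NA_character_, n_sp), species)
  for (i in seq_along(config$planted_signals)) {
    sig <- config$planted_signals[[i]]
    cells_i <- which(covariates$cell %in% region_cells(sig, covariates))
    if (length(cells_i) < sig$n_taxa) {
      abort("impossible placement: planted region has fewer cells than planted taxa")
    }
    for (sp in labels[[i]]) {
      if (!sp %in% species) abort("planted taxa missing from tree; regenerate the phylogeny with the same signals")
      allowed_idx[[sp]] <- cells_i
      planted_of[sp] <- sprintf("%s%02d", sig$signal_type, i)
    }
  }

  withr::with_seed(config$seed + 23L, {
    rs_cfg <- config$range_size
    target <- if (!is.null(rs_cfg$fixed)) {
      rep(as.integer(rs_cfg$fixed), n_sp)
    } else {
      1L + rnbinom(n_sp, size = rs_cfg$size, mu = max(rs_cfg$mu - 1, 0.01))
    }
    target <- pmin(target, vapply(allowed_idx, length, 0L))
    target <- pmax(target, 1L)

    nbr <- config$niche_breadth_range
    rs_rank <- (rank(target, ties.method = "average") - 0.5) / n_sp
    nb <- nbr[1] + diff(nbr) * pmin(pmax(0.7 * rs_rank + 0.3 * runif(n_sp), 0), 1)

    opt <- numeric(n_sp)
    for (j in seq_len(n_sp)) {
      a <- allowed_idx[[j]]
      opt[j] <- if (is.na(planted_of[j])) runif(1, min(elev), max(elev)) else mean(elev[a])
    }
    tau <- (0.08 + 0.35 * nb) * (erange + 1)

    m <- matrix(0L, n_cells, n_sp, dimnames = list(covariates$cell, species))
    for (j in seq_len(n_sp)) {
      suit <- exp(-(elev - opt[j])^2 / (2 * tau[j]^2)) + 1e-9
      occ <- grow_range(target[j], allowed_idx[[j]], suit, adj)
      m[occ, j] <- 1L
    }
  })

  grid <- as_occurrence_grid(m, covariates[, geometry_cols])
  traits <- tibble::tibble(
    species = species,
    niche_breadth = nb,
    range_size = as.integer(colSums(m)),
    elev_opt = opt,
    planted = unname(planted_of)
  )
  list(grid = grid, traits = traits)
}

#' Project the occurrence grid to a future climate slice
#'
#' Each species' elevational envelope is displaced upslope (its optimum
#' moves toward the island summit by the `future_shift` fraction of the
#' remaining distance), its thermal tolerance narrows by `0.5 * future_shift`,
#' and its range contracts: the fraction of cells lost is `min(1, 2 *
#' future_shift * (1 - niche_breadth))`, so specialists lose proportionally
#' more and, at `future_shift = 1`, every specialist (niche breadth < 0.5)
#' is extirpated. Contracted ranges are regrown around the shifted optimum
#' with a sharpened suitability kernel — survivors settle in the best
#' remaining habitat rather than proportionally across it — which
#' concentrates upshifted assemblages in the same summit cells, the
#' mechanism behind highland biotic homogenization (planted taxa stay
#' confined to their region). Species whose contracted envelope is empty are
#' retained as all-zero columns, mirroring projected local extinction; list
#' them with [extinct_species()]. With `future_shift = 0` the current slice
#' is returned unchanged.
#'
#' @param current occurrence tibble for the current slice.
#' @param covariates tibble from [simulate_covariates()].
#' @param traits traits tibble from [simulate_ranges()].
#' @param config the [landscape_config()].
#' @return an occurrence tibble for the future slice.
#' @export
project_future <- function(current, covariates, traits, config) {
  shift <- config$future_shift
  if (shift == 0) return(current)
  assert_same_cells(current, covariates, "occurrences and covariates")
  species <- occ_species(current)
  m <- occ_matrix(current)
  elev <- covariates$elevation
  adj <- queen_adjacency(config$n_rows, config$n_cols)
  erange <- diff(range(elev))

  tr <- traits[match(species, traits$species), ]
  labels <- planted_labels(config$planted_signals)
  allowed_idx <- rep(list(seq_len(nrow(covariates))), length(species))
  names(allowed_idx) <- species
  for (i in seq_along(config$planted_signals)) {
    sig <- config$planted_signals[[i]]
    cells_i <- which(covariates$cell %in% region_cells(sig, covariates))
    for (sp in intersect(labels[[i]], species)) allowed_idx[[sp]] <- cells_i
  }

  withr::with_seed(config$seed + 37L, {
    out <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_along(species)) {
      rs_cur <- sum(m[, j])
      if (rs_cur == 0) next
      f_loss <- min(1, 2 * shift * (1 - tr$niche_breadth[j]))
      new_size <- round(rs_cur * (1 - f_loss))
      if (new_size < 1) next
      opt_new <- tr$elev_opt[j] + shift * (max(elev) - tr$elev_opt[j])
      tau <- (0.08 + 0.35 * tr$niche_breadth[j]) * (erange + 1) * (1 - 0.5 * shift)
      suit <- exp(-(elev - opt_new)^2 / (2 * tau^2)) + 1e-9
      occ <- grow_range(new_size, allowed_idx[[j]], suit, adj,
                        seed_gamma = 6, grow_gamma = 2)
      out[occ, j] <- 1L
    }
  })
  as_occurrence_grid(out, current[, geometry_cols])
}

#' Species present now but absent from a future slice
#'
#' @param current,future occurrence tibbles on the same grid.
#' @return character vector of locally extinct species ids.
#' @export
extinct_species <- function(current, future) {
  sp <- occ_species(current)
  cur <- colSums(occ_matrix(current)); fut <- colSums(occ_matrix(future)[, sp, drop = FALSE])
  sp[cur > 0 & fut == 0]
}

#' Simulate protected-area and climatic-refugia masks
#'
#' The protected-area mask covers `pa_fraction` of the cells (to the nearest
#' cell), biased toward high elevation — emulating a mountain-centred
#' reserve network. The refugia mask marks cells whose long-term climate
#' stability exceeds the `refugia_quantile` quantile.
#'
#' @param covariates tibble from [simulate_covariates()].
#' @param pa_fraction fraction of cells protected, in \[0,1\].
#' @param refugia_quantile stability quantile above which a cell is refugial.
#' @param seed integer seed.
#' @return a tibble: `cell`, `row`, `col`, `protected`, `refugia`.
#' @export
simulate_masks <- function(covariates, pa_fraction = 0.4, refugia_quantile = 0.75,
                           seed = 1) {
  if (pa_fraction < 0 || pa_fraction > 1) abort("pa_fraction must be in [0,1]")
  n <- nrow(covariates)
  withr::with_seed(seed + 51L, {
    score <- std0(covariates$elevation) + 0.75 * rnorm(n)
  })
  n_prot <- round(pa_fraction * n)
  protected <- rank(-score, ties.method = "first") <= n_prot
  qs <- quantile(covariates$stability, refugia_quantile)
  refugia <- covariates$stability > qs
  dplyr::mutate(covariates[, c("cell", "row", "col")],
                protected = protected, refugia = refugia)
}

#' Simulate a complete synthetic landscape
#'
#' Runs every generator in sequence from one config: phylogeny, covariates,
#' current ranges and traits, future slice, and masks.
#'
#' @param config a [landscape_config()].
#' @param pa_fraction,refugia_quantile passed to [simulate_masks()].
#' @return a `landscape` list: `tree`, `covariates`, `current`, `future`,
#'   `traits`, `masks`, `config`.
#' @export
simulate_landscape <- function(config = landscape_config(),
                               pa_fraction = 0.4, refugia_quantile = 0.75) {
  tree <- simulate_phylogeny(config$n_species, config$seed, config$planted_signals)
  covariates <- simulate_covariates(config)
  rg <- simulate_ranges(tree, covariates, config)
  future <- project_future(rg$grid, covariates, rg$traits, config)
  masks <- simulate_masks(covariates, pa_fraction, refugia_quantile, config$seed)
  structure(list(tree = tree, covariates = covariates, current = rg$grid,
                 future = future, traits = rg$traits, masks = masks,
                 config = config),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d grid, %d species, seed %d\n",
              x$config$n_rows, x$config$n_cols, x$config$n_species, x$config$seed))
  cat(sprintf("  planted signals: %d; future_shift: %.2f; extinct in future: %d\n",
              length(x$config$planted_signals), x$config$future_shift,
              length(extinct_species(x$current, x$future))))
  invisible(x)
}
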