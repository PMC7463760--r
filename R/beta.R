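# edge presence vector for a species set (union of root paths)
edge_presence <- function(species, te) {
  if (length(species) == 0) return(rep(FALSE, ncol(te$D)))
  miss <- setdiff(species, rownames(te$D))
  if (length(miss)) abort(paste0("species absent from tree: ", paste(miss, collapse = ", ")))
  colSums(te$D[species, , drop = FALSE]) > 0
}

#' Pairwise phylogenetic beta diversity between two cells
#'
#' Decomposes total phylogenetic dissimilarity (Sorensen, `beta_sor`) into
#' turnover (Simpson, `beta_sim`) and nestedness-resultant (`beta_sne`)
#' components on shared and unique branch lengths: with `a` the branch
#' length shared by both assemblages' root paths and `b`, `c` the lengths
#' unique to each, `beta_sim = min(b,c) / (a + min(b,c))` (0 when that
#' denominator is 0), `beta_sor = (b + c) / (2a + b + c)`, and
#' `beta_sne = beta_sor - beta_sim`.
#'
#' @param species_a,species_b character vectors of species present in each
#'   cell (subsets of the tree's tips); at least one must be non-empty.
#' @param tree `phylo`.
#' @return a one-row tibble: `a`, `b`, `c`, `beta_sim`, `beta_sne`,
#'   `beta_sor`.
#' @export
phylo_beta_pair <- function(species_a, species_b, tree) {
  validate_tree(tree)
  if (length(species_a) == 0 && length(species_b) == 0) {
    abort("undefined pair: both species sets are empty")
  }
  te <- tip_edge_matrix(tree)
  ea <- edge_presence(species_a, te); eb <- edge_presence(species_b, te)
  len <- te$lengths
  a <- sum(len[ea & eb])
  b <- sum(len[ea & !eb])
  cc <- sum(len[eb & !ea])
  mn <- min(b, cc)
  bsim <- if (a + mn > 0) mn / (a + mn) else 0
  bsor <- if (2 * a + b + cc > 0) (b + cc) / (2 * a + b + cc) else 0
  tibble::tibble(a = a, b = b, c = cc,
                 beta_sim = bsim, beta_sne = bsor - bsim, beta_sor = bsor)
}

# full pairwise beta_sim matrix over the cells of B (cells x edges logical)
beta_sim_matrix <- function(B, len) {
  Bl <- B * rep(len, each = nrow(B))
  a <- Bl %*% t(B)               # shared length
  tot <- as.vector(B %*% len)
  bmat <- outer(tot, rep(1, length(tot))) - a   # b_ij = tot_i - a_ij
  cmat <- t(bmat)
  mn <- pmin(bmat, cmat)
  den <- a + mn
  out <- ifelse(den > 0, mn / den, 0)
  diag(out) <- 0
  out
}

#' Neighborhood turnover surface
#'
#' Per-cell phylogenetic turnover: the mean pairwise `beta_sim` between the
#' focal cell and its non-empty neighbors within a square moving window
#' (queen adjacency at `window = 1`, i.e. a 3x3 window). Empty cells and
#' cells with no non-empty neighbor are no-data (`NA`).
#'
#' @param grid occurrence tibble.
#' @param tree `phylo`.
#' @param window neighborhood radius in cells (Chebyshev distance).
#' @return a tibble keyed by `cell`: `beta_sim`, `n_neighbors`.
#' @export
beta_map <- function(grid, tree, window = 1) {
  validate_tree(tree)
  te <- tip_edge_matrix(tree)
  m <- occ_matrix(grid)
  B <- cell_edge_incidence(m, te)
  nonempty <- rowSums(m) > 0
  bsim <- beta_sim_matrix(B, te$lengths)
  out <- rep(NA_real_, nrow(m)); nn <- integer(nrow(m))
  for (i in which(nonempty)) {
    nb <- which(abs(grid$row - grid$row[i]) <= window &
                abs(grid$col - grid$col[i]) <= window & nonempty)
    nb <- nb[nb != i]
    nn[i] <- length(nb)
    if (length(nb)) out[i] <- mean(bsim[i, nb])
  }
  tibble::tibble(cell = grid$cell, beta_sim = out, n_neighbors = nn)
}

#' Current-to-future change surfaces
#'
#' Per-cell differences between a future and the current slice, all signed
#' future minus current so that negative values are losses: `d_sr` (species
#' richness change), `d_pd` (change in the standardized effect size of PD,
#' from the two significance surfaces), `d_eg` (change in mean niche breadth
#' of the present species, always using current niche-breadth values — traits
#' are never re-estimated for the future; negative values mean a shift
#' toward specialists), and `d_bd` (change in the neighborhood `beta_sim`
#' surface; negative values mean biotic homogenization). Deltas are defined
#' only where both slices have data.
#'
#' @param current,future occurrence tibbles on the same grid with the same
#'   species universe.
#' @param tree `phylo`.
#' @param traits traits tibble with `species` and `niche_breadth`.
#' @param sig_current,sig_future optional [null_significance()] tibbles for
#'   the two slices (computed with the same `n_rand` and seed policy); when
#'   omitted, `d_pd` is `NA`.
#' @param window neighborhood radius for the turnover surface.
#' @return a tibble keyed by `cell`: `sr_current`, `sr_future`, `d_sr`,
#'   `d_pd`, `d_eg`, `d_bd`.
#' @export
compute_deltas <- function(current, future, tree, traits,
                           sig_current = NULL, sig_future = NULL, window = 1) {
  assert_same_cells(current, future, "current and future slices")
  if (!setequal(occ_species(current), occ_species(future))) {
    abort("current and future slices must share the same species universe")
  }
  mc <- occ_matrix(current)
  mf <- occ_matrix(future)[, colnames(mc), drop = FALSE]
  sr_c <- unname(rowSums(mc)); sr_f <- unname(rowSums(mf))
  both <- sr_c > 0 & sr_f > 0

  nb <- traits$niche_breadth[match(colnames(mc), traits$species)]
  if (anyNA(nb)) abort("traits are missing niche breadth for some species")
  eg <- function(m, sr) ifelse(sr > 0, as.vector(m %*% nb) / pmax(sr, 1), NA_real_)

  bd_c <- beta_map(current, tree, window)$beta_sim
  bd_f <- beta_map(future, tree, window)$beta_sim

  d_pd <- rep(NA_real_, length(sr_c))
  if (!is.null(sig_current) && !is.null(sig_future)) {
    assert_same_cells(current, sig_current, "grid and current significance")
    assert_same_cells(current, sig_future, "grid and future significance")
    d_pd <- sig_future$ses_pd - sig_current$ses_pd
  }
  mask <- function(x) ifelse(both, x, NA_real_)
  tibble::tibble(
    cell = current$cell,
    sr_current = as.integer(sr_c), sr_future = as.integer(sr_f),
    d_sr = ifelse(both, as.integer(sr_f - sr_c), NA_integer_),
    d_pd = mask(d_pd),
    d_eg = mask(eg(mf, sr_f) - eg(mc, sr_c)),
    d_bd = mask(bd_f - bd_c)
  )
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; undefined (error) when
#' `n <= k + 1`.
#'
#' @param log_lik model log-likelihood.
#' @param k number of estimated parameters (including the error variance).
#' @param n sample size.
#' @return the AICc value.
#' @export
aicc <- function(log_lik, k, n) {
  if (n <= k + 1) abort("insufficient data: AICc undefined for n <= k + 1")
  -2 * log_lik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc model selection for drivers of a change surface
#'
#' Fits additive polynomial-basis linear models (default cubic basis per
#' term) for every subset of the candidate predictors — including the
#' intercept-only model — and ranks them by AICc. This is an unpenalized
#' additive-model stand-in for smoothing-spline regression that keeps the
#' selection logic (AICc ranking, deviance explained) intact.
#'
#' @param data tibble containing the response and predictor columns; rows
#'   with missing values in any used column are dropped.
#' @param response name of the response column.
#' @param predictors character vector of candidate predictor columns.
#' @param basis_degree polynomial degree per predictor (1 = linear).
#' @return a tibble ranked by AICc: `terms`, `k`, `log_lik`, `aicc`,
#'   `d_aicc`, `deviance_explained`; the best fit (an `lm`) is attached as
#'   attribute `best_fit`.
#' @export
driver_model_selection <- function(data, response,
                                   predictors = c("d_eg", "d_pd", "d_sr", "elevation"),
                                   basis_degree = 3) {
  stopifnot(length(predictors) >= 1)
  cols <- c(response, predictors)
  miss <- setdiff(cols, names(data))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  d <- data[complete.cases(data[, cols]), cols]
  n <- nrow(d)

  subsets <- c(list(character(0)),
               unlist(lapply(seq_along(predictors), function(s) {
                 asplit(combn(predictors, s), 2)
               }), recursive = FALSE))
  fits <- lapply(subsets, function(ss) {
    rhs <- if (length(ss) == 0) "1" else {
      paste(sprintf("poly(%s, %d)", ss, basis_degree), collapse = " + ")
    }
    fit <- lm(stats::as.formula(paste(response, "~", rhs)), data = d)
    k <- length(coef(fit)) + 1   # + error variance
    ll <- as.numeric(logLik(fit))
    tibble::tibble(
      terms = if (length(ss)) paste(ss, collapse = "+") else "(intercept)",
      k = k, log_lik = ll, aicc = aicc(ll, k, n),
      deviance_explained = summary(fit)$r.squared,
      fit = list(fit)
    )
  })
  tab <- dplyr::bind_rows(fits)
  tab <- dplyr::arrange(tab, .data$aicc)
  tab$d_aicc <- tab$aicc - tab$aicc[1]
  best <- tab$fit[[1]]
  tab <- dplyr::select(tab, "terms", "k", "log_lik", "aicc", "d_aicc",
                       "deviance_explained")
  attr(tab, "best_fit") <- best
  tab
}
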