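#' Variance-inflation screen for multicollinearity
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on the others.
#' Perfectly collinear predictors get an infinite VIF and are flagged, as is
#' anything at or above `threshold` (default 2, a deliberately strict
#' screen).
#'
#' @param data tibble of per-cell predictors.
#' @param predictors columns to screen; default all numeric columns except
#'   the geometry ones.
#' @param threshold flagging threshold.
#' @return a tibble: `predictor`, `vif`, `flagged`.
#' @export
vif_screen <- function(data, predictors = NULL, threshold = 2) {
  predictors <- predictors %||%
    setdiff(names(data)[vapply(data, is.numeric, TRUE)], geometry_cols)
  if (length(predictors) < 2) abort("need at least 2 predictors")
  d <- data[, predictors]
  if (nrow(d) <= length(predictors) + 1) abort("need n > predictors + 1")
  vifs <- vapply(predictors, function(p) {
    r2 <- summary(lm(stats::reformulate(setdiff(predictors, p), p), data = d))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  tibble::tibble(predictor = predictors, vif = unname(vifs),
                 flagged = !is.finite(vifs) | vifs >= threshold)
}

#' Row-standardized k-nearest-neighbor spatial weights
#'
#' Neighbors by Euclidean distance between cell centers, distance ties
#' broken toward the lower cell index; each of the k neighbors gets weight
#' 1/k, so rows sum to one. The eigenvalues of the weight matrix are
#' computed once here and reused by every SAR fit on these weights.
#'
#' @param coords tibble with `cell`, `x`, `y`.
#' @param k neighbors per cell (1 <= k < n).
#' @return a `knn_weights` object: `W` (dense matrix), `idx` (n x k neighbor
#'   indices), `k`, `cells`, `eigenvalues`.
#' @export
build_knn_weights <- function(coords, k) {
  n <- nrow(coords)
  if (k < 1 || k >= n) abort("config error: k must satisfy 1 <= k < n")
  xy <- as.matrix(coords[, c("x", "y")])
  dm <- as.matrix(dist(xy))
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))     # distance, then index (tie rule)
    ord <- ord[ord != i]
    idx[i, ] <- ord[seq_len(k)]
  }
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, idx[i, ]] <- 1 / k
  structure(list(W = W, idx = idx, k = as.integer(k), cells = coords$cell,
                 eigenvalues = eigen(W, only.values = TRUE)$values),
            class = "knn_weights")
}

standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardize a constant variable")
  (x - mean(x)) / s
}

#' Spatial autoregressive error model by profile maximum likelihood
#'
#' Fits `y = X beta + u`, `u = lambda W u + eps`, `eps ~ iid N(0, sigma^2)`.
#' The response and predictors are standardized internally (mean 0, sd 1) —
#' enforced, not assumed — so coefficients are comparable effect sizes.
#' `lambda` is profiled over (-0.999, 0.999) with the exact log-determinant
#' `log |I - lambda W|` from the precomputed eigenvalues of W; `beta` and
#' `sigma^2` come from generalized least squares at the profile optimum.
#' Reports log-likelihood, AICc (parameter count includes `beta`, `lambda`
#' and `sigma^2`) and the Nagelkerke pseudo-R-squared
#' `GR2 = (1 - exp(-(2/n)(l - l0))) / (1 - exp((2/n) l0))` against the
#' intercept-only non-spatial null.
#'
#' @param data tibble holding response and predictors per cell.
#' @param response response column name.
#' @param predictors character vector of predictor column names.
#' @param weights a [build_knn_weights()] object on the same cells.
#' @param fixed_lambda fix the spatial error parameter instead of profiling
#'   it (`fixed_lambda = 0` reduces the fit to ordinary least squares on the
#'   standardized data); `NULL` (default) estimates it.
#' @return a `sar_error_fit` object; see [tidy.sar_error_fit()] and
#'   [glance.sar_error_fit()].
#' @export
sar_error_fit <- function(data, response, predictors, weights,
                          fixed_lambda = NULL) {
  n <- nrow(data)
  if (n != length(weights$cells)) abort("data and weights differ in size")
  if (n <= length(predictors) + 2) abort("need n > predictors + 2")
  y <- standardize(data[[response]])
  X <- cbind(`(Intercept)` = 1,
             vapply(predictors, function(p) standardize(data[[p]]), numeric(n)))
  W <- weights$W
  ev <- weights$eigenvalues
  Wy <- W %*% y; WX <- W %*% X

  prof <- function(lambda) {
    Ay <- y - lambda * Wy
    AX <- X - lambda * WX
    fit <- lm.fit(AX, Ay)
    s2 <- sum(fit$residuals^2) / n
    ldet <- Re(sum(log(1 - lambda * ev)))
    ldet - n / 2 * log(s2)
  }
  if (is.null(fixed_lambda)) {
    opt <- optimize(prof, interval = c(-0.999, 0.999), maximum = TRUE, tol = 1e-8)
    lambda <- opt$maximum
  } else {
    lambda <- fixed_lambda
  }
  boundary <- is.null(fixed_lambda) && abs(lambda) > 0.985
  if (boundary) warn("lambda estimate at the search boundary; interpret with care")

  Ay <- y - lambda * Wy
  AX <- X - lambda * WX
  fit <- lm.fit(AX, Ay)
  beta <- fit$coefficients
  eps <- fit$residuals
  s2 <- sum(eps^2) / n
  ldet <- Re(sum(log(1 - lambda * ev)))
  ll <- -n / 2 * (log(2 * pi) + log(s2) + 1) + ldet
  vcov_beta <- s2 * solve(crossprod(AX))
  se <- sqrt(diag(vcov_beta))

  k <- ncol(X) + 2   # beta (incl. intercept), lambda, sigma^2
  s2_0 <- mean((y - mean(y))^2)
  ll0 <- -n / 2 * (log(2 * pi) + log(s2_0) + 1)
  gr2 <- (1 - exp(-(2 / n) * (ll - ll0))) / (1 - exp((2 / n) * ll0))

  structure(list(
    coefficients = tibble::tibble(term = colnames(X), estimate = unname(beta),
                                  std_error = unname(se)),
    lambda = lambda, sigma2 = s2, log_lik = ll, aicc = aicc(ll, k, n),
    gr2 = gr2, n = n, k = k, predictors = predictors, response = response,
    residuals = as.vector(y - X %*% beta),   # spatially structured residual u
    innovations = as.vector(eps),
    boundary = boundary, null_log_lik = ll0
  ), class = "sar_error_fit")
}

#' @export
print.sar_error_fit <- function(x, ...) {
  cat(sprintf("<sar_error_fit> %s ~ %s\n", x$response,
              paste(x$predictors, collapse = " + ")))
  cat(sprintf("  lambda = %.3f, logLik = %.2f, AICc = %.2f, GR2 = %.3f, n = %d\n",
              x$lambda, x$log_lik, x$aicc, x$gr2, x$n))
  print(x$coefficients)
  invisible(x)
}

#' Tidy a SAR error fit
#' @param x a `sar_error_fit`.
#' @param ... unused.
#' @return coefficient tibble: `term`, `estimate`, `std_error`.
#' @method tidy sar_error_fit
#' @export
tidy.sar_error_fit <- function(x, ...) x$coefficients

#' One-row summary of a SAR error fit
#' @param x a `sar_error_fit`.
#' @param ... unused.
#' @return tibble: `lambda`, `sigma2`, `log_lik`, `aicc`, `gr2`, `n`, `k`.
#' @method glance sar_error_fit
#' @export
glance.sar_error_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, sigma2 = x$sigma2, log_lik = x$log_lik,
                 aicc = x$aicc, gr2 = x$gr2, n = x$n, k = x$k)
}

#' Joint neighbor-count and predictor-subset selection by AICc
#'
#' Fits a SAR error model for every combination of k (neighbors) in
#' `k_range` and every non-empty predictor subset, and ranks candidates by
#' AICc. Individual fit failures are recorded, not fatal (unless all fail).
#'
#' @param data tibble with response and predictors.
#' @param response response column.
#' @param predictors candidate predictor columns.
#' @param coords tibble with `cell`, `x`, `y` (same rows as `data`).
#' @param k_range candidate neighbor counts.
#' @return ranking tibble (`k_neighbors`, `terms`, `lambda`, `log_lik`,
#'   `aicc`, `d_aicc`, `gr2`, `error`); best fit attached as attribute
#'   `best_fit`.
#' @export
select_sar_model <- function(data, response, predictors, coords, k_range = 4:8) {
  stopifnot(length(predictors) >= 1)
  subsets <- unlist(lapply(seq_along(predictors), function(s) {
    asplit(combn(predictors, s), 2)
  }), recursive = FALSE)
  rows <- list(); fits <- list()
  for (k in k_range) {
    w <- build_knn_weights(coords, k)
    for (ss in subsets) {
      res <- tryCatch(sar_error_fit(data, response, as.character(ss), w),
                      error = function(e) conditionMessage(e))
      key <- sprintf("k%d:%s", k, paste(ss, collapse = "+"))
      if (inherits(res, "sar_error_fit")) {
        fits[[key]] <- res
        rows[[key]] <- tibble::tibble(
          k_neighbors = k, terms = paste(ss, collapse = "+"),
          lambda = res$lambda, log_lik = res$log_lik, aicc = res$aicc,
          gr2 = res$gr2, error = NA_character_)
      } else {
        rows[[key]] <- tibble::tibble(
          k_neighbors = k, terms = paste(ss, collapse = "+"),
          lambda = NA_real_, log_lik = NA_real_, aicc = NA_real_,
          gr2 = NA_real_, error = res)
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  if (all(is.na(tab$aicc))) abort("all candidate fits failed")
  tab <- dplyr::arrange(tab, .data$aicc)
  tab$d_aicc <- tab$aicc - tab$aicc[1]
  best_key <- sprintf("k%d:%s", tab$k_neighbors[1], tab$terms[1])
  attr(tab, "best_fit") <- fits[[best_key]]
  tab
}

#' Moran correlogram of residual spatial autocorrelation
#'
#' Moran's I of `values` within equal-width distance classes, with the
#' permutation-free normal approximation of [ape::Moran.I()] per class
#' (expectation -1/(n-1)). Empty classes are dropped with a note.
#'
#' @param values per-cell values (e.g. model residuals).
#' @param coords tibble with `x`, `y` (same order).
#' @param n_lags number of distance classes.
#' @return a tibble: `lag`, `d_lo`, `d_hi`, `midpoint`, `n_pairs`,
#'   `moran_i`, `expected`, `sd`, `p_value`.
#' @export
moran_correlogram <- function(values, coords, n_lags = 10) {
  if (n_lags < 1) abort("n_lags must be >= 1")
  n <- length(values)
  dm <- as.matrix(dist(as.matrix(coords[, c("x", "y")])))
  pos <- dm[upper.tri(dm)]
  breaks <- seq(min(pos), max(pos), length.out = n_lags + 1)
  breaks[1] <- breaks[1] - 1e-9
  out <- list()
  for (l in seq_len(n_lags)) {
    wb <- (dm > breaks[l] & dm <= breaks[l + 1]) * 1
    diag(wb) <- 0
    n_pairs <- sum(wb) / 2
    if (n_pairs == 0 || any(rowSums(wb) == 0)) {
      # Moran's I undefined for isolated cells in this class
      if (n_pairs == 0) { message(sprintf("distance class %d empty; dropped", l)); next }
    }
    keep <- rowSums(wb) > 0
    if (sum(keep) < 3) { message(sprintf("distance class %d too sparse; dropped", l)); next }
    mi <- suppressWarnings(ape::Moran.I(values[keep], wb[keep, keep]))
    # a class containing every pair pins I to its expectation; the normal
    # variance is then undefined and reported as NA
    if (!is.finite(mi$sd)) { mi$sd <- NA_real_; mi$p.value <- NA_real_ }
    out[[length(out) + 1]] <- tibble::tibble(
      lag = l, d_lo = max(breaks[l], 0), d_hi = breaks[l + 1],
      midpoint = (max(breaks[l], 0) + breaks[l + 1]) / 2,
      n_pairs = n_pairs, moran_i = mi$observed, expected = mi$expected,
      sd = mi$sd, p_value = mi$p.value)
  }
  dplyr::bind_rows(out)
}
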