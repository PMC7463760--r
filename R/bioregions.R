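#' Pairwise phylogenetic turnover dissimilarity between all non-empty cells
#'
#' @param grid occurrence tibble.
#' @param tree `phylo`.
#' @return a symmetric `beta_sim` matrix with cell ids as dimnames (empty
#'   cells excluded).
#' @export
beta_dissimilarity <- function(grid, tree) {
  validate_tree(tree)
  te <- tip_edge_matrix(tree)
  m <- occ_matrix(grid)
  keep <- rowSums(m) > 0
  B <- cell_edge_incidence(m[keep, , drop = FALSE], te)
  d <- beta_sim_matrix(B, te$lengths)
  dimnames(d) <- list(grid$cell[keep], grid$cell[keep])
  d
}

#' Principal-coordinates embedding of compositional turnover
#'
#' Classical multidimensional scaling (PCoA) of the pairwise phylogenetic
#' `beta_sim` matrix, giving each non-empty cell coordinates in a
#' compositional-turnover space suitable for centroid-based clustering. By
#' default axes with non-positive eigenvalues are dropped without
#' correction, and the variance represented by the retained axes plus the
#' discarded negative magnitude are reported as attributes. Min-based
#' turnover is distinctly non-metric, so the uncorrected embedding is lossy;
#' `correction = "cailliez"` (or `"lingoes"`) applies the usual additive
#' constant, after which embedding distances reproduce the (shifted)
#' dissimilarities essentially exactly.
#'
#' @param grid occurrence tibble.
#' @param tree `phylo`.
#' @param n_axes maximum number of axes to retain (>= 1).
#' @param correction `"none"` (default), `"cailliez"` or `"lingoes"`.
#' @return a tibble: `cell`, `axis1`..`axisK`; attributes
#'   `variance_represented` and `negative_eigenvalue_fraction`.
#' @export
compositional_embedding <- function(grid, tree, n_axes = 10,
                                    correction = c("none", "cailliez", "lingoes")) {
  correction <- match.arg(correction)
  if (n_axes < 1) abort("n_axes must be >= 1")
  d <- beta_dissimilarity(grid, tree)
  if (nrow(d) < 3) abort("need at least 3 non-empty cells")
  if (all(d == 0)) abort("zero dissimilarity everywhere: cells are compositionally identical")
  k_try <- min(n_axes, nrow(d) - 1)
  if (correction == "none") {
    mds <- suppressWarnings(cmdscale(as.dist(d), k = k_try, eig = TRUE))
    eig <- mds$eig
    pos <- which(eig > 1e-12)
    k_keep <- min(k_try, length(pos), ncol(mds$points))
    pts <- mds$points[, seq_len(k_keep), drop = FALSE]
    var_rep <- sum(eig[seq_len(k_keep)]) / sum(eig[pos])
    neg_frac <- sum(abs(eig[eig < 0])) / sum(abs(eig))
  } else {
    pc <- ape::pcoa(as.dist(d), correction = correction)
    vec <- if (!is.null(pc$vectors.cor)) pc$vectors.cor else pc$vectors
    k_keep <- min(k_try, ncol(vec))
    pts <- vec[, seq_len(k_keep), drop = FALSE]
    ev <- if (!is.null(pc$values$Corr_eig)) pc$values$Corr_eig else pc$values$Eigenvalues
    ev <- pmax(ev, 0)
    var_rep <- sum(ev[seq_len(k_keep)]) / sum(ev)
    neg_frac <- 0
  }
  colnames(pts) <- paste0("axis", seq_len(k_keep))
  out <- dplyr::bind_cols(tibble::tibble(cell = rownames(d)), tibble::as_tibble(pts))
  attr(out, "variance_represented") <- var_rep
  attr(out, "negative_eigenvalue_fraction") <- neg_frac
  out
}

new_regionalization <- function(cells, labels, k, algorithm, sil, extra = list()) {
  out <- tibble::tibble(cell = cells, cluster = as.integer(labels))
  attr(out, "k") <- as.integer(k)
  attr(out, "algorithm") <- algorithm
  attr(out, "mean_silhouette") <- sil
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("regionalization", class(out))
  out
}

#' @export
print.regionalization <- function(x, ...) {
  cat(sprintf("<regionalization> %s, k = %d, mean silhouette = %.3f, %d cells\n",
              attr(x, "algorithm"), attr(x, "k"), attr(x, "mean_silhouette"), nrow(x)))
  NextMethod()
}

mean_sil <- function(labels, d) {
  if (length(unique(labels)) < 2) return(NA_real_)
  mean(cluster::silhouette(labels, dmatrix = as.matrix(d))[, "sil_width"])
}

#' K-means bioregionalization of embedded cells
#'
#' Multi-start Lloyd iterations on the PCoA coordinates; the best start by
#' within-cluster sum of squares is kept. Deterministic for a fixed seed.
#'
#' @param coords tibble from [compositional_embedding()].
#' @param k number of regions (2 <= k <= cells - 1).
#' @param seed integer seed.
#' @param n_starts number of random initializations.
#' @return a `regionalization` tibble (`cell`, `cluster`) with attributes
#'   `k`, `algorithm`, `mean_silhouette`, `wcss`.
#' @export
kmeans_regionalize <- function(coords, k, seed = 1, n_starts = 10) {
  x <- as.matrix(coords[, grep("^axis", names(coords)), drop = FALSE])
  if (k < 2 || k > nrow(x) - 1) abort("config error: k must be in [2, cells - 1]")
  km <- withr::with_seed(seed, withCallingHandlers(
    kmeans(x, centers = k, nstart = n_starts, iter.max = 200,
           algorithm = "Lloyd"),
    # Lloyd restarts can land on empty clusters; the multi-start picks the
    # best non-degenerate solution, so these warnings are noise
    warning = function(w) {
      if (grepl("empty cluster", conditionMessage(w))) invokeRestart("muffleWarning")
    }))
  sil <- mean_sil(km$cluster, dist(x))
  new_regionalization(coords$cell, km$cluster, k, "kmeans", sil,
                      list(wcss = km$tot.withinss))
}

#' CLARA bioregionalization (PAM on subsamples)
#'
#' Clustering-for-large-applications: PAM (build + swap) is run on each of
#' `n_samples` random subsamples; each candidate medoid set is scored by the
#' total dissimilarity of all cells to their nearest medoid, and the best
#' set assigns every cell. When the sample size reaches the full data the
#' result equals plain PAM.
#'
#' @param x either a symmetric dissimilarity matrix with cell dimnames (e.g.
#'   [beta_dissimilarity()]) or a coordinate tibble from
#'   [compositional_embedding()] (Euclidean distances are used).
#' @param k number of regions (>= 2).
#' @param seed integer seed.
#' @param n_samples number of subsamples.
#' @param sample_size cells per subsample; default `min(n, 40 + 2k)`.
#' @return a `regionalization` tibble with attributes `k`, `algorithm`,
#'   `mean_silhouette`, `total_dissimilarity`, `medoids`.
#' @export
clara_regionalize <- function(x, k, seed = 1, n_samples = 5, sample_size = NULL) {
  if (is.data.frame(x)) {
    cells <- x$cell
    dm <- as.matrix(dist(as.matrix(x[, grep("^axis", names(x)), drop = FALSE])))
    dimnames(dm) <- list(cells, cells)
  } else {
    dm <- as.matrix(x); cells <- rownames(dm)
  }
  n <- nrow(dm)
  if (k < 2) abort("config error: k must be >= 2")
  sample_size <- sample_size %||% min(n, 40 + 2 * k)
  if (sample_size < k) abort("config error: sample_size must be >= k")
  sample_size <- min(sample_size, n)

  withr::with_seed(seed, {
    best_cost <- Inf; best_medoids <- NULL
    for (s in seq_len(n_samples)) {
      idx <- if (sample_size >= n) seq_len(n) else sort(sample(n, sample_size))
      pm <- cluster::pam(as.dist(dm[idx, idx]), k = k, diss = TRUE)
      medoids <- idx[pm$id.med]
      cost <- sum(apply(dm[, medoids, drop = FALSE], 1, min))
      if (cost < best_cost) { best_cost <- cost; best_medoids <- medoids }
      if (sample_size >= n) break
    }
  })
  labels <- apply(dm[, best_medoids, drop = FALSE], 1, which.min)
  sil <- mean_sil(labels, dm)
  new_regionalization(cells, labels, k, "clara", sil,
                      list(total_dissimilarity = best_cost,
                           medoids = cells[best_medoids]))
}

#' Silhouette-optimal number of regions
#'
#' Sweeps `k_range`, clusters with the chosen algorithm, and keeps the k
#' with the highest mean silhouette width (ties broken toward smaller k).
#' When even the best mean silhouette is at or below 0.5 the result carries
#' a `weak_structure` flag, following the usual silhouette reading (widths
#' of 0.5 and below indicate weak, possibly artificial structure; note that
#' k-means on pure i.i.d. noise already reaches widths around 0.4): the
#' landscape shows no convincing compositional sectors and the partition
#' should be read cautiously.
#'
#' @param x coordinates tibble (kmeans or clara) or dissimilarity matrix
#'   (clara only).
#' @param k_range integer vector of candidate region counts.
#' @param algorithm `"kmeans"` or `"clara"`.
#' @param seed integer seed.
#' @param ... passed to the underlying regionalizer.
#' @return the best `regionalization`, with attributes `sweep` (tibble of k
#'   and mean silhouette) and `weak_structure`.
#' @export
silhouette_optimal_k <- function(x, k_range = 2:20,
                                 algorithm = c("kmeans", "clara"),
                                 seed = 1, ...) {
  algorithm <- match.arg(algorithm)
  if (length(k_range) == 0) abort("config error: empty k_range")
  n <- if (is.data.frame(x)) nrow(x) else nrow(as.matrix(x))
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) abort("config error: k_range outside [2, cells - 1]")
  fits <- lapply(k_range, function(k) {
    if (algorithm == "kmeans") kmeans_regionalize(x, k, seed = seed, ...)
    else clara_regionalize(x, k, seed = seed, ...)
  })
  sils <- vapply(fits, function(f) attr(f, "mean_silhouette"), 0)
  best <- which.max(sils)   # first maximum -> smallest k on ties
  out <- fits[[best]]
  attr(out, "sweep") <- tibble::tibble(k = k_range, mean_silhouette = sils)
  attr(out, "weak_structure") <- max(sils, na.rm = TRUE) <= 0.5
  out
}

#' V-measure association between two regionalizations
#'
#' Information-theoretic comparison of two partitions of the same cells:
#' homogeneity `h = 1 - H(A|B)/H(A)` (1 when `H(A) = 0`), completeness
#' `c = 1 - H(B|A)/H(B)` (1 when `H(B) = 0`), and their harmonic mean V.
#' Invariant to label permutation; cells are weighted equally (equal-area
#' grid).
#'
#' @param reg_a,reg_b `regionalization` tibbles (or any tibbles with `cell`
#'   and `cluster`) over the same cell set.
#' @return a one-row tibble: `homogeneity`, `completeness`, `v_measure`,
#'   `k_a`, `k_b`.
#' @export
v_measure <- function(reg_a, reg_b) {
  if (!setequal(reg_a$cell, reg_b$cell)) abort("alignment error: cell sets differ")
  b <- reg_b$cluster[match(reg_a$cell, reg_b$cell)]
  a <- reg_a$cluster
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h_a <- ent(pa); h_b <- ent(pb)
  h_ab <- -sum(tab[tab > 0] * log(tab[tab > 0]))   # joint entropy
  h_a_given_b <- h_ab - h_b
  h_b_given_a <- h_ab - h_a
  h <- if (h_a == 0) 1 else 1 - h_a_given_b / h_a
  cmp <- if (h_b == 0) 1 else 1 - h_b_given_a / h_b
  v <- if (h + cmp > 0) 2 * h * cmp / (h + cmp) else 0
  tibble::tibble(homogeneity = h, completeness = cmp, v_measure = v,
                 k_a = length(unique(a)), k_b = length(unique(b)))
}
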