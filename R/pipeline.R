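#' Overlap of endemism centers with a mask
#'
#' For each CANAPE category, the percentage of its cells falling inside a
#' boolean mask (protected areas, climatic refugia, ...). Categories with no
#' cells are reported as `NA` (undefined), not 0. Percentages are emitted at
#' full precision; round at report time (the package's reporting policy is
#' one decimal, round-half-to-even, which is R's `round()`).
#'
#' @param canape tibble from [canape_classify()].
#' @param mask tibble with `cell` and the boolean mask column.
#' @param mask_col name of the mask column (e.g. `"protected"`).
#' @return a tibble: `category`, `n_cells`, `n_inside`, `pct_inside`.
#' @export
overlap_percentages <- function(canape, mask, mask_col = "protected") {
  if (!setequal(canape$cell, mask$cell)) abort("alignment error: cell sets differ")
  inside <- mask[[mask_col]][match(canape$cell, mask$cell)]
  purrr::map_dfr(canape_levels, function(lv) {
    sel <- canape$category == lv
    n <- sum(sel)
    tibble::tibble(category = lv, n_cells = n, n_inside = sum(sel & inside),
                   pct_inside = if (n > 0) 100 * sum(sel & inside) / n else NA_real_)
  }) |> dplyr::mutate(category = factor(.data$category, levels = canape_levels))
}

#' Run the full endemism pipeline on a synthetic landscape
#'
#' Orchestrates, in dependency order: landscape simulation, metric surfaces,
#' randomization nulls and CANAPE for both time slices, change surfaces and
#' their driver selection, bioregionalization of both slices with the
#' V-measure between them, SAR driver models of PE and RPE, and
#' protected-area/refugia overlaps. Stages can be toggled; later stages that
#' need a disabled stage are skipped. Fully reproducible from the config
#' seed.
#'
#' @param config a [landscape_config()].
#' @param n_rand randomizations for the null model.
#' @param stages character subset of
#'   `c("canape", "deltas", "bioregions", "sar")` (metrics always run).
#' @param window neighborhood radius for turnover surfaces.
#' @param k_range candidate region counts for the silhouette sweep.
#' @param sar_k_range candidate neighbor counts for SAR selection.
#' @param out_dir optional directory; when given, every table is written as
#'   CSV/TSV plus a `manifest.json` with md5 checksums and provenance.
#' @return a `run_report` list; see the fields in the examples of the
#'   package vignette.
#' @export
run_pipeline <- function(config = landscape_config(),
                         n_rand = 199,
                         stages = c("canape", "deltas", "bioregions", "sar"),
                         window = 1, k_range = 2:8, sar_k_range = c(4, 6, 8),
                         out_dir = NULL) {
  t0 <- Sys.time()
  timings <- list()
  tic <- function() Sys.time()
  toc <- function(start, name) timings[[name]] <<- as.numeric(Sys.time() - start, units = "secs")

  s <- tic()
  land <- simulate_landscape(config)
  toc(s, "simulate")

  s <- tic()
  metrics_current <- phylo_metrics(land$current, land$tree)
  metrics_future <- phylo_metrics(land$future, land$tree)
  toc(s, "metrics")

  report <- list(
    config = config,
    landscape = land,
    metrics = list(current = metrics_current, future = metrics_future),
    extinct = extinct_species(land$current, land$future),
    provenance = list(
      seed = config$seed,
      config_hash = rlang::hash(unclass(config)),
      n_rand = n_rand,
      r_version = as.character(getRversion()),
      timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
    )
  )

  sig <- list(current = NULL, future = NULL)
  if ("canape" %in% stages) {
    s <- tic()
    sig$current <- null_significance(land$current, land$tree, n_rand, config$seed + 101L)
    sig$future <- null_significance(land$future, land$tree, n_rand, config$seed + 102L)
    cn <- canape_classify(sig$current)
    cf <- canape_classify(sig$future)
    report$significance <- sig
    report$canape <- list(current = cn, future = cf)
    report$canape_counts <- list(current = canape_counts(cn, land$covariates),
                                 future = canape_counts(cf, land$covariates))
    report$elevation_test <- tryCatch(center_elevation_test(cn, land$covariates),
                                      error = function(e) NULL)
    report$overlap <- list(
      current = list(
        protected = overlap_percentages(cn, land$masks, "protected"),
        refugia = overlap_percentages(cn, land$masks, "refugia")),
      future = list(
        protected = overlap_percentages(cf, land$masks, "protected"),
        refugia = overlap_percentages(cf, land$masks, "refugia")))
    toc(s, "canape")
  }

  if ("deltas" %in% stages) {
    s <- tic()
    deltas <- compute_deltas(land$current, land$future, land$tree, land$traits,
                             sig$current, sig$future, window = window)
    report$deltas <- deltas
    dd <- dplyr::inner_join(deltas, land$covariates[, c("cell", "elevation")], by = "cell")
    report$driver_selection <- tryCatch(
      driver_model_selection(dd, "d_bd",
                             predictors = intersect(c("d_eg", "d_pd", "d_sr", "elevation"),
                                                    names(dd)[colSums(!is.na(dd)) > 0])),
      error = function(e) NULL)
    report$delta_by_elevation <- dd |>
      dplyr::mutate(elev_quartile = dplyr::ntile(.data$elevation, 4)) |>
      dplyr::group_by(.data$elev_quartile) |>
      dplyr::summarise(dplyr::across(c("d_sr", "d_pd", "d_eg", "d_bd"),
                                     ~ mean(.x, na.rm = TRUE)), .groups = "drop")
    toc(s, "deltas")
  }

  if ("bioregions" %in% stages) {
    s <- tic()
    emb_c <- compositional_embedding(land$current, land$tree)
    emb_f <- compositional_embedding(land$future, land$tree)
    reg_c <- silhouette_optimal_k(emb_c, k_range, "kmeans", seed = config$seed + 201L)
    reg_f <- silhouette_optimal_k(emb_f, k_range, "kmeans", seed = config$seed + 201L)
    shared <- intersect(reg_c$cell, reg_f$cell)
    report$bioregions <- list(
      current = reg_c, future = reg_f,
      v_measure = v_measure(reg_c[reg_c$cell %in% shared, ],
                            reg_f[reg_f$cell %in% shared, ]))
    toc(s, "bioregions")
  }

  if ("sar" %in% stages) {
    s <- tic()
    sar_data <- dplyr::inner_join(metrics_current, land$covariates, by = "cell") |>
      dplyr::filter(.data$richness > 0)
    preds <- c("elevation", "ph", "diurnal_range", "stability")
    preds <- preds[vapply(preds, function(p) sd(sar_data[[p]]) > 0, TRUE)]
    report$vif <- vif_screen(sar_data, preds)
    coords <- sar_data[, c("cell", "x", "y")]
    report$sar <- list(
      pe = tryCatch(select_sar_model(sar_data, "pe", preds, coords, sar_k_range),
                    error = function(e) NULL),
      rpe = tryCatch(select_sar_model(sar_data, "rpe", preds, coords, sar_k_range),
                     error = function(e) NULL))
    toc(s, "sar")
  }

  report$timings <- timings
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d, %d x %d grid, %d species\n",
              x$config$seed, x$config$n_rows, x$config$n_cols, x$config$n_species))
  if (!is.null(x$canape_counts)) {
    cc <- x$canape_counts$current
    cat("  CANAPE (current): ",
        paste(sprintf("%s=%d", cc$category, cc$n_cells), collapse = ", "), "\n")
  }
  if (!is.null(x$bioregions)) {
    cat(sprintf("  bioregions: k_current=%d, k_future=%d, V=%.3f\n",
                attr(x$bioregions$current, "k"), attr(x$bioregions$future, "k"),
                x$bioregions$v_measure$v_measure))
  }
  if (!is.null(x$sar$pe)) {
    best <- x$sar$pe[1, ]
    cat(sprintf("  SAR best (PE): %s, k=%d, GR2=%.3f\n",
                best$terms, best$k_neighbors, best$gr2))
  }
  cat("  stages run:", paste(names(x$timings), collapse = ", "), "\n")
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes every tabular component as CSV (occurrences as TSV, the tree as
#' Newick) plus a `manifest.json` listing each file with its md5 checksum
#' and the run provenance (config hash, seed, versions).
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a list, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(df, p)
    files[[name]] <<- unname(tools::md5sum(p))
  }
  land <- report$landscape
  write_newick(land$tree, file.path(out_dir, "tree.nwk"))
  files[["tree.nwk"]] <- unname(tools::md5sum(file.path(out_dir, "tree.nwk")))
  write_occurrences(land$current, file.path(out_dir, "occurrences_current.tsv"))
  files[["occurrences_current.tsv"]] <-
    unname(tools::md5sum(file.path(out_dir, "occurrences_current.tsv")))
  write_occurrences(land$future, file.path(out_dir, "occurrences_future.tsv"))
  files[["occurrences_future.tsv"]] <-
    unname(tools::md5sum(file.path(out_dir, "occurrences_future.tsv")))
  put_csv(land$covariates, "covariates.csv")
  put_csv(land$traits, "traits.csv")
  put_csv(land$masks, "masks.csv")
  put_csv(report$metrics$current, "metrics_current.csv")
  put_csv(report$metrics$future, "metrics_future.csv")
  if (!is.null(report$significance)) {
    put_csv(report$significance$current, "significance_current.csv")
    put_csv(report$significance$future, "significance_future.csv")
    put_csv(report$canape$current, "canape_current.csv")
    put_csv(report$canape$future, "canape_future.csv")
    put_csv(report$canape_counts$current, "canape_counts_current.csv")
    put_csv(report$overlap$current$protected, "overlap_current_protected.csv")
    put_csv(report$overlap$current$refugia, "overlap_current_refugia.csv")
  }
  if (!is.null(report$deltas)) {
    put_csv(report$deltas, "deltas.csv")
    if (!is.null(report$driver_selection)) put_csv(report$driver_selection, "driver_selection.csv")
  }
  if (!is.null(report$bioregions)) {
    put_csv(report$bioregions$current, "bioregions_current.csv")
    put_csv(report$bioregions$future, "bioregions_future.csv")
    put_csv(report$bioregions$v_measure, "bioregions_v_measure.csv")
  }
  if (!is.null(report$sar$pe)) {
    put_csv(dplyr::select(report$sar$pe, -dplyr::any_of("error")), "sar_pe_ranking.csv")
  }
  manifest <- list(provenance = report$provenance,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Grid-size and tree-variant sensitivity of the CANAPE map
#'
#' Re-runs the CANAPE classification on coarsened grids (cells aggregated by
#' each factor with any-presence: a species occupies the super-cell if it
#' occupies any member cell) and on seeded random polytomy resolutions of
#' the tree, then reports agreement of each variant's category map with the
#' baseline as raw percent agreement and Cohen's kappa over comparable
#' (non-`no_data`) cells. Coarse categories are compared on the base grid by
#' assigning each base cell its super-cell's category.
#'
#' @param land a `landscape` (or list with `current`, `tree`, `covariates`).
#' @param factors aggregation factors (1 = baseline resolution).
#' @param n_tree_variants number of seeded polytomy resolutions to compare
#'   (no-ops on an already bifurcating tree).
#' @param n_rand randomizations per variant.
#' @param seed integer seed.
#' @return a tibble: `variant`, `type`, `factor`, `pct_agreement`, `kappa`.
#' @export
sensitivity_sweep <- function(land, factors = c(1, 2, 3, 4),
                              n_tree_variants = 2, n_rand = 99, seed = 1) {
  if (length(factors) + n_tree_variants < 2) abort("need at least 2 variants")
  base_sig <- null_significance(land$current, land$tree, n_rand, seed)
  base <- canape_classify(base_sig)
  base_cat <- setNames(as.character(base$category), base$cell)

  out <- list()
  for (f in factors) {
    if (f == 1) {
      cat_f <- base_cat[names(base_cat)]
    } else {
      agg <- aggregate_grid(land$current, f)
      sig_f <- null_significance(agg$grid, land$tree, n_rand, seed)
      cf <- canape_classify(sig_f)
      sup_cat <- setNames(as.character(cf$category), cf$cell)
      cat_f <- sup_cat[agg$membership[names(base_cat)]]
    }
    out[[length(out) + 1]] <- agreement_row(base_cat, cat_f,
                                            sprintf("grid_x%d", f), "cell_size", f)
  }
  for (v in seq_len(n_tree_variants)) {
    tv <- resolve_polytomies(land$tree, seed + v)
    sig_v <- null_significance(land$current, tv, n_rand, seed)
    cv <- canape_classify(sig_v)
    cat_v <- setNames(as.character(cv$category), cv$cell)[names(base_cat)]
    out[[length(out) + 1]] <- agreement_row(base_cat, cat_v,
                                            sprintf("tree_variant%d", v), "tree", NA_real_)
  }
  dplyr::bind_rows(out)
}

agreement_row <- function(a, b, variant, type, factor) {
  comparable <- a != "no_data" & b != "no_data" & !is.na(b)
  tibble::tibble(variant = variant, type = type, factor = factor,
                 n_comparable = sum(comparable),
                 pct_agreement = 100 * mean(a[comparable] == b[comparable]),
                 kappa = cohen_kappa(a[comparable], b[comparable]))
}

cohen_kappa <- function(a, b) {
  lv <- union(unique(a), unique(b))
  tab <- table(factor(a, lv), factor(b, lv)) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

#' Aggregate an occurrence grid to a coarser resolution
#'
#' Any-presence aggregation by an integer factor: a species occupies a
#' super-cell if it occupies any member base cell. Grids whose dimensions
#' the factor does not divide are padded with empty (no-data) cells.
#'
#' @param grid occurrence tibble.
#' @param factor integer aggregation factor (>= 1).
#' @return a list: `grid` (coarse occurrence tibble, cell size multiplied by
#'   `factor`) and `membership` (named character vector base cell ->
#'   super-cell).
#' @export
aggregate_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1)
  if (factor == 1) {
    return(list(grid = grid, membership = setNames(grid$cell, grid$cell)))
  }
  sup_row <- grid$row %/% factor
  sup_col <- grid$col %/% factor
  membership <- setNames(cell_id(sup_row, sup_col), grid$cell)
  m <- occ_matrix(grid)
  key <- membership[rownames(m)]
  agg <- rowsum(m, key) > 0
  storage.mode(agg) <- "integer"
  n_rows <- max(sup_row) + 1L; n_cols <- max(sup_col) + 1L
  cs <- if (nrow(grid) > 1) {
    dx <- sort(unique(grid$x)); if (length(dx) > 1) (dx[2] - dx[1]) * factor else 1000 * factor
  } else 1000 * factor
  geom <- grid_geometry(n_rows, n_cols, cs)
  full <- matrix(0L, nrow(geom), ncol(agg),
                 dimnames = list(geom$cell, colnames(agg)))
  full[rownames(agg), ] <- agg
  list(grid = as_occurrence_grid(full, geom), membership = membership)
}
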