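#' Read and write landscape configurations as YAML
#'
#' @param config a [landscape_config()].
#' @param path file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `landscape_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$planted_signals <- lapply(x$planted_signals, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  signals <- lapply(x$planted_signals, function(p) {
    planted_signal(p$rows, p$cols, p$signal_type, p$n_taxa, p$branch_scale)
  })
  landscape_config(
    n_rows = x$n_rows, n_cols = x$n_cols, n_species = x$n_species,
    seed = x$seed, elevation_relief = x$elevation_relief,
    range_size = x$range_size,
    niche_breadth_range = unlist(x$niche_breadth_range),
    future_shift = x$future_shift, planted_signals = signals,
    cell_size = x$cell_size
  )
}

#' Read/write per-cell covariates as CSV
#'
#' @param covariates tibble from [simulate_covariates()] (or compatible).
#' @param path file path.
#' @return the tibble (read) or the path, invisibly (write).
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
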