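#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] that enforces the contracts the
#' grid metrics rely on: at least two uniquely labelled tips, branch lengths
#' present and non-negative. Polytomies are accepted as-is; see
#' [resolve_polytomies()] for seeded random resolutions used in sensitivity
#' runs.
#'
#' @param source path to a Newick file, or a Newick string (recognised by the
#'   presence of a parenthesis).
#' @return an [ape::phylo] object.
#' @export
read_newick <- function(source) {
  tree <- if (grepl("(", source, fixed = TRUE)) {
    tryCatch(ape::read.tree(text = source),
             error = function(e) abort(paste0("malformed Newick: ", conditionMessage(e))))
  } else {
    tryCatch(ape::read.tree(source),
             error = function(e) abort(paste0("malformed Newick: ", conditionMessage(e))))
  }
  if (is.null(tree)) abort("malformed Newick: parser returned no tree")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a phylogeny")
  if (ape::Ntip(tree) < 2) abort("tree has fewer than 2 tips")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1]
    abort(paste0("negative branch length on edge ", bad))
  }
  invisible(tree)
}

#' Write a tree to Newick
#'
#' @param tree an `phylo` object.
#' @param path output file; if `NULL`, the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the path, or the Newick string when `path` is `NULL`.
#' @export
write_newick <- function(tree, path = NULL, digits = 15) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Rescale a tree to unit total branch length
#'
#' Branch lengths are re-expressed as fractions of the total tree length, so
#' that diversity and endemism sums from different trees are directly
#' comparable. Idempotent up to floating point.
#'
#' @param tree a `phylo` object with positive total branch length.
#' @return the rescaled tree.
#' @export
scale_tree <- function(tree) {
  validate_tree(tree)
  tot <- sum(tree$edge.length)
  if (tot <= 0) abort("degenerate input: total branch length is zero")
  tree$edge.length <- tree$edge.length / tot
  tree
}

#' Build the equal-branch-length comparison tree
#'
#' Keeps the topology but sets every branch to the same length, scaled so the
#' comparison tree has unit total length (each of the E edges gets length
#' 1/E). Dividing a metric computed on the actual (unit-scaled) tree by its
#' value on this tree yields the relative metrics RPD and RPE.
#'
#' @param tree a `phylo` object.
#' @return a `phylo` object with identical topology and equal branch lengths.
#' @export
comparison_tree <- function(tree) {
  validate_tree(tree)
  n_edge <- nrow(tree$edge)
  tree$edge.length <- rep(1 / n_edge, n_edge)
  tree
}

#' Seeded random resolution of polytomies
#'
#' Used by [sensitivity_sweep()] to mirror a two-tree sensitivity check:
#' community-level metrics are expected to be robust to how polytomies are
#' resolved, and this provides reproducible resolutions to verify it.
#'
#' @param tree a `phylo` object.
#' @param seed integer seed.
#' @return a bifurcating `phylo`; zero-length edges introduced by the
#'   resolution are kept at zero.
#' @export
resolve_polytomies <- function(tree, seed = 1) {
  withr::with_seed(seed, ape::multi2di(tree, random = TRUE))
}
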