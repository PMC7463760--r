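# tips-below-edge indicator: ntip x nedge logical matrix, postorder accumulation
tip_edge_matrix <- function(tree) {
  n_tip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  n_edge <- nrow(po$edge)
  D <- matrix(FALSE, n_tip, n_edge, dimnames = list(po$tip.label, NULL))
  node_tips <- vector("list", n_tip + po$Nnode)
  for (i in seq_len(n_tip)) node_tips[[i]] <- i
  for (e in seq_len(n_edge)) {
    child <- po$edge[e, 2]
    tips <- node_tips[[child]]
    D[tips, e] <- TRUE
    parent <- po$edge[e, 1]
    node_tips[[parent]] <- c(node_tips[[parent]], tips)
  }
  list(D = D, lengths = po$edge.length, edge = po$edge)
}

# cells x edges presence (edge represented in a cell if any descendant tip is)
cell_edge_incidence <- function(m, te) {
  sp <- colnames(m)
  miss <- setdiff(sp, rownames(te$D))
  if (length(miss)) {
    abort(paste0("species absent from tree: ", paste(miss, collapse = ", ")))
  }
  Dsp <- te$D[sp, , drop = FALSE] * 1
  (m %*% Dsp) > 0
}

#' Branch incidence: which cells does each branch reach?
#'
#' For every edge of the tree, the set of grid cells where at least one
#' descendant tip is present, and that set's cardinality — the branch range
#' size by which phylogenetic endemism divides the branch length.
#'
#' @param grid occurrence tibble.
#' @param tree `phylo`; must contain every grid species among its tips.
#' @return a tibble with one row per edge: `edge`, `parent`, `child`,
#'   `length`, `n_cells`, and a list-column `cells`.
#' @export
branch_incidence <- function(grid, tree) {
  validate_tree(tree)
  te <- tip_edge_matrix(tree)
  B <- cell_edge_incidence(occ_matrix(grid), te)
  tibble::tibble(
    edge = seq_len(ncol(B)),
    parent = te$edge[, 1], child = te$edge[, 2],
    length = te$lengths,
    n_cells = colSums(B),
    cells = lapply(seq_len(ncol(B)), function(e) grid$cell[B[, e]])
  )
}

#' Per-cell diversity and endemism surfaces
#'
#' Computes, for every grid cell, Faith phylogenetic diversity (PD: summed
#' branch lengths over the root-paths of the present tips), phylogenetic
#' endemism (PE: the same sum with each branch length divided by the number
#' of cells the branch reaches), their counterparts on the equal-branch
#' comparison tree ([comparison_tree()]), and the ratios RPD = PD/PD_comp and
#' RPE = PE/PE_comp. Both the actual and the comparison tree are rescaled to
#' unit total length before metric computation, so PD and PE are fractions of
#' the tree; the unscaled sums are emitted as `pd_raw`/`pe_raw` since some
#' reports use absolute branch-length units (the ratios are identical either
#' way). Cells with no species are flagged by `richness = 0` and carry `NA`
#' metrics (no-data).
#'
#' @param grid occurrence tibble.
#' @param tree `phylo` containing every grid species.
#' @return a tibble keyed by `cell`: `richness`, `pd`, `pd_comp`, `pe`,
#'   `pe_comp`, `rpd`, `rpe`, `pd_raw`, `pe_raw`.
#' @export
phylo_metrics <- function(grid, tree) {
  validate_tree(tree)
  te <- tip_edge_matrix(tree)
  m <- occ_matrix(grid)
  B <- cell_edge_incidence(m, te)
  rng <- colSums(B)

  len_raw <- te$lengths
  len <- len_raw / sum(len_raw)
  len_comp <- rep(1 / length(len_raw), length(len_raw))

  pe_w <- function(l) ifelse(rng > 0, l / pmax(rng, 1), 0)
  pd <- as.vector(B %*% len)
  pd_comp <- as.vector(B %*% len_comp)
  pe <- as.vector(B %*% pe_w(len))
  pe_comp <- as.vector(B %*% pe_w(len_comp))
  pd_raw <- as.vector(B %*% len_raw)
  pe_raw <- as.vector(B %*% pe_w(len_raw))

  richness <- as.integer(rowSums(m))
  empty <- richness == 0
  ratio <- function(num, den) ifelse(!empty & den > 0, num / den, NA_real_)
  na_empty <- function(x) ifelse(empty, NA_real_, x)
  tibble::tibble(
    cell = grid$cell, richness = richness,
    pd = na_empty(pd), pd_comp = na_empty(pd_comp),
    pe = na_empty(pe), pe_comp = na_empty(pe_comp),
    rpd = ratio(pd, pd_comp), rpe = ratio(pe, pe_comp),
    pd_raw = na_empty(pd_raw), pe_raw = na_empty(pe_raw)
  )
}
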