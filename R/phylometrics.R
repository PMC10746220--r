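#' Phylogenetic diversity of a leaf set
#'
#' The total branch length of the minimal spanning subtree connecting the
#' given leaves, computed on the unrooted edge set (the stem edge above
#' the leaves' most recent common ancestor is excluded, so the value does
#' not depend on root placement). A set of fewer than two leaves spans no
#' edges and has diversity zero.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param leaves Character vector of leaf labels.
#' @return List with `pd` (branch-length units) and `percent`
#'   (100 * pd / total tree length).
#' @export
phylogenetic_diversity <- function(tree, leaves) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  leaves <- unique(as.character(leaves))
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("leaf label(s) not in tree: ", paste(unknown, collapse = ", "))
  total <- sum(tree$edge.length)
  pd <- if (length(leaves) < 2L) 0 else pd_spanning_length(tree, leaves)
  list(pd = pd, percent = 100 * pd / total)
}

# internal: an edge belongs to the spanning subtree iff both sides of the
# split it induces contain a selected leaf; root-invariant by construction
pd_spanning_length <- function(tree, leaves) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  sel <- integer(ntip + tree$Nnode)
  sel[match(leaves, tree$tip.label)] <- 1L
  for (i in seq_len(nrow(po$edge)))
    sel[po$edge[i, 1]] <- sel[po$edge[i, 1]] + sel[po$edge[i, 2]]
  below <- sel[po$edge[, 2]]
  include <- below > 0L & (length(leaves) - below) > 0L
  sum(po$edge.length[include])
}

#' Phylogenetic gain of a focal leaf set over a base set
#'
#' The additional branch length contributed by the focal leaves:
#' `PD(focal union base) - PD(base)`. The percentage is reported relative
#' to the combined set's diversity; the absolute value is returned
#' alongside so other denominators can be applied.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param focal,base Disjoint character vectors of leaf labels.
#' @return List with `gain`, `percent` (100 * gain / PD(union)),
#'   `pd_union` and `pd_base`.
#' @export
phylogenetic_gain <- function(tree, focal, base) {
  focal <- unique(as.character(focal))
  base <- unique(as.character(base))
  overlap <- intersect(focal, base)
  if (length(overlap))
    stop("focal and base sets overlap: ", paste(overlap, collapse = ", "))
  pd_base <- phylogenetic_diversity(tree, base)$pd
  if (!length(focal))
    return(list(gain = 0, percent = 0, pd_union = pd_base,
                pd_base = pd_base))
  pd_union <- phylogenetic_diversity(tree, union(focal, base))$pd
  gain <- pd_union - pd_base
  list(gain = gain,
       percent = if (pd_union > 0) 100 * gain / pd_union else 0,
       pd_union = pd_union, pd_base = pd_base)
}

#' Diversity and gain of a leaf set from files
#'
#' @param tree_path Newick file (branch lengths required).
#' @param focal_path Text file with one leaf label per line.
#' @param base_path Optional base-set file; when given, gain of the focal
#'   set over the base set is also reported.
#' @return Data frame with metric, branch-length value and percent.
#' @export
pd_from_files <- function(tree_path, focal_path, base_path = NULL) {
  tree <- read_newick(tree_path)
  focal <- readLines(focal_path, warn = FALSE)
  focal <- focal[nzchar(focal)]
  div <- phylogenetic_diversity(tree, focal)
  out <- data.frame(metric = "diversity", value = div$pd,
                    percent = div$percent, stringsAsFactors = FALSE)
  if (!is.null(base_path)) {
    base <- readLines(base_path, warn = FALSE)
    base <- base[nzchar(base)]
    gn <- phylogenetic_gain(tree, focal, base)
    out <- rbind(out, data.frame(metric = "gain", value = gn$gain,
                                 percent = gn$percent,
                                 stringsAsFactors = FALSE))
  }
  out
}
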