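#' Parse a newick string into a neutral tree
#'
#' The neutral tree relates the species present in the alignment; its branch
#' lengths are expected substitutions per neutral site, so the sum of all
#' branch lengths (the phylogenetic scope, [neutral_rate()]) is the per-site
#' neutral rate when no species is missing.
#'
#' Every non-root edge must carry a branch length and leaf labels must be
#' unique.  Rooted binary trees and unrooted trees written with a basal
#' multifurcation are both accepted.
#'
#' @param text A newick string, e.g. `"((A:0.1,B:0.2):0.05,C:0.3);"`.
#' @return An [ape::read.tree()] `"phylo"` object.
#' @examples
#' tr <- parse_newick("((A:0.1,B:0.2):0.05,C:0.3);")
#' neutral_rate(tr)  # 0.65
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed newick string: ", substr(text, 1, 60))
  validate_tree(tr)
  tr
}

#' Read a neutral tree from a newick file
#'
#' @param path Path to a newick file.
#' @return A `"phylo"` object (see [parse_newick()]).
#' @export
read_neutral_tree <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge))
    stop("missing branch lengths in tree")
  bad <- which(is.na(tr$edge.length) | !is.finite(tr$edge.length))
  if (length(bad)) {
    node <- tr$edge[bad[1], 2]
    lab <- if (node <= length(tr$tip.label)) tr$tip.label[node]
           else paste0("internal node ", node)
    stop("missing or non-finite branch length on edge to '", lab, "'")
  }
  if (any(tr$edge.length < 0))
    stop("negative branch length in tree")
  if (sum(tr$edge.length) <= 0)
    stop("tree has zero total branch length")
  invisible(tr)
}

#' Total neutral rate (phylogenetic scope) of a tree
#'
#' Sum of all branch lengths, in expected substitutions per neutral site.
#' For a per-column projected tree this is the site-specific neutral rate n.
#'
#' @param tree A `"phylo"` tree with branch lengths.
#' @return Numeric scalar.
#' @export
neutral_rate <- function(tree) {
  validate_tree(tree)
  sum(tree$edge.length)
}

#' Project a tree onto the species observed at a column
#'
#' Returns the induced subtree on `species`, with internal nodes left with a
#' single child collapsed (their incident branch lengths summed) so the total
#' branch length equals the length of the minimal subtree connecting the
#' retained leaves.  With fewer than 3 species no valid tree exists for rate
#' estimation and `NULL` is returned (the "too shallow" signal).
#'
#' @param tree A `"phylo"` tree.
#' @param species Character vector of leaf labels to keep (a subset of
#'   `tree$tip.label`).
#' @return A projected `"phylo"` tree, or `NULL` if fewer than 3 species.
#' @export
project_tree <- function(tree, species) {
  species <- unique(as.character(species))
  unknown <- setdiff(species, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(species) < 3) return(NULL)
  if (length(species) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, species)
}

#' Rescale every branch of a tree by a constant factor
#'
#' @param tree A `"phylo"` tree.
#' @param r Non-negative scale factor.
#' @return The rescaled tree.
#' @export
rescale_tree <- function(tree, r) {
  stopifnot(is.numeric(r), length(r) == 1, r >= 0)
  tree$edge.length <- tree$edge.length * r
  tree
}

# Postorder edge arrays for the C++ likelihood core.
tree_data <- function(tree) {
  validate_tree(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  list(parent = as.integer(tr$edge[, 1]),
       child = as.integer(tr$edge[, 2]),
       elen = as.numeric(tr$edge.length),
       ntip = ntip,
       nnode = ntip + tr$Nnode,
       root = ntip + 1L,
       tips = tr$tip.label)
}
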