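#' Read a rooted phylogenetic tree from a Newick file
#'
#' Branch lengths are expected in substitutions per site. A missing length on
#' the root edge is tolerated and treated as 0; negative branch lengths are
#' rejected. Multifurcations are permitted.
#'
#' @param path Path to a Newick file.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error in ", path)
  validate_tree(tr)
}

## Shared validation for trees from any source.
validate_tree <- function(tr) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (anyNA(tr$edge.length)) {
    ## tolerate only missing lengths on edges out of the root
    root <- ape::Ntip(tr) + 1L
    bad <- which(is.na(tr$edge.length))
    if (any(tr$edge[bad, 1] != root))
      stop("missing branch length on a non-root edge")
    tr$edge.length[bad] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("validation error: negative branch length (",
         format(min(tr$edge.length)), ")")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels")
  tr
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Prune a tree to a set of taxa
#'
#' Returns the subtree induced by `keep`: unsampled leaves are removed and
#' degree-2 internal nodes are suppressed with their branch lengths summed,
#' so all pairwise patristic distances among kept leaves are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to retain.
#' @return The induced `phylo` subtree.
#' @export
prune_to_taxa <- function(tree, keep) {
  tree <- validate_tree(tree)
  if (length(keep) == 0L) stop("keep set is empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  if (setequal(keep, tree$tip.label)) return(tree)
  if (length(keep) < 2L) stop("need at least 2 taxa to form a tree")
  ape::keep.tip(tree, keep)
}

## children of each node as a list indexed by node number (postorder-safe)
tree_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], i)  # store edge indices
  }
  ch
}
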