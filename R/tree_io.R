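#' Read a rooted phylogenetic tree from a newick file
#'
#' Wraps [ape::read.tree()] with the validation the NRI machinery needs:
#' unique tip labels and non-negative branch lengths. Trees without branch
#' lengths are an error unless \code{default_branch_length} is given (useful
#' for toy topologies).
#'
#' @param path path to a newick file.
#' @param default_branch_length optional positive number imputed when the
#'   newick carries no branch lengths.
#' @return An [ape::read.tree()] \code{"phylo"} object.
#' @export
read_tree <- function(path, default_branch_length = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick in '", path, "'")
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree, default_branch_length)
}

#' @rdname read_tree
#' @param tree a \code{"phylo"} object.
#' @export
validate_tree <- function(tree, default_branch_length = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (is.null(default_branch_length))
      stop("tree has no branch lengths (patristic distances undefined); ",
           "pass default_branch_length to impute one")
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  tree
}
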