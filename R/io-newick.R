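#' Read a rooted tree from a Newick file
#'
#' Thin validating wrapper around [ape::read.tree()]: the file must hold a
#' single rooted tree with unique leaf names. Trees round-trip losslessly
#' through [write_newick()] (topology, names, branch lengths to six
#' decimals).
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Optional Newick string (used instead of `path`).
#' @return An object of class `phylo`.
#' @examples
#' tr <- read_newick(text = "((A,B),C);")
#' tr$tip.label
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tr)) abort("Newick parse error: no tree found.")
  if (inherits(tr, "multiPhylo")) {
    abort("expected a single tree, found several.")
  }
  if (anyDuplicated(tr$tip.label)) {
    abort(paste0("duplicate leaf name(s): ",
                 paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
                       collapse = ", ")))
  }
  if (!ape::is.rooted(tr)) abort("tree must be rooted.")
  tr
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @param digits Decimal places for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 6) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
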