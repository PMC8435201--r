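# Newick tree input/output on top of ape's phylo representation.
#
# Trees are stored as read (rooted input stays rooted); likelihood code
# works on an unrooted view and is invariant to the root placement by the
# pulley principle.  Internal-node labels (e.g. support values) are
# preserved but ignored by all computations.

#' Read a Newick tree
#'
#' @param path path to a Newick file (first tree is used) or a Newick
#'   string ending in `;`.
#' @param default_branch_length length assigned to branches without an
#'   explicit length in the input (default 0.1 expected substitutions per
#'   site).
#' @return an [ape::phylo] tree with non-negative branch lengths.
#' @export
read_newick <- function(path, default_branch_length = 0.1) {
  txt <- if (grepl(";", path, fixed = TRUE)) path else {
    if (!file.exists(path)) format_error("file not found: %s", path)
    paste(readLines(path, warn = FALSE), collapse = "")
  }
  n_open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  n_close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (n_open != n_close)
    format_error("unbalanced parentheses in Newick input")
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) format_error("Newick parse failure: %s",
                                                  conditionMessage(e)))
  if (is.null(tr)) format_error("Newick parse failure")
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(default_branch_length, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    tr$edge.length[is.na(tr$edge.length)] <- default_branch_length
  }
  if (any(tr$edge.length < 0))
    value_error("negative branch length in Newick input")
  if (anyDuplicated(tr$tip.label))
    format_error("duplicate leaf labels in Newick input")
  tr
}

#' Write a tree to a Newick file
#' @param tree an [ape::phylo].
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Unrooted view of a tree
#'
#' @param tree an [ape::phylo].
#' @return the same topology unrooted (degree-3 basal node).
#' @export
unrooted_view <- function(tree) {
  if (ape::is.rooted(tree)) ape::unroot(tree) else tree
}

#' @keywords internal
validate_tree_against_alignment <- function(tree, aln) {
  miss <- setdiff(tree$tip.label, rownames(aln))
  if (length(miss) > 0)
    value_error("tree leaves absent from alignment: %s",
                paste(miss, collapse = ", "))
  invisible(TRUE)
}
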