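#' Read and write newick tree files
#'
#' Thin wrappers over \code{ape::read.tree}/\code{ape::write.tree} that always
#' return/accept a \code{multiPhylo} list.  Polytomies are preserved; rooted
#' trees round-trip with their root.
#'
#' @param path file path (one newick string per line or semicolon-separated).
#' @return \code{readTrees}: a \code{multiPhylo}; \code{writeTrees}: the path,
#'   invisibly.
#' @export
readTrees <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick in ", path)
  asMultiPhylo(tr)
}

#' @rdname readTrees
#' @param trees a \code{phylo} or \code{multiPhylo}.
#' @export
writeTrees <- function(trees, path) {
  trees <- asMultiPhylo(trees)
  ape::write.tree(trees, file = path)
  invisible(path)
}

asMultiPhylo <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (is.list(trees) && !inherits(trees, "multiPhylo"))
    class(trees) <- "multiPhylo"
  trees
}
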