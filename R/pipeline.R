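# content hash of an in-memory object, for run manifests
objectHash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(obj, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run a global three-taxon analysis
#'
#' The staged workflow on one supermatrix: optional taxon reduction, 50\%
#' majority-rule consensus of the designated outgroup taxa as the operational
#' outgroup, Williams-Siebert statement encoding of the ingroup, and a
#' uniform-weight parsimony search on the statement matrix.  The manifest
#' records statement and violation counts, length, CI/RI, the seed, and
#' content hashes of the intermediate objects.
#'
#' @param aln supermatrix (\linkS4class{DnaAlignment}).
#' @param outgroupTaxa taxa whose consensus forms the operational outgroup;
#'   they are excluded from the encoded ingroup.
#' @param keep optional reduced taxon list (applied before consensus; the
#'   outgroup taxa are always retained).
#' @param threshold consensus threshold, see [consensusSequence()].
#' @param zeros zeros convention, see [polarizeColumn()].
#' @param searchParams list of arguments for [mpSearch()].
#' @param seed integer seed.
#' @return list with elements \code{search} (\linkS4class{ParsimonySearch}),
#'   \code{tsMatrix}, \code{consensus}, \code{manifest}.
#' @export
runGlobal3ta <- function(aln, outgroupTaxa, keep = NULL, threshold = 0.5,
                         zeros = "absence", searchParams = list(),
                         seed = 1L) {
  outgroupTaxa <- normalizeLabels(outgroupTaxa)
  missing <- setdiff(outgroupTaxa, taxa(aln))
  if (length(missing))
    stop("outgroup taxa not in matrix: ", paste(missing, collapse = ", "))
  if (!is.null(keep))
    aln <- subsetTaxa(aln, union(normalizeLabels(keep), outgroupTaxa))
  cons <- consensusSequence(aln, outgroupTaxa, threshold)
  ingroup <- setdiff(taxa(aln), outgroupTaxa)
  ts <- encodeMatrix(subsetTaxa(aln, ingroup), cons, zeros = zeros)
  sr <- do.call(mpSearch, c(list(ts), searchParams, list(seed = seed)))
  manifest <- list(
    stage = "global_3ta", nTaxa = length(ingroup),
    nStatements = nStatements(ts), length = searchScore(sr),
    violations = searchScore(sr) - nStatements(ts),
    ci = ensembleCI(sr), ri = ensembleRI(sr), seed = seed,
    params = sr@params,
    hashes = list(consensus = objectHash(cons), tsMatrix = objectHash(ts),
                  trees = objectHash(ape::write.tree(bestTrees(sr)))))
  list(search = sr, tsMatrix = ts, consensus = cons, manifest = manifest)
}

#' Run clade-wise local three-taxon analyses
#'
#' Each clade is analysed within its own taxon set against a clade-specific
#' operational outgroup (e.g. the consensus of a sister clade).  Where a
#' search returns several equally optimal trees, both the strict consensus
#' and the RF median consensus are produced.
#'
#' @param aln supermatrix (\linkS4class{DnaAlignment}).
#' @param clades named list; each element a list with components \code{taxa}
#'   (the clade's taxon labels) and \code{outgroup} (taxa whose consensus
#'   polarizes this clade).
#' @inheritParams runGlobal3ta
#' @return named list, one element per clade, each with \code{search},
#'   \code{strict}, \code{median} (list of tree and score), and
#'   \code{manifest}.
#' @export
runLocal3tas <- function(aln, clades, threshold = 0.5, zeros = "absence",
                         searchParams = list(), seed = 1L) {
  if (!length(clades)) stop("no clades given")
  if (is.null(names(clades))) names(clades) <- paste0("clade", seq_along(clades))
  out <- vector("list", length(clades))
  names(out) <- names(clades)
  for (nm in names(clades)) {
    cl <- clades[[nm]]
    if (!length(cl$taxa)) stop("empty clade: ", nm)
    res <- runGlobal3ta(subsetTaxa(aln, union(cl$taxa, cl$outgroup)),
                        outgroupTaxa = cl$outgroup, threshold = threshold,
                        zeros = zeros, searchParams = searchParams,
                        seed = seed)
    trees <- bestTrees(res$search)
    if (length(trees) > 1) {
      strict <- strictConsensus(trees)
      med <- rfMedian(trees)
    } else {
      strict <- trees[[1]]
      med <- list(tree = trees[[1]], score = 0)
    }
    res$manifest$stage <- paste0("local_3ta:", nm)
    res$manifest$medianScore <- med$score
    out[[nm]] <- list(search = res$search, strict = strict, median = med,
                      manifest = res$manifest)
  }
  out
}

#' Combine topologies into an RF supertree
#'
#' The global and local minimal topologies are combined into the single
#' median RF supertree; with a single input the input is returned with score
#' 0, and with identical leaf sets the exact RF median is used.
#'
#' @param trees \code{multiPhylo} or list of \code{phylo}.
#' @param mode see [rfSupertree()].
#' @return list with elements \code{tree}, \code{score}, \code{manifest}.
#' @export
combineTopologies <- function(trees, mode = "auto") {
  trees <- asMultiPhylo(trees)
  res <- if (length(trees) == 1) list(tree = trees[[1]], score = 0)
         else rfSupertree(trees, mode = mode)
  res$manifest <- list(stage = "combine", nInputs = length(trees),
                       score = res$score,
                       hashes = list(supertree = objectHash(
                         ape::write.tree(res$tree))))
  res
}
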