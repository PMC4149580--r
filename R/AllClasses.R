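#' DnaAlignment: a partitioned symbolic alignment
#'
#' Taxa-by-columns matrix of aligned nucleotide symbols (IUPAC codes, gap
#' \code{-} and missing \code{?}), together with a partition map assigning
#' contiguous, disjoint column intervals (0-based, half-open) to loci.
#'
#' @slot seqs character matrix; rownames are unique taxon labels.
#' @slot partition data.frame with columns \code{locus}, \code{start},
#'   \code{end}; intervals are 0-based half-open, contiguous, and cover all
#'   columns.
#' @seealso [dnaAlignment()], [readAlignment()], [concatSupermatrix()]
#' @exportClass DnaAlignment
setClass("DnaAlignment",
         representation(seqs = "matrix", partition = "data.frame"))

setValidity("DnaAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || any(rownames(m) == ""))
    return("all rows must carry a taxon label")
  if (anyDuplicated(rownames(m)))
    return(sprintf("duplicate taxon label: %s",
                   rownames(m)[duplicated(rownames(m))][1]))
  bad <- which(!(m %in% DNA_ALPHABET))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    return(sprintf("symbol '%s' (taxon %s, column %d) is not in the alphabet",
                   m[bad[1]], rownames(m)[rc[1]], rc[2]))
  }
  p <- object@partition
  if (!all(c("locus", "start", "end") %in% names(p)))
    return("partition needs columns locus, start, end")
  if (nrow(p)) {
    if (anyDuplicated(p$locus)) return("duplicate locus name in partition")
    o <- order(p$start)
    if (p$start[o][1] != 0 || p$end[o][nrow(p)] != ncol(m) ||
        any(p$end[o][-nrow(p)] != p$start[o][-1]) ||
        any(p$end <= p$start))
      return("partition intervals must be disjoint, contiguous, and cover all columns")
  }
  TRUE
})

#' TsMatrix: a deduplicated three-taxon-statement matrix
#'
#' The Williams-Siebert binary representation of a polarized DNA matrix, kept
#' as the deduplicated multiset of statements ij|k (taxa i and j share a
#' derived state to the exclusion of k) with per-statement multiplicities
#' under uniform weighting.  The all-plesiomorphic operational outgroup is an
#' implicit extra row; it never participates in a statement.  Expanded, every
#' statement is one binary character with 1 at i and j, 0 at k and the
#' outgroup, and ? elsewhere, hence every character is parsimony-informative.
#'
#' @slot taxa ingroup taxon labels, in matrix order.
#' @slot outgroupLabel reserved label of the implicit operational outgroup.
#' @slot statements data.frame with integer columns \code{i}, \code{j},
#'   \code{k} (indices into \code{taxa}, \code{i < j}) and numeric
#'   \code{mult} (occurrence count).
#' @slot nStatements total statement count with multiplicity.
#' @slot recodings per-column provenance summary: data.frame with columns
#'   \code{column} (1-based source column), \code{state} (derived state),
#'   \code{n1}, \code{n0}, \code{n} (statements contributed).
#' @slot provenance optional full occurrence table (\code{column},
#'   \code{state}, \code{i}, \code{j}, \code{k}); zero rows unless requested
#'   at encoding time.
#' @slot convention zeros convention used ("absence" or "plesiomorphic").
#' @seealso [encodeMatrix()], [tsLength()], [writeTsNexus()]
#' @exportClass TsMatrix
setClass("TsMatrix",
         representation(taxa = "character", outgroupLabel = "character",
                        statements = "data.frame", nStatements = "numeric",
                        recodings = "data.frame", provenance = "data.frame",
                        convention = "character"))

setValidity("TsMatrix", function(object) {
  st <- object@statements
  if (!all(c("i", "j", "k", "mult") %in% names(st)))
    return("statements needs columns i, j, k, mult")
  n <- length(object@taxa)
  if (nrow(st)) {
    if (any(st$i >= st$j)) return("statement indices must satisfy i < j")
    if (any(st$k == st$i | st$k == st$j)) return("k must differ from i and j")
    if (any(c(st$i, st$j, st$k) < 1) || any(c(st$i, st$j, st$k) > n))
      return("statement indices out of range")
    if (any(st$mult < 1)) return("multiplicities must be >= 1")
  }
  if (abs(sum(st$mult) - object@nStatements) > 1e-9)
    return("nStatements must equal the sum of multiplicities")
  if (object@outgroupLabel %in% object@taxa)
    return("the operational outgroup label must not collide with a taxon")
  TRUE
})

#' ParsimonySearch: the result of a parsimony tree search
#'
#' @slot trees equally optimal distinct trees (class \code{multiPhylo}).
#' @slot score total tree length of the optimal trees.
#' @slot ci ensemble consistency index.
#' @slot ri ensemble retention index.
#' @slot seed integer seed the search was run under.
#' @slot params search parameters (replicates, swap level, tree caps).
#' @slot kind "dna", "ts", or "exact".
#' @slot stats auxiliary statistics (sums of per-character minimum and maximum
#'   steps, statement and violation counts for 3TS matrices).
#' @exportClass ParsimonySearch
setClass("ParsimonySearch",
         representation(trees = "ANY", score = "numeric", ci = "numeric",
                        ri = "numeric", seed = "integer", params = "list",
                        kind = "character", stats = "list"))

setValidity("ParsimonySearch", function(object) {
  if (!inherits(object@trees, "multiPhylo")) return("trees must be a multiPhylo")
  if (length(object@ci) && !is.na(object@ci) &&
      (object@ci < 0 || object@ci > 1 + 1e-9)) return("CI out of [0,1]")
  if (length(object@ri) && !is.na(object@ri) &&
      (object@ri < -1e-9 || object@ri > 1 + 1e-9)) return("RI out of [0,1]")
  TRUE
})

#' SimConfig: parameters of the supermatrix simulator
#'
#' Configuration for the synthetic-data generator, shaped after a multi-locus
#' plastid supermatrix: a pure-birth ingroup tree with basally attached
#' outgroup taxa, per-locus Jukes-Cantor sequence evolution, per-taxon locus
#' dropout (padded as missing when loci are concatenated), and short injected
#' gap runs.
#'
#' @slot nTaxa total taxon count (ingroup + outgroup).
#' @slot nLoci number of loci.
#' @slot locusLengths column count per locus (recycled to \code{nLoci}).
#' @slot birthRate speciation rate of the pure-birth tree.
#' @slot rates per-locus substitution rate scaling (recycled).
#' @slot missingProb probability a taxon lacks a given locus entirely.
#' @slot gapRate expected fraction of sites opening a short gap run.
#' @slot nOutgroup number of outgroup taxa attached below the ingroup root.
#' @slot seed mandatory integer seed; all stage generators derive from it.
#' @seealso [simConfig()], [simulateTree()], [evolveSequences()]
#' @exportClass SimConfig
setClass("SimConfig",
         representation(nTaxa = "integer", nLoci = "integer",
                        locusLengths = "integer", birthRate = "numeric",
                        rates = "numeric", missingProb = "numeric",
                        gapRate = "numeric", nOutgroup = "integer",
                        seed = "integer"))

setValidity("SimConfig", function(object) {
  if (object@nTaxa < 4) return("nTaxa must be >= 4")
  if (object@nLoci < 1) return("nLoci must be >= 1")
  if (length(object@locusLengths) != object@nLoci) return("one length per locus")
  if (any(object@locusLengths < 1)) return("locus lengths must be positive")
  if (object@birthRate <= 0 || any(object@rates < 0)) return("rates must be >= 0")
  if (object@missingProb < 0 || object@missingProb > 1) return("missingProb in [0,1]")
  if (object@gapRate < 0 || object@gapRate > 1) return("gapRate in [0,1]")
  if (object@nOutgroup < 1 || object@nOutgroup >= object@nTaxa - 2)
    return("need >= 1 outgroup taxon and >= 3 ingroup taxa")
  if (is.na(object@seed)) return("seed is mandatory")
  TRUE
})
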