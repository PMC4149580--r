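#' Accessors for tritax objects
#'
#' @param x a \linkS4class{DnaAlignment}, \linkS4class{TsMatrix}, or
#'   \linkS4class{ParsimonySearch}.
#' @name accessors
NULL

#' @describeIn accessors taxon labels.
#' @export
setGeneric("taxa", function(x) standardGeneric("taxa"))

#' @describeIn accessors number of alignment columns.
#' @export
setGeneric("nColumns", function(x) standardGeneric("nColumns"))

#' @describeIn accessors the locus partition map (0-based half-open intervals).
#' @export
setGeneric("partitionMap", function(x) standardGeneric("partitionMap"))

#' @describeIn accessors deduplicated statement table of a \code{TsMatrix}.
#' @export
setGeneric("statements", function(x) standardGeneric("statements"))

#' @describeIn accessors total statement count with multiplicity.
#' @export
setGeneric("nStatements", function(x) standardGeneric("nStatements"))

#' @describeIn accessors equally optimal trees of a search.
#' @export
setGeneric("bestTrees", function(x) standardGeneric("bestTrees"))

#' @describeIn accessors optimal tree length of a search.
#' @export
setGeneric("searchScore", function(x) standardGeneric("searchScore"))

#' @describeIn accessors ensemble consistency index of a search.
#' @export
setGeneric("ensembleCI", function(x) standardGeneric("ensembleCI"))

#' @describeIn accessors ensemble retention index of a search.
#' @export
setGeneric("ensembleRI", function(x) standardGeneric("ensembleRI"))

setMethod("taxa", "DnaAlignment", function(x) rownames(x@seqs))
setMethod("taxa", "TsMatrix", function(x) x@taxa)
setMethod("nColumns", "DnaAlignment", function(x) ncol(x@seqs))
setMethod("partitionMap", "DnaAlignment", function(x) x@partition)
setMethod("statements", "TsMatrix", function(x) x@statements)
setMethod("nStatements", "TsMatrix", function(x) x@nStatements)
setMethod("bestTrees", "ParsimonySearch", function(x) x@trees)
setMethod("searchScore", "ParsimonySearch", function(x) x@score)
setMethod("ensembleCI", "ParsimonySearch", function(x) x@ci)
setMethod("ensembleRI", "ParsimonySearch", function(x) x@ri)

#' @export
#' @method as.matrix DnaAlignment
as.matrix.DnaAlignment <- function(x, ...) x@seqs

setMethod("show", "DnaAlignment", function(object) {
  cat(sprintf("DnaAlignment: %d taxa x %d columns, %d %s\n",
              nrow(object@seqs), ncol(object@seqs), nrow(object@partition),
              if (nrow(object@partition) == 1) "locus" else "loci"))
  lab <- rownames(object@seqs)
  cat("  taxa: ", paste(head(lab, 4), collapse = ", "),
      if (length(lab) > 4) sprintf(", ... (%d more)", length(lab) - 4) else "",
      "\n", sep = "")
})

setMethod("show", "TsMatrix", function(object) {
  cat(sprintf(
    "TsMatrix: %s three-taxon statements (%d distinct) over %d taxa + '%s'\n",
    format(object@nStatements, big.mark = ","), nrow(object@statements),
    length(object@taxa), object@outgroupLabel))
  cat(sprintf("  zeros convention: %s\n", object@convention))
})

setMethod("show", "ParsimonySearch", function(object) {
  cat(sprintf("ParsimonySearch (%s): %d optimal tree%s, length %s\n",
              object@kind, length(object@trees),
              if (length(object@trees) == 1) "" else "s",
              format(object@score, big.mark = ",")))
  cat(sprintf("  CI = %.4f, RI = %.4f (seed %d)\n",
              object@ci, object@ri, object@seed))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d taxa (%d outgroup), %d loci (%s columns), seed %d\n",
    object@nTaxa, object@nOutgroup, object@nLoci,
    format(sum(object@locusLengths), big.mark = ","), object@seed))
})
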