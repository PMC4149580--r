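#' Per-column state frequencies over a taxon set
#'
#' Frequencies are computed over \emph{applicable} symbols only: the four
#' nucleotides.  Gap \code{-}, missing \code{?}, and \code{N} never count;
#' partial IUPAC ambiguities are excluded by default or, with
#' \code{ambiguity = "fractional"}, split their weight equally among their
#' component nucleotides.
#'
#' @param aln a \linkS4class{DnaAlignment}.
#' @param taxa taxon labels to profile over.
#' @param col 1-based column index.
#' @param ambiguity \code{"exclude"} (default) or \code{"fractional"}.
#' @return named numeric vector of frequencies over A, C, G, T (summing to 1
#'   when any symbol is applicable, all zero otherwise), with attribute
#'   \code{"applicable"} giving the applicable weight.
#' @export
columnProfile <- function(aln, taxa, col,
                          ambiguity = c("exclude", "fractional")) {
  ambiguity <- match.arg(ambiguity)
  taxa <- normalizeLabels(taxa)
  if (!length(taxa)) stop("taxon set must be nonempty")
  unknown <- setdiff(taxa, rownames(aln@seqs))
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (col < 1 || col > nColumns(aln)) stop("column index out of range")
  counts <- baseCounts(aln@seqs[taxa, col, drop = FALSE], ambiguity)[, 1]
  applicable <- sum(counts)
  freqs <- if (applicable > 0) counts / applicable else counts
  attr(freqs, "applicable") <- applicable
  freqs
}

# 4 x ncol matrix of (possibly fractional) nucleotide counts
baseCounts <- function(mat, ambiguity) {
  counts <- vapply(NUCLEOTIDES, function(b) .colSums(mat == b, nrow(mat), ncol(mat)),
                   numeric(ncol(mat)))
  counts <- matrix(t(counts), 4, ncol(mat), dimnames = list(NUCLEOTIDES, NULL))
  if (ambiguity == "fractional") {
    for (code in names(IUPAC_SETS)) {
      hits <- .colSums(mat == code, nrow(mat), ncol(mat))
      if (any(hits > 0)) {
        members <- IUPAC_SETS[[code]]
        counts[members, ] <- counts[members, ] +
          rep(hits / length(members), each = length(members))
      }
    }
  }
  counts
}

#' Majority-rule consensus sequence of a taxon set
#'
#' Per column, the modal applicable state is emitted when it is unique and
#' its frequency among applicable states reaches the threshold; otherwise the
#' column receives \code{?} (no applicable symbol, sub-threshold mode, or tied
#' modes).  With the default threshold of 0.5 this is the 50\% majority-rule
#' consensus used to construct an operational outgroup sequence.
#'
#' @inheritParams columnProfile
#' @param threshold minimum frequency among applicable states required to
#'   include a state, in (0, 1].
#' @return character vector of consensus symbols (A, C, G, T, or \code{?}).
#' @export
consensusSequence <- function(aln, taxa, threshold = 0.5,
                              ambiguity = c("exclude", "fractional")) {
  ambiguity <- match.arg(ambiguity)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  taxa <- normalizeLabels(taxa)
  unknown <- setdiff(taxa, rownames(aln@seqs))
  if (length(unknown)) stop("unknown taxa: ", paste(unknown, collapse = ", "))
  counts <- baseCounts(aln@seqs[taxa, , drop = FALSE], ambiguity)
  applicable <- .colSums(counts, 4, ncol(counts))
  maxv <- apply(counts, 2, max)
  eps <- 1e-9
  nModes <- .colSums(counts >= rep(maxv - eps, each = 4) & counts > 0, 4, ncol(counts))
  modal <- NUCLEOTIDES[max.col(t(counts), ties.method = "first")]
  ok <- applicable > 0 & nModes == 1 & (maxv / pmax(applicable, eps)) >= threshold - eps
  ifelse(ok, modal, "?")
}
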