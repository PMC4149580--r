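#' @noRd
symbolBits <- function(mat) {
  out <- matrix(SYMBOL_BITS[mat], nrow(mat), ncol(mat))
  rownames(out) <- rownames(mat)
  out
}

# collapse identical columns to patterns with weights
compressPatterns <- function(bits) {
  key <- do.call(paste, c(as.data.frame(t(bits)), sep = ","))
  f <- factor(key, levels = unique(key))
  idx <- !duplicated(key)
  list(states = bits[, idx, drop = FALSE],
       weights = as.numeric(table(f)),
       map = as.integer(f))
}

coerceCharMatrix <- function(x) {
  if (is(x, "DnaAlignment")) return(x@seqs)
  if (is.character(x) && is.null(dim(x))) {
    if (is.null(names(x))) stop("column vector must be named by taxon")
    return(matrix(toupper(x), ncol = 1, dimnames = list(names(x), NULL)))
  }
  m <- x
  m[] <- toupper(m)
  m
}

#' Fitch parsimony length of a tree
#'
#' Minimum number of state changes of unordered (Fitch) characters on a tree,
#' computed by the set-intersection pass generalized to polytomies
#' (Hartigan's bottom-up rule).  Missing data (\code{?}, \code{-}, \code{N})
#' behave as the full nucleotide set and partial IUPAC ambiguities as their
#' component sets.  Binary 01 characters may be scored through the same
#' kernel (Wagner and Fitch parsimony coincide for binary states).
#'
#' @param tree a \code{phylo}; polytomies allowed; branch lengths ignored.
#' @param x a \linkS4class{DnaAlignment}, character matrix, or a single named
#'   column vector.  Every tree leaf must have a row.
#' @return \code{fitchLength}: total length (numeric); \code{fitchSteps}:
#'   integer vector of per-column steps.
#' @export
fitchLength <- function(tree, x) sum(fitchSteps(tree, x))

#' @rdname fitchLength
#' @export
fitchSteps <- function(tree, x) {
  mat <- coerceCharMatrix(x)
  if (is.null(tree$tip.label)) stop("tree has no tip labels")
  missing <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing))
    stop("leaf without a character row: ", paste(missing, collapse = ", "))
  bits <- symbolBits(mat[tree$tip.label, , drop = FALSE])
  cp <- compressPatterns(bits)
  po <- ape::reorder.phylo(tree, "postorder")
  res <- fitch_count_cpp(po$edge, length(tree$tip.label), cp$states,
                         cp$weights)
  res$steps[cp$map]
}

#' Per-character parsimony statistics on a tree
#'
#' For each column: observed steps \code{s} on the tree (Fitch), the minimum
#' conceivable steps \code{m} = (number of observed states - 1), and the
#' maximum \code{g} = (number of scored taxa) - (largest state count), both
#' over unambiguously scored taxa.
#'
#' @param x alignment (\linkS4class{DnaAlignment} or character matrix).
#' @param tree a scored \code{phylo}.
#' @return data.frame with columns \code{steps}, \code{minSteps},
#'   \code{maxSteps}; invariant \code{m <= s <= g} holds columnwise.
#' @export
charStats <- function(x, tree) {
  mat <- coerceCharMatrix(x)
  s <- fitchSteps(tree, mat)
  counts <- baseCounts(mat, "exclude")
  r <- .colSums(counts > 0, 4, ncol(counts))
  nScored <- .colSums(counts, 4, ncol(counts))
  maxCount <- apply(counts, 2, max)
  data.frame(steps = s,
             minSteps = pmax(r - 1, 0),
             maxSteps = ifelse(r > 0, nScored - maxCount, 0))
}

#' Ensemble consistency and retention indices
#'
#' \code{CI = sum(m) / L} and \code{RI = (sum(g) - L) / (sum(g) - sum(m))}
#' over all characters; \code{RI} is \code{NA} (with a warning) when every
#' character is constant or uninformative (\code{sum(g) == sum(m)}).
#'
#' @param stats data.frame from [charStats()].
#' @param length tree length; defaults to \code{sum(stats$steps)}.
#' @return list with elements \code{ci}, \code{ri}, \code{length}.
#' @export
ensembleCiRi <- function(stats, length = NULL) {
  L <- if (is.null(length)) sum(stats$steps) else length
  sm <- sum(stats$minSteps); sg <- sum(stats$maxSteps)
  ci <- if (L > 0) sm / L else NA_real_
  ri <- if (sg - sm > 0) (sg - L) / (sg - sm) else {
    warning("RI undefined: all characters constant or uninformative")
    NA_real_
  }
  list(ci = ci, ri = ri, length = L)
}

#' Closed-form ensemble CI/RI of a uniform-weight statement matrix
#'
#' Every expanded three-taxon-statement character has minimum 1 and maximum 2
#' steps, so for \code{N} statements at tree length \code{L}:
#' \code{CI = N / L} and \code{RI = (2N - L) / N}.  The expanded binary
#' matrix is never materialized.
#'
#' @param nStatements total statement count N (with multiplicity).
#' @param length optimal tree length L, between N and 2N.
#' @return list with elements \code{ci}, \code{ri}, \code{length}.
#' @export
tsEnsembleCiRi <- function(nStatements, length) {
  N <- as.numeric(nStatements); L <- as.numeric(length)
  if (N <= 0) stop("need at least one statement")
  if (L < N - 1e-9 || L > 2 * N + 1e-9)
    warning("length outside [N, 2N]; not a uniform statement matrix?")
  list(ci = N / L, ri = (2 * N - L) / N, length = L)
}

#' Parsimony length of a tree under a three-taxon-statement matrix
#'
#' A statement ij|k is accommodated on a tree polarized at the operational
#' outgroup iff the most recent common ancestor of i and j is a proper
#' descendant of the most recent common ancestor of i, j, and k.  Each
#' statement contributes 1 step when accommodated and 2 when violated, so
#' \code{length = N + V}.  This equals the summed Fitch length over the
#' expanded binary characters.
#'
#' @param tree a \code{phylo} whose leaves include every statement taxon and
#'   either the operational outgroup leaf or an explicit root.
#' @param ts a \linkS4class{TsMatrix}.
#' @return list with elements \code{length}, \code{violations} (with
#'   multiplicity), \code{accommodated}, \code{nStatements}.
#' @export
tsLength <- function(tree, ts) {
  st <- ts@statements
  N <- ts@nStatements
  if (!nrow(st))
    return(list(length = 0, violations = 0, accommodated = 0, nStatements = 0))
  idx <- match(ts@taxa, tree$tip.label)
  used <- sort(unique(c(st$i, st$j, st$k)))
  if (anyNA(idx[used]))
    stop("statement taxa missing from tree: ",
         paste(ts@taxa[used][is.na(idx[used])], collapse = ", "))
  ogTip <- match(ts@outgroupLabel, tree$tip.label)
  if (is.na(ogTip)) {
    if (!ape::is.rooted(tree))
      stop("unrooted tree without the designated outgroup leaf '",
           ts@outgroupLabel, "'")
    ogTip <- 0L
  }
  viol <- ts_violations_cpp(tree$edge, length(tree$tip.label), ogTip,
                            idx[st$i], idx[st$j], idx[st$k])
  V <- sum(st$mult[viol])
  list(length = N + V, violations = V, accommodated = N - V, nStatements = N)
}
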