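#' Polarize one alignment column against an outgroup state
#'
#' The first step of the Williams-Siebert binary representation: for each
#' nucleotide \code{s} different from the outgroup state and observed in at
#' least one ingroup taxon, a binary recoding is produced in which the taxa
#' bearing \code{s} are scored 1 (apomorphic) and a zeros set is scored 0.
#' Taxa with gap, missing, \code{N} or a partial ambiguity are unscored.
#'
#' Two zeros conventions are supported: \code{"absence"} (default; 0 = every
#' scored taxon lacking \code{s}, the presence/absence reading of a binary
#' representation) and \code{"plesiomorphic"} (0 = only taxa bearing the
#' outgroup state).
#'
#' @param column character vector of symbols, one per ingroup taxon.
#' @param outgroupState the polarizing state; must be one of A, C, G, T
#'   (columns whose operational outgroup is \code{?} are skipped upstream and
#'   contribute no statements).
#' @param zeros zeros convention, see Details.
#' @return list of recodings, each a list with elements \code{state},
#'   \code{ones} (integer taxon indices), \code{zeros} (integer taxon
#'   indices).  Empty when the column is constant at the outgroup state or
#'   entirely unscored.
#' @export
polarizeColumn <- function(column, outgroupState,
                           zeros = c("absence", "plesiomorphic")) {
  zeros <- match.arg(zeros)
  column <- toupper(column)
  if (!outgroupState %in% NUCLEOTIDES)
    stop("outgroup state must be one of A, C, G, T")
  scored <- column %in% NUCLEOTIDES
  derived <- setdiff(unique(column[scored]), outgroupState)
  lapply(derived, function(s) {
    list(state = s,
         ones = which(column == s),
         zeros = if (zeros == "absence") which(scored & column != s)
                 else which(column == outgroupState))
  })
}

#' Enumerate the three-taxon statements of a binary recoding
#'
#' Emits the statement ij|k for every unordered pair \{i, j\} of apomorphic
#' taxa and every taxon k in the zeros set; the count is
#' \eqn{\binom{n_1}{2} n_0}.
#'
#' @param recoding one element of the list returned by [polarizeColumn()].
#' @return data.frame with integer columns \code{i}, \code{j}, \code{k}
#'   (\code{i < j}).
#' @export
enumerateStatements <- function(recoding) {
  ones <- sort(recoding$ones)
  zeros <- recoding$zeros
  if (length(ones) < 2 || length(zeros) < 1)
    return(data.frame(i = integer(), j = integer(), k = integer()))
  pr <- combn(ones, 2)
  n1 <- ncol(pr); n0 <- length(zeros)
  data.frame(i = rep(pr[1, ], times = n0),
             j = rep(pr[2, ], times = n0),
             k = rep(zeros, each = n1))
}

#' Encode a polarized DNA matrix as a three-taxon-statement matrix
#'
#' Applies [polarizeColumn()] and [enumerateStatements()] to every column and
#' merges identical statements, recording multiplicities (uniform weight 1
#' per occurrence).  Columns whose outgroup symbol is not a plain nucleotide
#' contribute nothing (no polarity).  The operational outgroup itself is an
#' implicit all-plesiomorphic row of the result and never appears inside a
#' statement.
#'
#' @param aln ingroup alignment (\linkS4class{DnaAlignment} or character
#'   matrix); must not contain the outgroup label.
#' @param outgroupSeq operational outgroup symbols, one per column (vector or
#'   single string).
#' @param zeros zeros convention, see [polarizeColumn()].
#' @param outgroupLabel label reserved for the implicit outgroup row.
#' @param provenance if TRUE, keep the full per-occurrence statement table
#'   (memory-hungry on large matrices; the deduplicated matrix and the
#'   per-recoding summary are always kept).
#' @return a \linkS4class{TsMatrix}.
#' @export
encodeMatrix <- function(aln, outgroupSeq, zeros = c("absence", "plesiomorphic"),
                         outgroupLabel = "OP_OUTGROUP", provenance = FALSE) {
  zeros <- match.arg(zeros)
  mat <- if (is(aln, "DnaAlignment")) aln@seqs else aln
  if (length(outgroupSeq) == 1 && nchar(outgroupSeq[1]) > 1)
    outgroupSeq <- strsplit(outgroupSeq, "")[[1]]
  outgroupSeq <- toupper(outgroupSeq)
  if (length(outgroupSeq) != ncol(mat))
    stop(sprintf("outgroup sequence has %d symbols but the matrix has %d columns",
                 length(outgroupSeq), ncol(mat)))
  tx <- rownames(mat)
  nT <- length(tx)
  keyChunks <- vector("list", ncol(mat))
  recodings <- vector("list", ncol(mat))
  provChunks <- if (provenance) vector("list", ncol(mat)) else NULL
  for (col in seq_len(ncol(mat))) {
    og <- outgroupSeq[col]
    if (!og %in% NUCLEOTIDES) next
    recs <- polarizeColumn(mat[, col], og, zeros)
    if (!length(recs)) next
    colKeys <- lapply(recs, function(r) {
      st <- enumerateStatements(r)
      if (provenance && nrow(st))
        provChunks[[col]][[r$state]] <<-
          data.frame(column = col, state = r$state,
                     i = st$i, j = st$j, k = st$k)
      ((st$i - 1) * nT + (st$j - 1)) * nT + (st$k - 1)
    })
    recodings[[col]] <- data.frame(
      column = col,
      state = vapply(recs, `[[`, "", "state"),
      n1 = vapply(recs, function(r) length(r$ones), 0L),
      n0 = vapply(recs, function(r) length(r$zeros), 0L),
      n = lengths(colKeys))
    keyChunks[[col]] <- unlist(colKeys, use.names = FALSE)
  }
  keys <- unlist(keyChunks, use.names = FALSE)
  if (is.null(keys)) keys <- numeric()
  if (length(keys)) {
    mult <- rowsum(rep(1, length(keys)), keys)
    uk <- as.numeric(rownames(mult))
    st <- data.frame(i = as.integer(uk %/% (nT * nT)) + 1L,
                     j = as.integer((uk %/% nT) %% nT) + 1L,
                     k = as.integer(uk %% nT) + 1L,
                     mult = as.numeric(mult))
    st <- st[order(st$i, st$j, st$k), , drop = FALSE]
    rownames(st) <- NULL
  } else {
    st <- data.frame(i = integer(), j = integer(), k = integer(),
                     mult = numeric())
  }
  rec <- do.call(rbind, recodings[!vapply(recodings, is.null, TRUE)])
  if (is.null(rec))
    rec <- data.frame(column = integer(), state = character(),
                      n1 = integer(), n0 = integer(), n = integer())
  emptyProv <- data.frame(column = integer(), state = character(),
                          i = integer(), j = integer(), k = integer())
  prov <- if (provenance && length(provChunks)) {
    pm <- do.call(rbind, unlist(provChunks, recursive = FALSE))
    if (is.null(pm)) emptyProv else pm
  } else emptyProv
  new("TsMatrix", taxa = tx, outgroupLabel = outgroupLabel, statements = st,
      nStatements = length(keys), recodings = rec, provenance = prov,
      convention = zeros)
}

#' Write the expanded binary statement matrix as NEXUS
#'
#' One binary character per statement occurrence (uniform weighting written
#' out literally), with 1 at i and j, 0 at k, 0 for the appended
#' all-plesiomorphic operational outgroup row, and \code{?} elsewhere.
#' Characters are streamed in interleaved blocks so the expanded matrix is
#' never materialized in memory.
#'
#' @param ts a \linkS4class{TsMatrix}.
#' @param path output path.
#' @param blockSize characters per interleave block.
#' @export
writeTsNexus <- function(ts, path, blockSize = 1000L) {
  st <- ts@statements
  occ <- st[rep(seq_len(nrow(st)), times = st$mult), c("i", "j", "k"),
            drop = FALSE]
  nT <- length(ts@taxa)
  labels <- c(ts@taxa, ts@outgroupLabel)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#NEXUS", "BEGIN DATA;",
               sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nT + 1L, nrow(occ)),
               "FORMAT SYMBOLS=\"01\" MISSING=? GAP=- INTERLEAVE;",
               "MATRIX"), con)
  pad <- formatC(labels, width = max(nchar(labels)), flag = "-")
  nOcc <- nrow(occ)
  for (from in seq(1L, max(nOcc, 1L), by = blockSize)) {
    if (nOcc == 0) break
    to <- min(from + blockSize - 1L, nOcc)
    idx <- from:to
    block <- matrix("?", nT + 1L, length(idx))
    block[nT + 1L, ] <- "0"
    block[cbind(occ$i[idx], seq_along(idx))] <- "1"
    block[cbind(occ$j[idx], seq_along(idx))] <- "1"
    block[cbind(occ$k[idx], seq_along(idx))] <- "0"
    writeLines(sprintf("%s  %s", pad, apply(block, 1, paste, collapse = "")),
               con)
    writeLines("", con)
  }
  writeLines(c(";", "END;"), con)
  invisible(path)
}

#' Export deduplicated statements as TSV
#'
#' Columns: taxon labels of i, j, k, the multiplicity, and (when the matrix
#' was encoded with \code{provenance = TRUE}) a provenance string of
#' \code{column:state} occurrences.
#'
#' @param ts a \linkS4class{TsMatrix}.
#' @param path output path.
#' @export
writeStatementsTsv <- function(ts, path) {
  st <- ts@statements
  out <- data.frame(i = ts@taxa[st$i], j = ts@taxa[st$j], k = ts@taxa[st$k],
                    mult = st$mult)
  if (nrow(ts@provenance)) {
    pv <- ts@provenance
    pkey <- paste(pv$i, pv$j, pv$k)
    lab <- vapply(split(paste0(pv$column, ":", pv$state), pkey),
                  paste, character(1), collapse = ";")
    out$provenance <- unname(lab[paste(st$i, st$j, st$k)])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
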