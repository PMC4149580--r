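#' Construct a DnaAlignment
#'
#' Taxon labels are normalized by replacing internal whitespace with
#' underscores (comparison stays case-sensitive); sequence symbols are
#' uppercased and validated against the IUPAC alphabet plus \code{-} and
#' \code{?}.
#'
#' @param seqs character matrix (rows = taxa) or named character vector of
#'   sequence strings.
#' @param partition optional data.frame with columns \code{locus},
#'   \code{start}, \code{end} (0-based half-open).  Defaults to a single
#'   locus spanning all columns.
#' @return a \linkS4class{DnaAlignment}.
#' @export
dnaAlignment <- function(seqs, partition = NULL) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (is.null(names(seqs))) stop("sequence vector must be named by taxon")
    seqs <- do.call(rbind, lapply(strsplit(seqs, ""), identity))
  }
  mode(seqs) <- "character"
  seqs[] <- toupper(seqs)
  rownames(seqs) <- normalizeLabels(rownames(seqs))
  if (is.null(partition)) {
    partition <- if (ncol(seqs) == 0)
      data.frame(locus = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    else data.frame(locus = "locus1", start = 0L,
                    end = ncol(seqs), stringsAsFactors = FALSE)
  }
  new("DnaAlignment", seqs = seqs, partition = partition)
}

normalizeLabels <- function(x) gsub("[[:space:]]+", "_", trimws(x))

# informative alphabet error shared by the readers
checkSymbols <- function(mat) {
  bad <- which(!(mat %in% DNA_ALPHABET))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(mat))
    stop(sprintf("invalid symbol '%s' at taxon '%s', column %d",
                 mat[bad[1]], rownames(mat)[rc[1]], rc[2]), call. = FALSE)
  }
  invisible(mat)
}

#' Read an alignment from FASTA, relaxed PHYLIP, or NEXUS
#'
#' FASTA and relaxed PHYLIP (whitespace-delimited labels of any length,
#' sequential or interleaved) are parsed directly so that every symbol can be
#' validated; NEXUS character blocks are parsed through
#' \code{ape::read.nexus.data} (interleaving allowed; SETS/ASSUMPTIONS blocks
#' are ignored with a warning).  Lowercase input is uppercased; any symbol
#' outside the IUPAC alphabet plus \code{-}/\code{?} is rejected with the
#' offending taxon and column named.
#'
#' @param path file path.
#' @param format one of \code{"fasta"}, \code{"phylip"}, \code{"nexus"}.
#' @return a \linkS4class{DnaAlignment} with a single-locus partition.
#' @export
readAlignment <- function(path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  mat <- switch(format,
                fasta = parseFasta(path),
                phylip = parsePhylip(path),
                nexus = parseNexusChars(path))
  if (anyDuplicated(rownames(mat)))
    stop(sprintf("duplicate taxon label: %s",
                 rownames(mat)[duplicated(rownames(mat))][1]))
  checkSymbols(mat)
  dnaAlignment(mat)
}

parseFasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  labels <- normalizeLabels(sub("^>", "", lines[hdr]))
  starts <- hdr + 1L
  ends <- c(hdr[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (ends[i] < starts[i]) return("")
    paste(gsub("[[:space:]]", "", lines[starts[i]:ends[i]]), collapse = "")
  }, character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop(sprintf("ragged alignment: sequence lengths %s",
                 paste(unique(lens), collapse = ", ")))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- labels
  mat
}

parsePhylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]))
  if (length(dims) < 2 || anyNA(dims[1:2]))
    stop("malformed PHYLIP header in ", path)
  ntax <- dims[1]; nchr <- dims[2]
  body <- lines[-1]
  if (length(body) < ntax) stop("fewer sequence lines than taxa in ", path)
  labels <- character(ntax)
  chunks <- vector("list", ntax)
  for (i in seq_len(ntax)) {
    toks <- strsplit(trimws(body[i]), "[[:space:]]+")[[1]]
    labels[i] <- toks[1]
    chunks[[i]] <- paste(toks[-1], collapse = "")
  }
  extra <- body[-seq_len(ntax)]
  if (length(extra)) { # interleaved continuation blocks cycle through taxa
    for (r in seq_along(extra)) {
      i <- ((r - 1L) %% ntax) + 1L
      chunks[[i]] <- paste0(chunks[[i]], gsub("[[:space:]]", "", extra[r]))
    }
  }
  lens <- nchar(unlist(chunks))
  if (any(lens != nchr))
    stop(sprintf("ragged alignment: expected %d columns, got %s",
                 nchr, paste(unique(lens), collapse = ", ")))
  mat <- do.call(rbind, strsplit(toupper(unlist(chunks)), ""))
  rownames(mat) <- normalizeLabels(labels)
  mat
}

parseNexusChars <- function(path) {
  raw <- toupper(readLines(path, warn = FALSE))
  if (any(grepl("BEGIN[[:space:]]+(SETS|ASSUMPTIONS)", raw)))
    warning("SETS/ASSUMPTIONS blocks ignored")
  lst <- ape::read.nexus.data(path)
  mat <- do.call(rbind, lst)
  mat[] <- toupper(mat)
  rownames(mat) <- normalizeLabels(names(lst))
  mat
}

#' Write an alignment to FASTA, relaxed PHYLIP, or NEXUS
#'
#' Round-trip stable with [readAlignment()]: the symbol matrix is preserved
#' exactly, including gap \code{-} and missing \code{?}.
#'
#' @param aln a \linkS4class{DnaAlignment} (or character matrix).
#' @param path output file path.
#' @param format one of \code{"fasta"}, \code{"phylip"}, \code{"nexus"}.
#' @export
writeAlignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  format <- match.arg(format)
  mat <- if (is(aln, "DnaAlignment")) aln@seqs else aln
  seqs <- apply(mat, 1, paste, collapse = "")
  out <- switch(format,
    fasta = as.vector(rbind(paste0(">", rownames(mat)), seqs)),
    phylip = c(sprintf("%d %d", nrow(mat), ncol(mat)),
               sprintf("%s  %s", rownames(mat), seqs)),
    nexus = c("#NEXUS", "BEGIN DATA;",
              sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(mat), ncol(mat)),
              "FORMAT DATATYPE=DNA MISSING=? GAP=-;", "MATRIX",
              sprintf("%s  %s", rownames(mat), seqs), ";", "END;"))
  writeLines(out, path)
  invisible(path)
}

#' Concatenate per-locus alignments into a partitioned supermatrix
#'
#' Rows are the union of taxa over all parts (in order of first appearance);
#' a taxon absent from a locus is padded with \code{?} across that locus's
#' columns.  The returned alignment carries the locus partition map.
#'
#' @param parts a named list of \linkS4class{DnaAlignment} objects (or
#'   character matrices); names become locus names.
#' @return a \linkS4class{DnaAlignment} whose [partitionMap()] records each
#'   locus interval (0-based, half-open).
#' @export
concatSupermatrix <- function(parts) {
  if (!length(parts)) stop("need at least one locus")
  mats <- lapply(parts, function(p) if (is(p, "DnaAlignment")) p@seqs else p)
  widths <- vapply(mats, ncol, 0L)
  if (any(widths == 0))
    stop("zero-column locus: ", names(parts)[which(widths == 0)[1]])
  nm <- names(parts)
  if (is.null(nm)) nm <- paste0("locus", seq_along(parts))
  allTaxa <- unique(unlist(lapply(mats, rownames)))
  blocks <- lapply(mats, function(m) {
    out <- matrix("?", length(allTaxa), ncol(m),
                  dimnames = list(allTaxa, NULL))
    out[rownames(m), ] <- m
    out
  })
  ends <- cumsum(widths)
  partition <- data.frame(locus = nm, start = c(0L, ends[-length(ends)]),
                          end = ends, stringsAsFactors = FALSE)
  dnaAlignment(do.call(cbind, blocks), partition)
}

#' Subset an alignment to a set of taxa
#'
#' Rows are kept in their original order; columns are untouched (columns that
#' become constant are not recoded or dropped).
#'
#' @param aln a \linkS4class{DnaAlignment}.
#' @param keep character vector of taxon labels to retain.
#' @export
subsetTaxa <- function(aln, keep) {
  keep <- normalizeLabels(keep)
  unknown <- setdiff(keep, taxa(aln))
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  if (!length(keep)) stop("keep set must be nonempty")
  sel <- taxa(aln)[taxa(aln) %in% keep]
  new("DnaAlignment", seqs = aln@seqs[sel, , drop = FALSE],
      partition = aln@partition)
}

#' Append the operational outgroup as a terminal row
#'
#' @param aln a \linkS4class{DnaAlignment}.
#' @param seq consensus symbol vector of length \code{nColumns(aln)}.
#' @param label reserved taxon label for the operational outgroup.
#' @export
appendOutgroup <- function(aln, seq, label = "OP_OUTGROUP") {
  if (length(seq) == 1 && nchar(seq) > 1) seq <- strsplit(seq, "")[[1]]
  if (length(seq) != nColumns(aln)) stop("consensus length mismatch")
  if (label %in% taxa(aln)) stop("label already present: ", label)
  m <- rbind(aln@seqs, matrix(toupper(seq), 1))
  rownames(m) <- c(taxa(aln), label)
  new("DnaAlignment", seqs = m, partition = aln@partition)
}
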