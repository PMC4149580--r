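#' Build a simulation configuration
#'
#' Defaults emulate the structure of a multi-locus plastid supermatrix — ten
#' loci of a few hundred aligned columns each, a handful of designated
#' outgroup taxa, patchy per-taxon locus coverage and occasional short gap
#' runs — at a desk-scale taxon count.
#'
#' @param nTaxa total taxa (ingroup + outgroup).
#' @param nLoci number of loci.
#' @param locusLengths per-locus column counts (recycled to \code{nLoci}).
#' @param birthRate speciation rate of the pure-birth ingroup tree.
#' @param rates per-locus substitution rate scalings (recycled).
#' @param missingProb probability a taxon entirely lacks a given locus.
#' @param gapRate per-site probability of opening a short gap run.
#' @param nOutgroup outgroup taxa attached below the ingroup root.
#' @param seed mandatory integer seed.
#' @return a \linkS4class{SimConfig}.
#' @export
simConfig <- function(nTaxa = 40, nLoci = 10, locusLengths = 850,
                      birthRate = 1, rates = 1, missingProb = 0.15,
                      gapRate = 0.01, nOutgroup = 5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SimConfig", nTaxa = as.integer(nTaxa), nLoci = as.integer(nLoci),
      locusLengths = as.integer(rep_len(locusLengths, nLoci)),
      birthRate = as.numeric(birthRate),
      rates = as.numeric(rep_len(rates, nLoci)),
      missingProb = as.numeric(missingProb), gapRate = as.numeric(gapRate),
      nOutgroup = as.integer(nOutgroup), seed = as.integer(seed))
}

stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + stage) %% 2147483647L
}

#' Simulate a pure-birth tree with basal outgroups
#'
#' The ingroup is a pure-birth (Yule) tree; outgroup taxa are attached as a
#' basal ladder below the ingroup root, each on a long stem so the outgroup
#' is clearly divergent.  Branch lengths are in expected substitutions per
#' site before per-locus rate scaling.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a rooted binary \code{phylo} with tips \code{t01..} (ingroup) and
#'   \code{og1..} (outgroup).
#' @export
simulateTree <- function(config) {
  nIn <- config@nTaxa - config@nOutgroup
  withSeed(stageSeed(config@seed, 1L), {
    tr <- ape::rphylo(nIn, birth = config@birthRate, death = 0)
    tr$tip.label <- sprintf("t%02d", seq_len(nIn))
    height <- max(ape::node.depth.edgelength(tr))
    # ingroup crown depth 0.05 expected substitutions/site at rate 1:
    # plastid-like shallow divergence among congeners
    scale <- 0.05 / height
    tr$edge.length <- tr$edge.length * scale
    # successive speciations are separated by a minimum interval (5% of the
    # crown depth) so that every internal edge is resolvable in principle;
    # unresolvably short branches are a real-data complication the generator
    # deliberately excludes
    internal <- tr$edge[, 2] > length(tr$tip.label)
    tr$edge.length[internal] <- pmax(tr$edge.length[internal], 0.05 * 0.05)
    # outgroups diverge just below the ingroup root and are only moderately
    # divergent, so their majority consensus is a reliable polarity proxy
    nwk <- sub(";$", "", ape::write.tree(tr))
    for (i in seq_len(config@nOutgroup))
      nwk <- sprintf("(%s:%.6f,og%d:%.6f)", nwk, 0.005, i, 0.03 + 0.005 * i)
    ape::read.tree(text = paste0(nwk, ";"))
  })
}

#' Evolve a partitioned supermatrix along a tree
#'
#' Per-locus Jukes-Cantor evolution from random root sequences
#' (\code{phangorn::simSeq}), per-taxon locus dropout (the taxon is removed
#' from that locus, so concatenation pads it with \code{?}), and short
#' injected gap runs.  Loci are concatenated with [concatSupermatrix()].
#'
#' @param tree a \code{phylo} with branch lengths.
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{DnaAlignment} with the locus partition map.
#' @export
evolveSequences <- function(tree, config) {
  withSeed(stageSeed(config@seed, 2L), {
    parts <- vector("list", config@nLoci)
    names(parts) <- sprintf("locus%02d", seq_len(config@nLoci))
    dropout <- matrix(runif(length(tree$tip.label) * config@nLoci) <
                        config@missingProb,
                      length(tree$tip.label), config@nLoci,
                      dimnames = list(tree$tip.label, NULL))
    # a taxon must keep at least one locus
    allGone <- rowSums(!dropout) == 0
    dropout[allGone, 1] <- FALSE
    for (l in seq_len(config@nLoci)) {
      sim <- phangorn::simSeq(tree, l = config@locusLengths[l],
                              rate = config@rates[l])
      mat <- toupper(as.character(sim))
      mat <- injectGaps(mat, config@gapRate)
      keep <- rownames(mat)[!dropout[rownames(mat), l]]
      parts[[l]] <- mat[keep, , drop = FALSE]
    }
    concatSupermatrix(parts)
  })
}

injectGaps <- function(mat, gapRate) {
  if (gapRate <= 0) return(mat)
  nc <- ncol(mat)
  for (r in seq_len(nrow(mat))) {
    opens <- which(runif(nc) < gapRate / 4)  # runs average ~4 sites
    for (o in opens) {
      len <- sample(2:6, 1)
      mat[r, o:min(o + len - 1, nc)] <- "-"
    }
  }
  mat
}

#' Hand-built toy fixtures
#'
#' Deterministic small objects used throughout the test suite: (a) a 5-taxon
#' encoder toy whose statements are known by hand, (b) an 8-ingroup-taxon
#' zero-homoplasy matrix whose statements are all accommodated on its
#' generating tree, and (c) conflicting tree sets for consensus and supertree
#' exercises.
#'
#' @return named list with elements \code{encoderToy},
#'   \code{perfectEight}, \code{conflictSets}.
#' @export
fixtureToys <- function() {
  # (a) one informative column A C C G ? plus a duplicated column pair
  enc <- dnaAlignment(c(t1 = "AAA", t2 = "CGG", t3 = "CGG", t4 = "GAA",
                        t5 = "?AA"))
  encOut <- list(alignment = enc, outgroup = "AAA")

  # (b) perfect hierarchical characters on ((((a,b),c),d),((e,f),g),h)
  tree <- ape::read.tree(text = "(((((a,b),c),d),(((e,f),g),h)),og1,og2);")
  clades <- list(c("a", "b"), c("a", "b", "c"), c("a", "b", "c", "d"),
                 c("e", "f"), c("e", "f", "g"), c("e", "f", "g", "h"))
  tipnames <- c("a", "b", "c", "d", "e", "f", "g", "h", "og1", "og2")
  mat <- matrix("A", length(tipnames), length(clades),
                dimnames = list(tipnames, NULL))
  for (i in seq_along(clades)) mat[clades[[i]], i] <- "C"
  perfect <- list(alignment = dnaAlignment(mat),
                  outgroupTaxa = c("og1", "og2"), tree = tree)

  # (c) conflicting topologies on shared and overlapping leaf sets
  same <- asMultiPhylo(lapply(c("((a,b),(c,d),(e,f));",
                                "((a,c),(b,d),(e,f));",
                                "((a,b),(c,e),(d,f));"),
                              function(s) ape::read.tree(text = s)))
  overlapping <- asMultiPhylo(lapply(c("((a,b),(c,d),e);",
                                       "((c,d),(e,f),g);",
                                       "((a,b),(f,g),h);"),
                                     function(s) ape::read.tree(text = s)))
  list(encoderToy = encOut, perfectEight = perfect,
       conflictSets = list(sameLeaves = same, overlapping = overlapping))
}
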