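# Tree construction by direct edge-matrix surgery.  ape numbers tips
# 1..nTip and internal nodes nTip+1.., so inserting a leaf shifts every
# internal id by one; doing this in place is much faster than bind.tree.

startTriple <- function(labels) {
  structure(list(edge = cbind(rep(4L, 3), 1:3), tip.label = labels,
                 Nnode = 1L), class = "phylo")
}

insertTip <- function(tree, edgeRow, label) {
  nT <- length(tree$tip.label)
  E <- tree$edge
  E[E > nT] <- E[E > nT] + 1L
  newTip <- nT + 1L
  newNode <- nT + 1L + tree$Nnode + 1L
  oldChild <- E[edgeRow, 2]
  E[edgeRow, 2] <- newNode
  E <- rbind(E, c(newNode, oldChild), c(newNode, newTip))
  structure(list(edge = E, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode + 1L), class = "phylo")
}

# attach a tip as an extra child of an existing internal node (polytomy)
attachTipToNode <- function(tree, node, label) {
  nT <- length(tree$tip.label)
  E <- tree$edge
  E[E > nT] <- E[E > nT] + 1L
  node <- node + 1L
  E <- rbind(E, c(node, nT + 1L))
  structure(list(edge = E, tip.label = c(tree$tip.label, label),
                 Nnode = tree$Nnode), class = "phylo")
}

# graft a rooted subtree (phylo, or single label) onto an edge
insertClade <- function(tree, edgeRow, sub) {
  if (is.character(sub)) return(insertTip(tree, edgeRow, sub))
  nT <- length(tree$tip.label); nS <- length(sub$tip.label)
  E <- tree$edge
  E[E > nT] <- E[E > nT] + nS
  newNode <- nT + nS + tree$Nnode + 1L
  ES <- sub$edge
  tipS <- ES <= nS
  ES[tipS] <- ES[tipS] + nT
  ES[!tipS] <- ES[!tipS] - nS + newNode  # sub root nS+1 -> newNode+1
  oldChild <- E[edgeRow, 2]
  E[edgeRow, 2] <- newNode
  E <- rbind(E, c(newNode, oldChild), c(newNode, newNode + 1L), ES)
  structure(list(edge = E, tip.label = c(tree$tip.label, sub$tip.label),
                 Nnode = tree$Nnode + sub$Nnode + 1L), class = "phylo")
}

# SPR neighborhood on the stored (unrooted, basal multifurcation) tree; with
# tbr = TRUE the pruned clade is additionally rerooted at each of its tips
# before regrafting (TBR with limited reconnection distance).
sprNeighbors <- function(tree, tbr = FALSE) {
  nT <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= nT) tree$tip.label[child] else
      ape::extract.clade(tree, child)$tip.label
    if (nT - length(tips) < 3) next
    backbone <- ape::drop.tip(tree, tips)
    subs <- if (child <= nT) list(tips) else {
      cl <- ape::extract.clade(tree, child)
      if (tbr && length(cl$tip.label) >= 3) {
        un <- ape::unroot(cl)
        c(list(cl), lapply(cl$tip.label, function(tp)
          ape::root(un, outgroup = tp, resolve.root = TRUE)))
      } else list(cl)
    }
    for (sub in subs)
      for (f in seq_len(nrow(backbone$edge)))
        out[[length(out) + 1L]] <- insertClade(backbone, f, sub)
  }
  out
}

neighborFun <- function(swap) {
  switch(swap,
         none = function(tree) list(),
         nni = function(tree) {
           if (length(tree$tip.label) < 4) return(list())
           nb <- phangorn::nni(tree)
           lapply(seq_along(nb), function(i) nb[[i]]) # keep tip labels
         },
         spr = function(tree) sprNeighbors(tree, tbr = FALSE),
         tbr = function(tree) sprNeighbors(tree, tbr = TRUE))
}

# scoring closures -----------------------------------------------------------

makeScorer <- function(x) {
  if (is(x, "DnaAlignment") || is.matrix(x)) {
    mat <- coerceCharMatrix(x)
    bits <- symbolBits(mat)
    cp <- compressPatterns(bits)
    function(tree) {
      po <- ape::reorder.phylo(tree, "postorder")
      st <- cp$states[po$tip.label, , drop = FALSE]
      fitch_count_cpp(po$edge, length(po$tip.label), st, cp$weights)$total
    }
  } else if (is(x, "TsMatrix")) {
    st <- x@statements
    txa <- x@taxa
    og <- x@outgroupLabel
    function(tree) {
      if (is.null(tree$tip.label)) stop("tree has no tip labels")
      idx <- match(txa, tree$tip.label)
      ii <- idx[st$i]; jj <- idx[st$j]; kk <- idx[st$k]
      present <- !(is.na(ii) | is.na(jj) | is.na(kk))
      if (!any(present)) return(0)
      ogTip <- match(og, tree$tip.label)
      if (is.na(ogTip)) ogTip <- 0L
      viol <- ts_violations_cpp(tree$edge, length(tree$tip.label), ogTip,
                                ii[present], jj[present], kk[present])
      sum(st$mult[present]) + sum(st$mult[present][viol])
    }
  } else stop("cannot score objects of class ", class(x)[1])
}

searchTips <- function(x) {
  if (is(x, "TsMatrix")) c(x@outgroupLabel, x@taxa)
  else rownames(coerceCharMatrix(x))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv))
  }
  set.seed(seed)
  expr
}

# steepest-descent branch swapping with bounded exploration of equal-score
# plateaus: every pooled tree's neighborhood is expanded once, descending
# whenever any neighbor improves, so optima one plateau step away are found
swapDescent <- function(tree, score, scorer, neighbors, maxTrees) {
  pool <- list(tree)
  keys <- canonicalTreeKey(tree)
  bestScore <- score
  frontier <- 1L
  while (frontier <= length(pool)) {
    nb <- neighbors(pool[[frontier]])
    frontier <- frontier + 1L
    if (!length(nb)) next
    sc <- vapply(nb, scorer, numeric(1))
    mn <- min(sc)
    if (mn < bestScore - 1e-9) {
      best <- nb[[which.min(sc)]]
      bestScore <- mn
      pool <- list(best)
      keys <- canonicalTreeKey(best)
      frontier <- 1L
    } else {
      for (i in which(abs(sc - bestScore) < 1e-9)) {
        if (length(pool) >= maxTrees) break
        k <- canonicalTreeKey(nb[[i]])
        if (!(k %in% keys)) {
          pool <- c(pool, nb[i])
          keys <- c(keys, k)
        }
      }
    }
  }
  list(trees = pool, score = bestScore)
}

#' Heuristic maximum-parsimony search
#'
#' Random-addition starting trees (greedy stepwise insertion) followed by
#' branch swapping to a local optimum; equally optimal distinct trees are
#' pooled across replicates.  Conventional DNA matrices are scored by Fitch
#' parsimony; three-taxon-statement matrices by the statement accommodation
#' rule (Wagner and Fitch coincide for binary characters), with the
#' operational outgroup placed in the starting triple of every replicate so
#' the polarity leaf is always present.  Deterministic under a fixed seed.
#'
#' @param x a \linkS4class{DnaAlignment} or \linkS4class{TsMatrix}.
#' @param nAdditionReplicates number of random-addition replicates.
#' @param maxTreesPerReplicate cap on equally optimal trees kept per
#'   replicate.
#' @param swap branch-swapping level: \code{"nni"}, \code{"spr"} (default),
#'   \code{"tbr"} (SPR plus rerooting of the pruned clade at each of its
#'   tips), or \code{"none"}.
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return a \linkS4class{ParsimonySearch}.
#' @export
mpSearch <- function(x, nAdditionReplicates = 10, maxTreesPerReplicate = 10,
                     swap = c("spr", "nni", "tbr", "none"), seed = 1L) {
  swap <- match.arg(swap)
  if (nAdditionReplicates < 1 || maxTreesPerReplicate < 1)
    stop("search parameters out of range")
  tips <- searchTips(x)
  if (length(tips) < 4) stop("need at least 4 taxa")
  if (is(x, "TsMatrix") && x@nStatements == 0)
    stop("empty statement matrix")
  scorer <- makeScorer(x)
  neighbors <- neighborFun(swap)
  isTs <- is(x, "TsMatrix")
  pool <- list(); poolScore <- Inf
  withSeed(seed, {
    for (rep in seq_len(nAdditionReplicates)) {
      ord <- if (isTs) c(tips[1], sample(tips[-1])) else sample(tips)
      tr <- startTriple(ord[1:3])
      for (lab in ord[-(1:3)]) {
        cands <- lapply(seq_len(nrow(tr$edge)), function(e)
          insertTip(tr, e, lab))
        sc <- vapply(cands, scorer, numeric(1))
        tr <- cands[[which.min(sc)]]
      }
      res <- swapDescent(tr, scorer(tr), scorer, neighbors,
                         maxTreesPerReplicate)
      if (res$score < poolScore - 1e-9) {
        pool <- res$trees; poolScore <- res$score
      } else if (abs(res$score - poolScore) < 1e-9) {
        pool <- c(pool, res$trees)
      }
    }
  })
  keys <- vapply(pool, canonicalTreeKey, character(1))
  pool <- pool[!duplicated(keys)]
  buildSearchResult(x, pool, poolScore, seed,
                    params = list(nAdditionReplicates = nAdditionReplicates,
                                  maxTreesPerReplicate = maxTreesPerReplicate,
                                  swap = swap),
                    kind = if (isTs) "ts" else "dna")
}

buildSearchResult <- function(x, trees, score, seed, params, kind) {
  trees <- lapply(trees, function(tr) {
    tr <- ape::reorder.phylo(tr, "cladewise")
    tr
  })
  class(trees) <- "multiPhylo"
  if (is(x, "TsMatrix")) {
    e <- tsEnsembleCiRi(x@nStatements, score)
    stats <- list(nStatements = x@nStatements,
                  violations = score - x@nStatements)
  } else {
    cs <- charStats(x, trees[[1]])
    e <- ensembleCiRi(cs, length = score)
    stats <- list(sumMin = sum(cs$minSteps), sumMax = sum(cs$maxSteps))
  }
  new("ParsimonySearch", trees = trees, score = score, ci = e$ci, ri = e$ri,
      seed = as.integer(seed), params = params, kind = kind, stats = stats)
}

#' Exhaustive parsimony search
#'
#' Enumerates every unrooted topology (through \code{phangorn::allTrees}) and
#' returns the global optima.  Intended as an oracle for small problems; at
#' most 9 leaves (for a statement matrix: ingroup taxa plus the operational
#' outgroup leaf).
#'
#' @inheritParams mpSearch
#' @param maxTrees cap on the number of optimal trees returned.
#' @export
exactSearch <- function(x, maxTrees = 1000L, seed = 1L) {
  tips <- searchTips(x)
  n <- length(tips)
  if (n > 9) stop("too many taxa for exhaustive enumeration; use mpSearch")
  if (n < 4) stop("need at least 4 taxa")
  scorer <- makeScorer(x)
  trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = tips)
  # note: compact multiPhylo stores tip labels in an attribute; always index
  # with [[ so each tree carries its labels
  sc <- vapply(seq_along(trees), function(i) scorer(trees[[i]]), numeric(1))
  best <- which(abs(sc - min(sc)) < 1e-9)
  buildSearchResult(x, lapply(head(best, maxTrees), function(i) trees[[i]]),
                    min(sc), seed,
                    params = list(enumerated = length(trees)), kind = "exact")
}

#' Jackknife clade support
#'
#' Each replicate deletes \code{round(deleteFraction * nchar)} characters
#' without replacement (alignment columns, or expanded statement occurrences
#' of a \linkS4class{TsMatrix}, honouring multiplicities), reruns the search,
#' and records the clades of the replicate's strict consensus; support is the
#' percentage of replicates containing each clade.
#'
#' @param x a \linkS4class{DnaAlignment} or \linkS4class{TsMatrix}.
#' @param reps number of replicates.
#' @param deleteFraction fraction of characters deleted per replicate, in
#'   [0, 1).
#' @param searchParams list of arguments passed to [mpSearch()].
#' @param seed integer seed.
#' @return named numeric vector of percent support per clade (names are the
#'   clade's taxa joined by \code{+}), with attribute \code{"reps"}.
#' @export
jackknifeSupport <- function(x, reps = 100, deleteFraction = 0.37,
                             searchParams = list(nAdditionReplicates = 2,
                                                 maxTreesPerReplicate = 5,
                                                 swap = "nni"),
                             seed = 1L) {
  if (deleteFraction < 0 || deleteFraction >= 1)
    stop("deleteFraction must be in [0, 1)")
  isTs <- is(x, "TsMatrix")
  counts <- new.env(parent = emptyenv())
  withSeed(seed, {
    for (r in seq_len(reps)) {
      xr <- deleteCharacters(x, deleteFraction, isTs)
      sr <- do.call(mpSearch, c(list(xr), searchParams,
                                list(seed = seed + r)))
      cons <- if (length(bestTrees(sr)) > 1)
        strictConsensus(bestTrees(sr), mode = "unrooted")
      else bestTrees(sr)[[1]]
      for (key in splitKeys(cons, "unrooted")) {
        prev <- if (is.null(counts[[key]])) 0 else counts[[key]]
        assign(key, prev + 1, envir = counts)
      }
    }
  })
  keys <- ls(counts)
  support <- vapply(keys, function(k) 100 * counts[[k]] / reps, numeric(1))
  allTaxa <- searchTips(x)
  names(support) <- vapply(strsplit(keys, "\r", fixed = TRUE), function(s) {
    comp <- setdiff(allTaxa, s)  # label each clade by its smaller side
    side <- if (length(comp) < length(s)) sort(comp) else s
    paste(side, collapse = "+")
  }, character(1))
  support <- sort(support, decreasing = TRUE)
  attr(support, "reps") <- reps
  support
}

deleteCharacters <- function(x, fraction, isTs) {
  if (!isTs) {
    ncols <- nColumns(x)
    drop <- round(fraction * ncols)
    if (drop == 0) return(x)
    keep <- sort(sample.int(ncols, ncols - drop))
    dnaAlignment(x@seqs[, keep, drop = FALSE])
  } else {
    st <- x@statements
    occ <- rep(seq_len(nrow(st)), times = st$mult)
    drop <- round(fraction * length(occ))
    if (drop == 0) return(x)
    kept <- occ[-sample.int(length(occ), drop)]
    mult <- tabulate(kept, nbins = nrow(st))
    st2 <- st[mult > 0, , drop = FALSE]
    st2$mult <- mult[mult > 0]
    rownames(st2) <- NULL
    new("TsMatrix", taxa = x@taxa, outgroupLabel = x@outgroupLabel,
        statements = st2, nStatements = sum(st2$mult),
        recodings = x@recodings[0, ], provenance = x@provenance[0, ],
        convention = x@convention)
  }
}
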