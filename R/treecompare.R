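# descendant leaf-label sets per node (tips and internal nodes)
cladeSets <- function(tree) {
  nT <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", nT + tree$Nnode)
  for (i in seq_len(nT)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

# Canonical string keys of a tree's nontrivial bipartitions (unrooted mode:
# each split is represented by the side not containing the reference leaf,
# the lexicographically first label) or rooted clusters (internal nodes below
# the root).  Taxa within a key are sorted and joined by "\r".
splitKeys <- function(tree, mode = c("unrooted", "rooted")) {
  mode <- match.arg(mode)
  nT <- length(tree$tip.label)
  if (nT < 4 && mode == "unrooted") return(character())
  all <- sort(tree$tip.label)
  sets <- cladeSets(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1]
  keys <- character()
  for (v in setdiff(nT + seq_len(tree$Nnode), root)) {
    s <- sets[[v]]
    if (mode == "rooted") {
      if (length(s) >= 2 && length(s) <= nT - 1)
        keys <- c(keys, paste(sort(s), collapse = "\r"))
    } else {
      side <- if (all[1] %in% s) setdiff(all, s) else s
      if (length(side) >= 2 && length(side) <= nT - 2)
        keys <- c(keys, paste(sort(side), collapse = "\r"))
    }
  }
  unique(keys)
}

# topology identity key for deduplication of equally optimal trees
canonicalTreeKey <- function(tree) {
  paste(c(sort(tree$tip.label), sort(splitKeys(tree, "unrooted"))),
        collapse = "|")
}

resolveMode <- function(trees, mode) {
  if (mode != "auto") return(mode)
  if (all(vapply(trees, ape::is.rooted, TRUE))) "rooted" else "unrooted"
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference between the bipartition sets (unrooted
#' mode) or rooted cluster sets (rooted mode) of two trees on the same
#' leaves.  With \code{mode = "auto"}, rooted-cluster RF is used when both
#' trees are rooted and split RF otherwise.
#'
#' @param t1,t2 \code{phylo} objects with identical leaf sets.
#' @param mode \code{"auto"}, \code{"unrooted"}, or \code{"rooted"}.
#' @return integer distance.
#' @export
rfDistance <- function(t1, t2, mode = c("auto", "unrooted", "rooted")) {
  mode <- match.arg(mode)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ; restrict the trees to shared leaves first")
  mode <- resolveMode(list(t1, t2), mode)
  k1 <- splitKeys(t1, mode); k2 <- splitKeys(t2, mode)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

countClades <- function(trees, mode) {
  tab <- table(unlist(lapply(trees, splitKeys, mode = mode)))
  stats::setNames(as.integer(tab), names(tab))
}

keySet <- function(key) strsplit(key, "\r", fixed = TRUE)[[1]]

laminarCompatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

# build a tree from a laminar family of clusters over `labels`; in unrooted
# mode the reference leaf (first sorted label) sits at the root beside the
# top-level clusters, which reproduces the intended unrooted topology
buildTreeFromClusters <- function(clusters, labels) {
  sets <- lapply(clusters, keySet)
  sets <- sets[order(-lengths(sets))]
  nodes <- c(list(sort(labels)), sets, as.list(sort(labels)))
  parent <- integer(length(nodes)); parent[1] <- 0L
  for (i in seq_along(nodes)[-1]) {
    best <- 1L
    for (j in seq_along(nodes)) {
      if (j == i) next
      if (length(nodes[[j]]) > length(nodes[[i]]) &&
          all(nodes[[i]] %in% nodes[[j]]) &&
          length(nodes[[j]]) < length(nodes[[best]]))
        best <- j
      else if (length(nodes[[j]]) == length(nodes[[i]]) && j < i &&
               setequal(nodes[[i]], nodes[[j]]))
        best <- j  # duplicate cluster guard (should not occur)
    }
    parent[i] <- best
  }
  children <- split(seq_along(nodes)[-1], parent[-1])
  newick <- function(i) {
    if (length(nodes[[i]]) == 1) return(nodes[[i]])
    kids <- children[[as.character(i)]]
    kids <- kids[order(vapply(kids, function(k) min(nodes[[k]]), ""))]
    paste0("(", paste(vapply(kids, newick, ""), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(newick(1L), ";"))
}

consensusFromSelection <- function(trees, select, mode) {
  trees <- asMultiPhylo(trees)
  mode <- resolveMode(trees, mode)
  labels <- trees[[1]]$tip.label
  for (t in trees) if (!setequal(t$tip.label, labels))
    stop("consensus requires identical leaf sets")
  counts <- countClades(trees, mode)
  keep <- names(counts)[select(counts, length(trees))]
  buildTreeFromClusters(keep, labels)
}

#' Strict and majority-rule consensus trees
#'
#' Strict consensus keeps the clades present in every tree; majority-rule
#' keeps those in more than \code{threshold} of the trees (clades at exactly
#' the threshold are excluded).
#'
#' @param trees a \code{multiPhylo} (or list of \code{phylo}) on one leaf set.
#' @param mode \code{"auto"}, \code{"unrooted"}, or \code{"rooted"}.
#' @return a \code{phylo}.
#' @export
strictConsensus <- function(trees, mode = c("auto", "unrooted", "rooted")) {
  consensusFromSelection(trees, function(counts, k) counts == k,
                         match.arg(mode))
}

#' @rdname strictConsensus
#' @param threshold majority threshold in [0.5, 1).
#' @export
majorityConsensus <- function(trees, threshold = 0.5,
                              mode = c("auto", "unrooted", "rooted")) {
  if (threshold < 0.5 || threshold >= 1) stop("threshold must be in [0.5, 1)")
  consensusFromSelection(trees,
                         function(counts, k) counts > threshold * k + 1e-9,
                         match.arg(mode))
}

#' Robinson-Foulds median consensus
#'
#' The tree minimizing the total RF distance to the input profile.  The total
#' distance decomposes linearly over the candidate tree's clades: a clade
#' occurring in more than half of the inputs lowers the total, one in fewer
#' raises it, and one in exactly half is neutral.  All majority clades are
#' mutually compatible, so the optimum is computed exactly at any size as the
#' majority-rule consensus, optionally completed (tie-break toward
#' resolution) by greedily adding compatible exactly-half clades in
#' deterministic order.
#'
#' @inheritParams strictConsensus
#' @param resolveTies add compatible clades occurring in exactly half of the
#'   inputs (score-neutral, more resolved) instead of collapsing them.
#' @return list with elements \code{tree} and \code{score} (the minimal total
#'   RF distance, reported from an explicit re-evaluation).
#' @export
rfMedian <- function(trees, mode = c("auto", "unrooted", "rooted"),
                     resolveTies = TRUE) {
  trees <- asMultiPhylo(trees)
  mode <- resolveMode(trees, match.arg(mode))
  if (length(trees) == 1)
    return(list(tree = trees[[1]], score = 0))
  labels <- trees[[1]]$tip.label
  for (t in trees) if (!setequal(t$tip.label, labels))
    stop("rfMedian requires identical leaf sets")
  counts <- countClades(trees, mode)
  k <- length(trees)
  chosen <- names(counts)[2 * counts > k]
  if (resolveTies) {
    ties <- sort(names(counts)[2 * counts == k])
    sets <- lapply(chosen, keySet)
    for (key in ties) {
      s <- keySet(key)
      if (all(vapply(sets, laminarCompatible, TRUE, b = s))) {
        chosen <- c(chosen, key)
        sets <- c(sets, list(s))
      }
    }
  }
  med <- buildTreeFromClusters(chosen, labels)
  score <- sum(vapply(trees, rfDistance, numeric(1), t1 = med, mode = mode))
  list(tree = med, score = score)
}

# every unrooted topology (polytomies included) on the given labels, by
# recursive leaf addition: each tree on n-1 labels extends uniquely into each
# tree on n by inserting the new leaf on an edge or attaching it to an
# internal node
allTopologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  trees <- list(startTriple(labels[1:3]))
  for (i in seq_along(labels)[-(1:3)]) {
    lab <- labels[i]
    nxt <- vector("list", 0)
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge)))
        nxt[[length(nxt) + 1L]] <- insertTip(tr, e, lab)
      nT <- length(tr$tip.label)
      for (v in nT + seq_len(tr$Nnode))
        nxt[[length(nxt) + 1L]] <- attachTipToNode(tr, v, lab)
    }
    trees <- nxt
  }
  trees
}

contractEdge <- function(tree, e) {
  E <- tree$edge
  ch <- E[e, 2]; p <- E[e, 1]
  nT <- length(tree$tip.label)
  if (ch <= nT) stop("cannot contract a pendant edge")
  E[E[, 1] == ch, 1] <- p
  E <- E[-e, , drop = FALSE]
  E[E > ch] <- E[E > ch] - 1L
  structure(list(edge = E, tip.label = tree$tip.label,
                 Nnode = tree$Nnode - 1L), class = "phylo")
}

#' Robinson-Foulds supertree
#'
#' A tree on the union of the input leaf sets minimizing the summed RF
#' distance between each input and the supertree restricted to that input's
#' leaves.  For small unions (at most \code{exactLimit} leaves) every
#' topology, polytomies included, is enumerated and the optimum is exact;
#' larger problems use a greedy construction (largest input as backbone, best
#' insertion point per remaining leaf) refined by leaf reinsertion and edge
#' contraction moves.  Ties prefer the most resolved candidate, then
#' canonical key order.
#'
#' @param trees \code{multiPhylo} on overlapping leaf sets; the overlap graph
#'   must be connected.
#' @param mode \code{"auto"}, \code{"unrooted"}, or \code{"rooted"}.
#' @param exactLimit union size up to which exhaustive enumeration is used.
#' @return list with elements \code{tree} and \code{score}.
#' @export
rfSupertree <- function(trees, mode = c("auto", "unrooted", "rooted"),
                        exactLimit = 7) {
  trees <- asMultiPhylo(trees)
  mode <- resolveMode(trees, match.arg(mode))
  if (length(trees) == 1)
    return(list(tree = trees[[1]], score = 0))
  leafSets <- lapply(trees, `[[`, "tip.label")
  union <- sort(unique(unlist(leafSets)))
  checkOverlapConnected(leafSets)
  if (all(vapply(leafSets, setequal, TRUE, y = union)))
    return(rfMedian(trees, mode))
  scoreSuper <- function(S) {
    sum(vapply(trees, function(t) {
      if (length(t$tip.label) < 3) return(0)
      rfDistance(ape::keep.tip(S, t$tip.label), t, mode)
    }, numeric(1)))
  }
  if (length(union) <= exactLimit) {
    cands <- allTopologies(union)
    sc <- vapply(cands, scoreSuper, numeric(1))
    best <- which(abs(sc - min(sc)) < 1e-9)
    # most resolved, then canonical order
    res <- vapply(cands[best], function(t) t$Nnode, 0L)
    best <- best[res == max(res)]
    keys <- vapply(cands[best], canonicalTreeKey, character(1))
    return(list(tree = cands[[best[order(keys)[1]]]], score = min(sc)))
  }
  greedySupertree(trees, leafSets, union, scoreSuper)
}

checkOverlapConnected <- function(leafSets) {
  groups <- leafSets
  repeat {
    merged <- FALSE
    for (i in seq_along(groups)) {
      if (i >= length(groups)) break
      for (j in (i + 1):length(groups)) {
        if (length(intersect(groups[[i]], groups[[j]]))) {
          groups[[i]] <- union(groups[[i]], groups[[j]])
          groups[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  if (length(groups) > 1)
    stop("input trees do not overlap pairwise into a connected set")
  invisible(TRUE)
}

greedySupertree <- function(trees, leafSets, union, scoreSuper) {
  # partial objective over inputs sharing >= 3 leaves with the candidate
  partialScore <- function(S) {
    sum(vapply(trees, function(t) {
      shared <- intersect(t$tip.label, S$tip.label)
      if (length(shared) < 3) return(0)
      rfDistance(ape::keep.tip(S, shared), ape::keep.tip(t, shared), "unrooted")
    }, numeric(1)))
  }
  sizes <- lengths(leafSets)
  current <- trees[[which.max(sizes)]]
  remaining <- setdiff(union, current$tip.label)
  freq <- table(unlist(leafSets))
  remaining <- remaining[order(-as.integer(freq[remaining]), remaining)]
  for (lab in remaining) {
    cands <- lapply(seq_len(nrow(current$edge)), function(e)
      insertTip(current, e, lab))
    sc <- vapply(cands, partialScore, numeric(1))
    current <- cands[[which.min(sc)]]
  }
  best <- current; bestScore <- scoreSuper(best)
  for (iter in 1:10) {
    improved <- FALSE
    for (lab in sort(best$tip.label)) {   # leaf reinsertion
      base <- ape::drop.tip(best, lab)
      if (is.null(base) || length(base$tip.label) < 3) next
      cands <- lapply(seq_len(nrow(base$edge)), function(e)
        insertTip(base, e, lab))
      sc <- vapply(cands, scoreSuper, numeric(1))
      if (min(sc) < bestScore - 1e-9) {
        best <- cands[[which.min(sc)]]; bestScore <- min(sc); improved <- TRUE
      }
    }
    nT <- length(best$tip.label)          # edge contraction
    for (e in rev(seq_len(nrow(best$edge)))) {
      if (best$edge[e, 2] <= nT) next
      cand <- contractEdge(best, e)
      sc <- scoreSuper(cand)
      if (sc < bestScore - 1e-9) {
        best <- cand; bestScore <- sc; improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = best, score = bestScore)
}
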