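# Independent brute-force oracles and small generators used across the suite.
# These deliberately re-derive everything from first principles (own symbol
# table, own split extraction via ape::prop.part, exhaustive enumeration)
# rather than calling the package's own machinery.

ORACLE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                 R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                 B = 14L, D = 13L, H = 11L, V = 7L,
                 N = 15L, "-" = 15L, "?" = 15L)

randomMatrix <- function(n, m, missing = 0.1,
                         alphabet = c("A", "C", "G", "T")) {
  syms <- c(alphabet, if (missing > 0) c("?", "-"))
  probs <- c(rep((1 - missing) / length(alphabet), length(alphabet)),
             if (missing > 0) rep(missing / 2, 2))
  mat <- matrix(sample(syms, n * m, TRUE, prob = probs), n, m)
  rownames(mat) <- sprintf("t%02d", seq_len(n))
  mat
}

# exact minimum-change count by enumerating every internal-state assignment;
# ambiguous/missing leaves pay 0 when the parent state lies in their set
bruteFitch <- function(tree, column) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  E <- po$edge
  Nn <- tree$Nnode
  A <- as.matrix(expand.grid(rep(list(1:4), Nn)))
  cost <- numeric(nrow(A))
  leafSet <- ORACLE_BITS[toupper(column[tree$tip.label])]
  for (e in seq_len(nrow(E))) {
    p <- E[e, 1]; ch <- E[e, 2]
    ps <- A[, p - n]
    if (ch <= n) {
      cost <- cost +
        as.numeric(bitwAnd(bitwShiftL(1L, ps - 1L), leafSet[ch]) == 0)
    } else {
      cost <- cost + as.numeric(ps != A[, ch - n])
    }
  }
  min(cost)
}

# direct per-column statement enumeration (triple loops, no dedup)
bruteStatements <- function(col, og, zeros = "absence") {
  col <- toupper(col)
  nuc <- c("A", "C", "G", "T")
  if (!og %in% nuc) return(matrix(integer(), 0, 3))
  scored <- col %in% nuc
  out <- list()
  for (s in setdiff(unique(col[scored]), og)) {
    ones <- which(col == s)
    zs <- if (zeros == "absence") which(scored & col != s)
          else which(col == og)
    if (length(ones) >= 2 && length(zs) >= 1)
      for (a in seq_along(ones)) for (b in seq_along(ones)) if (a < b)
        for (k in zs)
          out[[length(out) + 1L]] <- c(ones[a], ones[b], k)
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

# unrooted split keys through ape::prop.part (independent of splitKeys)
oracleSplits <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  n <- length(labs)
  ref <- sort(labs)[1]
  keys <- character()
  for (cl in pp) {
    side <- labs[cl]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) >= 2 && length(side) <= n - 2)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

oracleRF <- function(t1, t2) {
  a <- oracleSplits(t1); b <- oracleSplits(t2)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

splitCompatible <- function(a, b) {
  i <- length(intersect(a, b))
  i == 0 || i == length(a) || i == length(b)
}

allNontrivialSides <- function(labels) {
  rest <- sort(labels)[-1]
  n <- length(labels)
  unlist(lapply(2:(n - 2), function(k) combn(rest, k, simplify = FALSE)),
         recursive = FALSE)
}

# exact RF-median score: every unrooted topology (equivalently every
# pairwise-compatible split set) is enumerated
bruteMedianScore <- function(trees) {
  labels <- sort(trees[[1]]$tip.label)
  sides <- allNontrivialSides(labels)
  inputSets <- lapply(trees, oracleSplits)
  kcount <- table(unlist(inputSets))
  k <- length(trees)
  best <- sum(lengths(inputSets))  # the star tree
  recurse <- function(chosen, score, start) {
    if (score < best) best <<- score
    if (start > length(sides)) return()
    for (i in start:length(sides)) {
      s <- sides[[i]]
      if (all(vapply(chosen, splitCompatible, TRUE, b = s))) {
        cnt <- unname(kcount[paste(sort(s), collapse = "|")])
        if (is.na(cnt)) cnt <- 0
        recurse(c(chosen, list(s)), score + k - 2 * cnt, i + 1L)
      }
    }
  }
  recurse(list(), best, 1L)
  as.numeric(best)
}

# exact RF-supertree score over all topologies on the leaf union
bruteSupertreeScore <- function(trees) {
  union <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  sides <- allNontrivialSides(union)
  inputSets <- lapply(trees, oracleSplits)
  projectScore <- function(chosen) {
    tot <- 0
    for (ti in seq_along(trees)) {
      L <- trees[[ti]]$tip.label
      refL <- sort(L)[1]
      proj <- character()
      for (s in chosen) {
        a <- intersect(s, L); b <- setdiff(L, a)
        if (length(a) >= 2 && length(b) >= 2) {
          side <- if (refL %in% a) b else a
          proj <- c(proj, paste(sort(side), collapse = "|"))
        }
      }
      proj <- unique(proj)
      tot <- tot + length(setdiff(proj, inputSets[[ti]])) +
        length(setdiff(inputSets[[ti]], proj))
    }
    tot
  }
  best <- projectScore(list())
  recurse <- function(chosen, start) {
    if (start > length(sides)) return()
    for (i in start:length(sides)) {
      s <- sides[[i]]
      if (all(vapply(chosen, splitCompatible, TRUE, b = s))) {
        cand <- c(chosen, list(s))
        sc <- projectScore(cand)
        if (sc < best) best <<- sc
        recurse(cand, i + 1L)
      }
    }
  }
  recurse(list(), 1L)
  best
}

randomUnrootedTree <- function(labels) {
  ape::unroot(ape::rtree(length(labels), tip.label = sample(labels)))
}
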