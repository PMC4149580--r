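test_that("RF distance matches bipartition listings and known cases", {
  t1 <- ape::read.tree(text = "((a,b),c,(d,e));")
  t2 <- ape::read.tree(text = "((a,c),b,(d,e));")
  expect_equal(rfDistance(t1, t2), 2)
  expect_equal(rfDistance(t1, t1), 0)
  star <- ape::read.tree(text = "(a,b,c,d,e);")
  expect_equal(rfDistance(t1, star), 2)  # t1 has two internal edges
  set.seed(51)
  big <- ape::unroot(ape::rtree(12))
  expect_equal(rfDistance(big, ape::read.tree(
    text = paste0("(", paste(big$tip.label, collapse = ","), ");"))),
    12 - 3)
  expect_error(rfDistance(t1, ape::read.tree(text = "((a,b),c,(d,f));")),
               "leaf sets")
})

test_that("RF agrees with an independent implementation and is a metric", {
  set.seed(52)
  for (r in 1:15) {
    labs <- paste0("t", 1:8)
    a <- randomUnrootedTree(labs)
    b <- randomUnrootedTree(labs)
    c <- randomUnrootedTree(labs)
    expect_equal(rfDistance(a, b, "unrooted"), phangorn::RF.dist(a, b))
    expect_equal(rfDistance(a, b, "unrooted"), rfDistance(b, a, "unrooted"))
    expect_true(rfDistance(a, c, "unrooted") <=
                  rfDistance(a, b, "unrooted") + rfDistance(b, c, "unrooted"))
  }
})

test_that("rooted-cluster RF distinguishes rootings that split RF cannot", {
  r1 <- ape::read.tree(text = "(((a,b),c),d);")
  r2 <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(rfDistance(r1, r2, "unrooted"), 0)
  expect_gt(rfDistance(r1, r2, "rooted"), 0)
})

test_that("strict and majority consensus follow the counting rules", {
  one <- ape::read.tree(text = "((((a,b),c),d),e);")
  expect_equal(oracleRF(strictConsensus(c(one, one)), one), 0)

  two <- ape::read.tree(text = "((((b,c),a),d),e);")  # cherry differs
  sc <- strictConsensus(c(one, two), mode = "rooted")
  # exactly the conflicting node collapses: {a,b,c} survives, {a,b}/{b,c} go
  keys <- tritax:::splitKeys(sc, "rooted")
  expect_true(paste(sort(c("a", "b", "c")), collapse = "\r") %in% keys)
  expect_false(any(grepl("^a\rb$|^b\rc$", keys)))

  three <- c(one, one, two)
  mc <- majorityConsensus(three, mode = "rooted")
  expect_true(paste(c("a", "b"), collapse = "\r") %in%
                tritax:::splitKeys(mc, "rooted"))  # 2/3 > 0.5 retained
  # a clade in exactly half of the trees is excluded
  mc2 <- majorityConsensus(c(one, two), mode = "rooted")
  expect_false(paste(c("a", "b"), collapse = "\r") %in%
                 tritax:::splitKeys(mc2, "rooted"))
  # strict clades are a subset of majority clades
  set.seed(53)
  trees <- lapply(1:4, function(i) randomUnrootedTree(paste0("t", 1:7)))
  class(trees) <- "multiPhylo"
  expect_true(all(tritax:::splitKeys(strictConsensus(trees), "unrooted") %in%
                    tritax:::splitKeys(majorityConsensus(trees), "unrooted")))
})

test_that("the RF median consensus is exact", {
  one <- ape::read.tree(text = "((a,b),(c,d),(e,f));")
  md <- rfMedian(c(one, one, one))
  expect_equal(md$score, 0)
  expect_equal(oracleRF(md$tree, one), 0)

  two <- ape::read.tree(text = "((a,c),(b,d),(e,f));")
  md2 <- rfMedian(c(one, two))
  expect_equal(md2$score, rfDistance(one, two))

  set.seed(54)
  for (r in 1:10) {
    k <- sample(3:5, 1)
    trees <- lapply(seq_len(k), function(i) randomUnrootedTree(letters[1:6]))
    class(trees) <- "multiPhylo"
    md <- rfMedian(trees)
    expect_equal(md$score, bruteMedianScore(trees), info = paste("case", r))
    # never worse than the best input
    bestInput <- min(vapply(trees, function(t)
      sum(vapply(trees, rfDistance, numeric(1), t1 = t, mode = "unrooted")),
      numeric(1)))
    expect_true(md$score <= bestInput)
  }
})

test_that("the RF supertree handles identity, compatibility, and conflict", {
  fx <- fixtureToys()$conflictSets
  one <- fx$sameLeaves[[1]]
  expect_equal(rfSupertree(c(one))$score, 0)

  # two trees identical on their overlap: score-0 supertree displays both
  base <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  in1 <- ape::unroot(ape::keep.tip(base, c("a", "b", "c", "d", "e", "g")))
  in2 <- ape::unroot(ape::keep.tip(base, c("c", "d", "e", "f", "g", "h")))
  res <- rfSupertree(c(in1, in2))
  expect_equal(res$score, 0)
  expect_equal(rfDistance(ape::keep.tip(res$tree, in1$tip.label), in1), 0)
  expect_equal(rfDistance(ape::keep.tip(res$tree, in2$tip.label), in2), 0)

  expect_error(rfSupertree(c(ape::read.tree(text = "((a,b),c,d);"),
                             ape::read.tree(text = "((x,y),z,w);"))),
               "overlap")
})

test_that("exhaustive supertree scores match brute-force minima", {
  set.seed(55)
  union <- letters[1:6]
  for (r in 1:6) {
    trees <- lapply(1:4, function(i) {
      keep <- sample(union, sample(4:5, 1))
      ape::unroot(ape::keep.tip(randomUnrootedTree(union), keep))
    })
    # guarantee connectivity through two anchor taxa
    trees <- c(trees, list(randomUnrootedTree(union)))
    class(trees) <- "multiPhylo"
    res <- rfSupertree(trees)
    expect_equal(res$score, bruteSupertreeScore(trees),
                 info = paste("case", r))
  }
})
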