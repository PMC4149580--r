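test_that("Fitch lengths match hand-scored quartets", {
  col <- c(i = "C", j = "C", k = "A", og = "A")
  expect_equal(fitchLength(ape::read.tree(text = "((i,j),(k,og));"), col), 1)
  expect_equal(fitchLength(ape::read.tree(text = "((i,k),(j,og));"), col), 2)
  expect_error(fitchLength(ape::read.tree(text = "((i,j),(k,zz));"), col),
               "zz")
})

test_that("Fitch equals the exhaustive assignment minimum, polytomies included", {
  set.seed(41)
  for (r in 1:40) {
    n <- sample(5:8, 1)
    tr <- ape::rtree(n)
    if (r %% 3 == 0) tr <- ape::di2multi(tr, tol = 0.35)
    col <- setNames(sample(c("A", "C", "G", "T", "?", "R", "-"), n, TRUE),
                    tr$tip.label)
    expect_equal(fitchLength(tr, col), bruteFitch(tr, col),
                 info = paste("case", r))
  }
})

test_that("matrix Fitch length agrees with an independent implementation", {
  set.seed(42)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    mat <- randomMatrix(n, 60, missing = 0.15)
    tr <- ape::rtree(n, tip.label = sample(rownames(mat)))
    expect_equal(fitchLength(tr, mat),
                 phangorn::parsimony(tr, phangorn::phyDat(mat)))
  }
})

test_that("per-character minimum and maximum step counts use closed forms", {
  tr <- ape::rtree(5, tip.label = paste0("t", 1:5))
  mat <- matrix(c("A", "A", "C", "C", "G"), 5, 1,
                dimnames = list(paste0("t", 1:5), NULL))
  cs <- charStats(mat, tr)
  expect_equal(cs$minSteps, 2)
  expect_equal(cs$maxSteps, 3)
  expect_true(cs$minSteps <= cs$steps && cs$steps <= cs$maxSteps)

  set.seed(43)
  mat2 <- randomMatrix(7, 40, missing = 0.2)
  tr2 <- ape::rtree(7, tip.label = rownames(mat2))
  cs2 <- charStats(mat2, tr2)
  expect_true(all(cs2$minSteps <= cs2$steps))
  expect_true(all(cs2$steps <= cs2$maxSteps))
  e <- ensembleCiRi(cs2)
  expect_true(e$ci >= 0 && e$ci <= 1)
  expect_true(e$ri >= 0 && e$ri <= 1)

  # all-constant matrix: RI undefined
  const <- matrix("A", 5, 3, dimnames = list(paste0("t", 1:5), NULL))
  expect_warning(e2 <- ensembleCiRi(charStats(const, tr)), "undefined")
  expect_true(is.na(e2$ri))
})

test_that("uninformative characters leave RI unchanged", {
  set.seed(44)
  mat <- randomMatrix(7, 30, missing = 0)
  tr <- ape::rtree(7, tip.label = rownames(mat))
  ri1 <- ensembleCiRi(charStats(mat, tr))$ri
  autapo <- matrix("A", 7, 1, dimnames = list(rownames(mat), NULL))
  autapo[2, 1] <- "C"  # m = g = 1: uninformative
  ri2 <- ensembleCiRi(charStats(cbind(mat, autapo), tr))$ri
  expect_equal(ri1, ri2)
})

test_that("statement length follows the accommodation rule and its bounds", {
  fx <- fixtureToys()$perfectEight
  cons <- consensusSequence(fx$alignment, fx$outgroupTaxa)
  ing <- subsetTaxa(fx$alignment,
                    setdiff(taxa(fx$alignment), fx$outgroupTaxa))
  ts <- encodeMatrix(ing, cons)
  good <- ape::read.tree(
    text = "(((((a,b),c),d),(((e,f),g),h)),OP_OUTGROUP);")
  r <- tsLength(good, ts)
  expect_equal(r$violations, 0)
  expect_equal(r$length, nStatements(ts))
  star <- ape::read.tree(text = "(a,b,c,d,e,f,g,h,OP_OUTGROUP);")
  r2 <- tsLength(star, ts)
  expect_equal(r2$length, 2 * nStatements(ts))
  expect_error(tsLength(ape::unroot(ape::rtree(8, tip.label = letters[1:8])),
                        ts), "outgroup")
})

test_that("statement length equals summed Fitch over expanded binary columns", {
  set.seed(45)
  for (r in 1:25) {
    n <- sample(5:10, 1); m <- sample(5:25, 1)
    mat <- randomMatrix(n, m, missing = 0.2)
    og <- sample(c("A", "C", "G", "T"), m, TRUE)
    ts <- encodeMatrix(mat, og)
    if (nStatements(ts) == 0) next
    tr <- ape::rtree(n + 1,
                     tip.label = sample(c(rownames(mat), "OP_OUTGROUP")))
    st <- statements(ts)
    occ <- st[rep(seq_len(nrow(st)), st$mult), ]
    expanded <- matrix("?", n + 1, nrow(occ),
                       dimnames = list(c(rownames(mat), "OP_OUTGROUP"), NULL))
    expanded[cbind(occ$i, seq_len(nrow(occ)))] <- "C"
    expanded[cbind(occ$j, seq_len(nrow(occ)))] <- "C"
    expanded[cbind(occ$k, seq_len(nrow(occ)))] <- "A"
    expanded[n + 1, ] <- "A"
    expect_equal(tsLength(tr, ts)$length, fitchLength(tr, expanded))
  }
})

test_that("heuristic search matches the exhaustive optimum and is reproducible", {
  set.seed(46)
  for (r in 1:6) {
    a <- dnaAlignment(randomMatrix(7, 25, missing = 0.1))
    ex <- exactSearch(a)
    mp <- mpSearch(a, nAdditionReplicates = 3, seed = r)
    expect_equal(searchScore(mp), searchScore(ex))
  }
  a <- dnaAlignment(randomMatrix(8, 30))
  m1 <- mpSearch(a, nAdditionReplicates = 3, seed = 7)
  m2 <- mpSearch(a, nAdditionReplicates = 3, seed = 7)
  expect_equal(searchScore(m1), searchScore(m2))
  expect_equal(ape::write.tree(bestTrees(m1)), ape::write.tree(bestTrees(m2)))
  expect_error(mpSearch(a, nAdditionReplicates = 0), "out of range")
  expect_error(exactSearch(dnaAlignment(randomMatrix(12, 5))), "mpSearch")
})

test_that("noiseless characters on a known tree are recovered exactly", {
  fx <- fixtureToys()$perfectEight
  cons <- consensusSequence(fx$alignment, fx$outgroupTaxa)
  ing <- subsetTaxa(fx$alignment,
                    setdiff(taxa(fx$alignment), fx$outgroupTaxa))
  ts <- encodeMatrix(ing, cons)
  mp <- mpSearch(ts, nAdditionReplicates = 3, seed = 2)
  expect_equal(searchScore(mp), nStatements(ts))
  truth <- ape::read.tree(
    text = "(((((a,b),c),d),(((e,f),g),h)),OP_OUTGROUP);")
  expect_true(any(vapply(seq_along(bestTrees(mp)), function(i)
    oracleRF(bestTrees(mp)[[i]], truth) == 0, TRUE)))
})

test_that("search length is non-increasing in swap radius", {
  set.seed(48)
  a <- dnaAlignment(randomMatrix(10, 40, missing = 0.1))
  s <- vapply(c("none", "nni", "spr", "tbr"), function(sw)
    searchScore(mpSearch(a, nAdditionReplicates = 1, swap = sw, seed = 5)),
    numeric(1))
  expect_true(s["none"] >= s["nni"])
  expect_true(s["nni"] >= s["spr"])
  expect_true(s["spr"] >= s["tbr"])
})

test_that("jackknife support behaves at its limits and is reproducible", {
  fx <- fixtureToys()$perfectEight
  # amplify the clean signal: each perfect column times 8
  mat <- as.matrix(fx$alignment)[, rep(1:6, each = 8)]
  a <- dnaAlignment(mat)
  sup <- jackknifeSupport(a, reps = 8, deleteFraction = 0.37, seed = 3)
  expect_equal(unname(sup["a+b"]), 100)
  expect_equal(attr(sup, "reps"), 8)
  sup2 <- jackknifeSupport(a, reps = 8, deleteFraction = 0.37, seed = 3)
  expect_equal(sup, sup2)
  # zero deletion reduces every replicate to the full search
  full <- mpSearch(a, nAdditionReplicates = 2, swap = "nni", seed = 4)
  cons <- strictConsensus(bestTrees(full), mode = "unrooted")
  sup0 <- jackknifeSupport(a, reps = 3, deleteFraction = 0, seed = 5)
  expect_true(all(sup0 == 100))
  expect_error(jackknifeSupport(a, reps = 2, deleteFraction = 1), "deleteFraction")
})

test_that("jackknife deletes statement occurrences of a 3TS matrix", {
  fx <- fixtureToys()$perfectEight
  cons <- consensusSequence(fx$alignment, fx$outgroupTaxa)
  ing <- subsetTaxa(fx$alignment,
                    setdiff(taxa(fx$alignment), fx$outgroupTaxa))
  ts <- encodeMatrix(dnaAlignment(as.matrix(ing)[, rep(1:6, each = 4)]),
                     rep(cons, each = 4))
  sup <- jackknifeSupport(ts, reps = 5, deleteFraction = 0.37, seed = 6)
  expect_equal(unname(sup["a+b"]), 100)
})
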