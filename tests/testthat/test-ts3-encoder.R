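test_that("polarization follows the worked 5-taxon example", {
  col <- c(t1 = "A", t2 = "C", t3 = "C", t4 = "G", t5 = "?")
  recs <- polarizeColumn(col, "A")
  states <- vapply(recs, `[[`, "", "state")
  expect_setequal(states, c("C", "G"))
  rc <- recs[[which(states == "C")]]
  expect_equal(unname(rc$ones), c(2L, 3L))
  expect_equal(unname(rc$zeros), c(1L, 4L))
  rg <- recs[[which(states == "G")]]
  expect_equal(unname(rg$ones), 4L)
  expect_equal(unname(rg$zeros), c(1L, 2L, 3L))
  st <- enumerateStatements(rc)
  expect_equal(st$i, c(2L, 2L)); expect_equal(st$j, c(3L, 3L))
  expect_equal(sort(st$k), c(1L, 4L))
  # plesiomorphic zeros restrict k to outgroup-state bearers
  rcp <- polarizeColumn(col, "A", zeros = "plesiomorphic")
  expect_equal(unname(rcp[[which(vapply(rcp, `[[`, "", "state") == "C")]]$zeros),
               1L)
})

test_that("degenerate columns produce no recodings or statements", {
  expect_length(polarizeColumn(c(a = "A", b = "A", c = "A"), "A"), 0)
  expect_length(polarizeColumn(c(a = "?", b = "-", c = "N"), "A"), 0)
  expect_error(polarizeColumn(c(a = "A"), "?"), "outgroup state")
  one <- list(state = "C", ones = 2L, zeros = c(1L, 3L))
  expect_equal(nrow(enumerateStatements(one)), 0L)
  three <- list(state = "C", ones = c(1L, 2L, 5L), zeros = c(3L, 4L, 6L, 7L))
  expect_equal(nrow(enumerateStatements(three)), 12L)  # C(3,2) * 4
})

test_that("matrix encoding merges statements with multiplicity", {
  fx <- fixtureToys()$encoderToy
  ts <- encodeMatrix(fx$alignment, fx$outgroup, provenance = TRUE)
  # hand enumeration: col1 gives (2,3|1),(2,3|4); cols 2-3 each give
  # (2,3|1),(2,3|4),(2,3|5)
  st <- statements(ts)
  expect_equal(st[, c("i", "j", "k")],
               data.frame(i = c(2L, 2L, 2L), j = c(3L, 3L, 3L),
                          k = c(1L, 4L, 5L)))
  expect_equal(st$mult, c(3, 3, 2))
  expect_equal(nStatements(ts), 8)
  expect_equal(nrow(ts@provenance), 8L)

  # identical to outgroup everywhere -> empty
  flat <- dnaAlignment(c(a = "AC", b = "AC", c = "AC"))
  expect_equal(nStatements(encodeMatrix(flat, "AC")), 0)
  expect_error(encodeMatrix(flat, "ACG"), "columns")
})

test_that("statement totals obey the count law on random toys", {
  set.seed(31)
  for (r in 1:100) {
    n <- sample(4:9, 1); m <- sample(2:12, 1)
    mat <- randomMatrix(n, m, missing = 0.25)
    og <- sample(c("A", "C", "G", "T", "?"), m, TRUE)
    for (zv in c("absence", "plesiomorphic")) {
      ts <- encodeMatrix(mat, og, zeros = zv)
      brute <- do.call(rbind, lapply(seq_len(m), function(cc)
        bruteStatements(mat[, cc], og[cc], zv)))
      expect_equal(nStatements(ts), nrow(brute))
      # closed form per recoding
      expect_equal(nStatements(ts),
                   sum(choose(ts@recodings$n1, 2) * ts@recodings$n0))
      # deduplicated sets agree
      if (nrow(brute)) {
        key <- function(i, j, k) paste(pmin(i, j), pmax(i, j), k)
        expect_equal(sort(unique(key(brute[, 1], brute[, 2], brute[, 3]))),
                     sort(key(statements(ts)$i, statements(ts)$j,
                              statements(ts)$k)))
      }
    }
  }
})

test_that("relabelling taxa permutes statements accordingly", {
  set.seed(32)
  mat <- randomMatrix(6, 10)
  og <- sample(c("A", "C", "G", "T"), 10, TRUE)
  perm <- sample(6)
  ts1 <- encodeMatrix(mat, og)
  ts2 <- encodeMatrix(mat[perm, , drop = FALSE], og)
  lab <- function(ts) {
    st <- statements(ts)
    key <- paste(pmin(taxa(ts)[st$i], taxa(ts)[st$j]),
                 pmax(taxa(ts)[st$i], taxa(ts)[st$j]), taxa(ts)[st$k],
                 st$mult)
    sort(key)
  }
  expect_equal(lab(ts1), lab(ts2))
})

test_that("the outgroup never enters a statement and all columns are informative", {
  set.seed(33)
  mat <- randomMatrix(7, 30, missing = 0.2)
  og <- sample(c("A", "C", "G", "T"), 30, TRUE)
  ts <- encodeMatrix(mat, og)
  expect_false(ts@outgroupLabel %in% taxa(ts)[unlist(statements(ts)[1:3])])
  # expanded NEXUS: every column has exactly two 1s and two 0s
  f <- tempfile()
  writeTsNexus(ts, f)
  nx <- ape::read.nexus.data(f)
  expect_length(nx, length(taxa(ts)) + 1)
  mat01 <- do.call(rbind, nx)
  expect_equal(ncol(mat01), nStatements(ts))
  expect_true(all(colSums(mat01 == "1") == 2))
  expect_true(all(colSums(mat01 == "0") == 2))
  expect_true(all(mat01["OP_OUTGROUP", ] == "0"))
})

test_that("statement TSV export carries labels, multiplicity and provenance", {
  fx <- fixtureToys()$encoderToy
  ts <- encodeMatrix(fx$alignment, fx$outgroup, provenance = TRUE)
  f <- tempfile()
  writeStatementsTsv(ts, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(tab$i, rep("t2", 3))
  expect_equal(tab$k, c("t1", "t4", "t5"))
  expect_equal(tab$mult, c(3, 3, 2))
  expect_match(tab$provenance[1], "1:C")
})
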