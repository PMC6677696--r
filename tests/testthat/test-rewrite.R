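## independent brute-force matcher: enumerate all injective ordered tuples
## and filter by the pattern predicate
bruteMatches <- function(pattern, state, directed = FALSE) {
  act <- which(state@active)
  incl <- pattern@included
  k <- length(incl)
  if (k == 0L) return(1L)
  tuples <- dggsim:::orderedTuples(act, k)
  ok <- 0L
  for (tp in tuples) {
    good <- TRUE
    bnd <- list()
    for (p in seq_len(k)) {
      lb <- pattern@labels[[p]]
      if (is.character(lb) && !identical(state@label[tp[p]], lb)) {
        good <- FALSE; break
      }
      if (is.symbol(lb)) {
        nm <- as.character(lb)
        if (!is.null(bnd[[nm]]) && !identical(bnd[[nm]], state@label[tp[p]])) {
          good <- FALSE; break
        }
        bnd[[nm]] <- state@label[tp[p]]
      }
    }
    if (good) for (p in seq_len(k)) for (q in seq_len(k)) {
      a <- incl[p]; b <- incl[q]
      if (pattern@adj[a, b] == 1L) {
        if (state@adj[tp[p], tp[q]] != 1L ||
            (!directed && state@adj[tp[q], tp[p]] != 1L)) {
          good <- FALSE
        }
      }
      if (pattern@forbid[a, b] == 1L && state@adj[tp[p], tp[q]] == 1L)
        good <- FALSE
    }
    if (good) ok <- ok + 1L
  }
  ok
}

test_that("ordered match counts follow the distinct-index-tuple convention", {
  g <- twoVertexPool(c("A", "A"))
  pat <- graphPattern(1, list(`1` = list(label = "A")))
  expect_length(findMatches(pat, g), 2L)
  ## two-vertex symmetric pattern on two A vertices: 2 ordered matches
  patAA <- graphPattern(2, list(`1` = list(label = "A"),
                                `2` = list(label = "A")))
  expect_length(findMatches(patAA, g), 2L)
  ## directed edge pattern A->B on the 3-cycle A->B->C->A: 1 match of 6
  ## ordered pairs
  cyc <- poolGraphFromConfig(c("A", "B", "C"),
                             rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                             directed = TRUE)
  patAB <- graphPattern(2, list(`1` = list(label = "A"),
                                `2` = list(label = "B")),
                        edges = list(c(1, 2)), directed = TRUE)
  expect_length(findMatches(patAB, cyc, directed = TRUE), 1L)
})

test_that("match counts agree with a brute-force matcher on random fixtures", {
  set.seed(77)
  for (i in 1:25) {
    g <- randomPoolGraph(nVertices = sample(4:7, 1))
    r <- randomGraphRule(maxK = 3)
    expect_identical(length(findMatches(r@lhs, g)),
                     as.integer(bruteMatches(r@lhs, g)))
  }
})

test_that("kept vertices preserve unmentioned external edges across firing", {
  ## triangle A-B-C plus an external edge touching the kept vertex
  g <- poolGraphFromConfig(c("A", "B", "C", "D"), matrix(0L, 4, 4))
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(1, 4))) {
    g@adj[e[1], e[2]] <- 1L; g@adj[e[2], e[1]] <- 1L
  }
  ## rewrite the triangle, keeping vertex 1 and relabeling it
  rule <- graphRule(
    graphPattern(3, list(`1` = list(label = "A"), `2` = list(label = "B"),
                         `3` = list(label = "C")),
                 edges = list(c(1, 2), c(2, 3), c(1, 3))),
    graphPattern(3, list(`1` = list(label = "X"))),
    cleanupMode = "full", ruleId = "collapse")
  m <- findMatches(rule@lhs, g)[[1]]
  fr <- fireGraphRule(g, rule, m)
  expect_identical(fr$state@label[1], "X")
  expect_equal(fr$state@adj[1, 4], 1L)  # external edge persists
  expect_equal(fr$state@adj[4, 1], 1L)
  expect_length(checkStateInvariants(fr$state), 0L)
})

test_that("cleanup modes control hanging-edge erasure on deletion", {
  g <- poolGraphFromConfig(c("A", "B"), rbind(c(0, 1), c(1, 0)))
  del <- graphRule(graphPattern(1, list(`1` = list(label = "A"))),
                   graphPattern(1, list()), cleanupMode = "full",
                   ruleId = "del")
  m <- findMatches(del@lhs, g)[[1]]
  full <- fireGraphRule(g, del, m)
  expect_equal(sum(full$state@adj), 0)
  expect_length(checkStateInvariants(full$state), 0L)
  delNone <- del; delNone@cleanupMode <- "none"
  none <- fireGraphRule(g, delNone, m)
  expect_gt(sum(none$state@adj), 0)
  expect_match(checkStateInvariants(none$state), "\\(b\\)", all = FALSE)
})

test_that("firing a stale match raises a precondition error", {
  g <- twoVertexPool(c("A", "B"))
  rl <- relabelRule("A", "B")
  m <- findMatches(rl@lhs, g)[[1]]
  g2 <- fireGraphRule(g, rl, m)$state       # vertex 1 is now B
  expect_error(fireGraphRule(g2, rl, m), "stale")
})

test_that("parameterized firing removes matched terms and samples the RHS", {
  rs <- stemCellGrammar(c = 0.1, d = 2)
  rule <- rs[["divide"]]
  pool <- makeStemCellPool(1, V0 = 2, d = 2)
  m <- matchTermPatterns(rule@lhs, pool)[[1]]
  set.seed(3)
  fr <- fireParamRule(pool, rule, m, params = rs@params)
  cc <- poolCounts(fr$state)
  expect_equal(cc[["stemcell"]], 1)
  expect_equal(cc[["TAcell"]], 1)
  vols <- vapply(fr$state@terms, function(t) t$args[[2]], numeric(1))
  expect_equal(vols, c(1, 1))               # V/2 each, total conserved
  xs <- lapply(fr$state@terms, function(t) t$args[[1]])
  expect_equal((xs[[1]] + xs[[2]]) / 2, c(0, 0))  # symmetric displacement
  ## with c = 0 both daughters sit exactly at the mother position
  rs0 <- stemCellGrammar(c = 0, d = 2)
  fr0 <- fireParamRule(pool, rs0[["divide"]],
                       matchTermPatterns(rs0[["divide"]]@lhs, pool)[[1]],
                       params = rs0@params)
  for (t in fr0$state@terms) expect_equal(t$args[[1]], c(0, 0))
  ## identity-parameter rule changes the multiset by {-A[5], +B[5]}
  idRule <- paramRule(list(termPattern("A", "x")),
                      list(termPattern("B", "x")), rate = 1, ruleId = "id")
  p <- addTerm(termPool(), "A", list(5))
  out <- fireParamRule(p, idRule, matchTermPatterns(idRule@lhs, p)[[1]])
  expect_identical(out$state@terms[[1]]$type, "B")
  expect_equal(out$state@terms[[1]]$args[[1]], 5)
})

test_that("full-cleanup firing preserves state invariants over random runs", {
  set.seed(41)
  nFirings <- 0L
  for (rep in 1:10) {
    rules <- replicate(3, randomGraphRule(maxK = 2), simplify = FALSE)
    rs <- ruleset(rules)
    g <- randomPoolGraph(nVertices = 5)
    res <- suppressWarnings(simulateSSA(rs, g, tmax = Inf, maxEvents = 100))
    nFirings <- nFirings + length(res$log)
    expect_length(checkStateInvariants(res$state), 0L)
  }
  expect_gt(nFirings, 200)
})
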