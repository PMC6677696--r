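labs2 <- c("A", "B")

realizeAll <- function(ops, nv = 2, labels = labs2, rates = numeric(0)) {
  lapply(ops, realizeOperator, nVertices = nv, labels = labels,
         rates = rates)
}

test_that("normal ordering implements the binary commutation relations", {
  gf <- dggsim:::genFactor
  ## a ahat = I - ahat a on the same bit (the result is the Z projector)
  o1 <- normalOrder(list(gf("a", "v:1:A"), gf("ahat", "v:1:A")), k = 1)
  oN <- normalOrder(list(gf("ahat", "v:1:A"), gf("a", "v:1:A")), k = 1)
  M1 <- realizeOperator(o1, 1, labs2)
  MN <- realizeOperator(oN, 1, labs2)
  expect_equal(max(abs(M1 - (Matrix::Diagonal(nrow(M1)) - MN))), 0)
  ## different bits commute
  o2 <- normalOrder(list(gf("a", "v:1:A"), gf("ahat", "v:2:B")), k = 2)
  o2r <- normalOrder(list(gf("ahat", "v:2:B"), gf("a", "v:1:A")), k = 2)
  expect_equal(max(abs(realizeOperator(o2, 2, labs2) -
                       realizeOperator(o2r, 2, labs2))), 0)
  ## a Z = 0 (prohibited and required on one bit annihilates the term)
  o3 <- normalOrder(list(gf("a", "v:1:A"), gf("z", "v:1:A")), k = 1)
  expect_length(o3, 0L)
  ## ahat^2 = 0
  o4 <- normalOrder(list(gf("ahat", "e:1:2"), gf("ahat", "e:1:2")), k = 2)
  expect_length(o4, 0L)
})

test_that("rule operators realize exactly as the oracle's flow matrices", {
  space <- enumerateStates(nVertices = 2, labels = labs2)
  vi <- validBitIndices(space)
  rules <- list(
    relabel = relabelRule("A", "B"),
    create = graphRule(graphPattern(1, list()),
                       graphPattern(1, list(`1` = list(label = "A"))),
                       ruleId = "create"),
    delete = graphRule(graphPattern(1, list(`1` = list(label = "A"))),
                       graphPattern(1, list()), cleanupMode = "full",
                       ruleId = "delete"),
    link = graphRule(graphPattern(2, list(`1` = list(label = "A"),
                                          `2` = list(label = "B")),
                                  forbid = list(c(1, 2))),
                     graphPattern(2, list(`1` = list(label = "A"),
                                          `2` = list(label = "B")),
                                  edges = list(c(1, 2))),
                     ruleId = "link"))
  for (r in rules) {
    M <- realizeOperator(opFromRule(r, "eq13"), 2, labs2)
    F <- buildRuleFlowMatrix(r, space)@mat
    expect_equal(max(abs(M[vi, vi] - F)), 0, info = r@ruleId)
  }
  ## the empty rule is the identity operator times its rate
  empty <- graphRule(graphPattern(1, list()), graphPattern(1, list()),
                     rate = 2, ruleId = "noop")
  Mi <- realizeOperator(opFromRule(empty, "eq15"), 1, labs2)
  expect_equal(max(abs(Mi - 2 * Matrix::Diagonal(nrow(Mi)))), 0)
})

test_that("eq13 operators carry erasure; eq15 operators leave hanging edges", {
  del <- graphRule(graphPattern(1, list(`1` = list(label = "A"))),
                   graphPattern(1, list()), ruleId = "del")
  W13 <- opFromRule(del, "eq13")
  expect_true(any(vapply(W13@terms, function(t) length(t$eranges) > 0,
                         logical(1))))
  W15 <- opFromRule(del, "eq15")
  expect_false(any(vapply(W15@terms, function(t) length(t$eranges) > 0,
                          logical(1))))
  ## on a state with an edge at the deleted vertex, eq13 erases it and
  ## eq15 maps it to a hanging-edge configuration
  g <- poolGraphFromConfig(c("A", "B"), rbind(c(0, 1), c(1, 0)))
  s <- dggsim:::poolGraphBitIndex(g, 2, labs2) + 1L
  M13 <- realizeOperator(W13, 2, labs2)
  M15 <- realizeOperator(W15, 2, labs2)
  gClean <- poolGraphFromConfig(c(NA, "B"), matrix(0L, 2, 2))
  t13 <- dggsim:::poolGraphBitIndex(gClean, 2, labs2) + 1L
  expect_equal(M13[t13, s], 1)
  expect_equal(M15[t13, s], 0)   # without erasure the edge bits stay set
})

test_that("products and commutators equal the matrix oracle exactly", {
  set.seed(2024)
  for (i in 1:30) {
    r1 <- randomGraphRule(labs2, maxK = 2)
    r2 <- randomGraphRule(labs2, maxK = 2)
    W1 <- opFromRule(r1, "eq13"); W2 <- opFromRule(r2, "eq13")
    M <- realizeAll(list(W1, W2))
    P <- opProduct(W1, W2)
    expect_equal(max(abs(realizeOperator(P, 2, labs2) -
                         M[[1]] %*% M[[2]])), 0)
    C <- opCommutator(W1, W2)
    expect_equal(max(abs(realizeOperator(C, 2, labs2) -
                         (M[[1]] %*% M[[2]] - M[[2]] %*% M[[1]]))), 0)
  }
})

test_that("structural algebra identities hold after canonicalization", {
  W1 <- opFromRule(relabelRule("A", "B"), "eq13")
  ## [W, W] is the empty sum, not a pair of uncancelled terms
  expect_length(opCommutator(W1, W1), 0L)
  ## disjoint pure reactions commute
  p1 <- pureRule(c(A = 1), c(B = 1), rate = 1, ruleId = "p1")
  p2 <- pureRule(c(C = 1), c(D = 1), rate = 1, ruleId = "p2")
  expect_length(opCommutator(opFromRule(p1), opFromRule(p2)), 0L)
  ## subpermutation invariance: renaming abstract indices leaves the
  ## canonical form unchanged
  t <- W1@terms[[1]]
  t2 <- dggsim:::renameTermIndices(t, seq_len(t$k))
  expect_identical(dggsim:::serializeTerm(dggsim:::canonicalTerm(t2)),
                   dggsim:::serializeTerm(dggsim:::canonicalTerm(t)))
  two <- opFromRule(graphRule(
    graphPattern(2, list(`1` = list(label = "A"), `2` = list(label = "B")),
                 edges = list(c(1, 2))),
    graphPattern(2, list(`1` = list(label = "B"), `2` = list(label = "A")),
                 edges = list(c(1, 2))), ruleId = "swap"), "eq15")
  tt <- two@terms[[1]]
  perm <- rev(seq_len(tt$k))
  t3 <- dggsim:::renameTermIndices(tt, perm)
  expect_identical(dggsim:::serializeTerm(dggsim:::canonicalTerm(t3)),
                   dggsim:::serializeTerm(dggsim:::canonicalTerm(tt)))
})

test_that("the product of a B->C and an A->B relabel has the expected forms", {
  WAB <- opFromRule(relabelRule("A", "B"), "eq15")
  WBC <- opFromRule(relabelRule("B", "C"), "eq15")
  P <- opProduct(WBC, WAB)
  ## one same-index summand (sequential relabel through B) and one
  ## distinct-index summand
  ks <- sort(vapply(P@terms, function(t) t$k, integer(1)))
  expect_identical(ks, c(1L, 2L))
  M <- realizeOperator(P, 2, c("A", "B", "C"), maxBits = 16L)
  ref <- realizeOperator(WBC, 2, c("A", "B", "C"), maxBits = 16L) %*%
    realizeOperator(WAB, 2, c("A", "B", "C"), maxBits = 16L)
  expect_equal(max(abs(M - ref)), 0)
})

test_that("diagonal parts satisfy the outflow identity on physical states", {
  space <- enumerateStates(nVertices = 2, labels = labs2)
  vi <- validBitIndices(space)
  set.seed(515)
  rules <- c(list(relabelRule("A", "B")),
             replicate(10, randomGraphRule(labs2, maxK = 2),
                       simplify = FALSE))
  for (r in rules) {
    What <- realizeOperator(opFromRule(r, "eq13"), 2, labs2)
    D <- realizeOperator(diagonalPart(r, "eq13"), 2, labs2)
    expect_equal(max(abs(Matrix::diag(D)[vi] -
                         Matrix::colSums(What)[vi])), 0,
                 info = r@ruleId)
    ## D realizes diagonally
    expect_equal(Matrix::nnzero(D - Matrix::Diagonal(x = Matrix::diag(D))), 0)
  }
  ## empty-LHS rule: D = rate * (free-index count on physical states)
  cre <- graphRule(graphPattern(1, list()),
                   graphPattern(1, list(`1` = list(label = "A"))),
                   rate = 3, ruleId = "cre")
  D <- realizeOperator(diagonalPart(cre), 2, labs2)
  gEmpty <- poolGraphFromConfig(c(NA, NA), matrix(0L, 2, 2))
  s <- dggsim:::poolGraphBitIndex(gEmpty, 2, labs2) + 1L
  expect_equal(D[s, s], 6)  # 3 per free vertex, 2 free vertices
})
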