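test_that("state enumeration counts are exact and invariant-filtered", {
  expect_length(enumerateStates(species = "A", caps = 3), 4L)
  expect_length(enumerateStates(species = c("A", "B"), caps = c(2, 1)), 6L)
  ## graph space: 3^2 label assignments x 2^4 edge subsets = 144 raw,
  ## minus states with an edge at an inactive vertex; cross-checked by a
  ## direct filter over the raw product space
  sp <- enumerateStates(nVertices = 2, labels = c("A", "B"))
  raw <- 0L
  for (l1 in 0:2) for (l2 in 0:2) for (e12 in 0:1) for (e21 in 0:1) {
    ok <- (e12 == 0 || (l1 > 0 && l2 > 0)) &&
          (e21 == 0 || (l1 > 0 && l2 > 0))
    if (ok) raw <- raw + 1L
  }
  expect_length(sp, raw)
  expect_false(anyDuplicated(sp@keys) > 0)
  expect_error(enumerateStates(species = "A", caps = 1e7), "explosion")
})

test_that("rule flow matrices encode falling-factorial mass action", {
  sp <- enumerateStates(species = "A", caps = 4)
  idx <- function(n) match(as.character(n), sp@keys)
  ## A -> 0 at rate d: flow n=2 -> n=1 equals 2d
  dec <- buildRuleFlowMatrix(pureRule(c(A = 1), NULL, rate = 0.7), sp)
  expect_equal(dec@mat[idx(1), idx(2)], 2 * 0.7)
  ## 0 -> A at rate k: uniform k below the cap, dropped at the cap
  birth <- buildRuleFlowMatrix(pureRule(NULL, c(A = 1), rate = 1.3), sp)
  expect_equal(birth@mat[idx(3), idx(2)], 1.3)
  expect_equal(sum(birth@mat[, idx(4)]), 0)  # truncation
  ## A + A -> 0: n=4 gives 4*3*k
  pair <- buildRuleFlowMatrix(pureRule(c(A = 2), NULL, rate = 2), sp)
  expect_equal(pair@mat[idx(2), idx(4)], 12 * 2)
  expect_true(all(dec@mat >= 0), all(birth@mat >= 0))
})

test_that("generators conserve probability and match a hand-built chain", {
  rs <- birthDeathRuleset(k = 2, d = 1)
  sp <- enumerateStates(species = "A", caps = 12)
  W <- buildGenerator(rs, sp)@mat
  expect_lt(max(abs(Matrix::colSums(W))), 1e-12)
  ## hand-built tridiagonal generator of the linear birth-death chain
  n <- 0:12
  Wref <- matrix(0, 13, 13)
  for (i in 1:12) Wref[i + 1, i] <- 2          # birth n-1 -> n
  for (i in 2:13) Wref[i - 1, i] <- n[i]        # death
  diag(Wref) <- -colSums(Wref)  # absorbing truncation: no birth out of cap
  expect_equal(as.matrix(W), Wref, ignore_attr = TRUE)
  ## empty ruleset gives the zero matrix
  W0 <- buildGenerator(ruleset(list()), sp)@mat
  expect_equal(sum(abs(W0)), 0)
})

test_that("master-equation evolution reproduces closed forms", {
  ## two-state decay: P(B at t=1) = 1 - exp(-1)
  rs <- ruleset(pureRule(c(A = 1), c(B = 1), rate = 1))
  sp <- enumerateStates(species = c("A", "B"), caps = c(1, 1))
  W <- buildGenerator(rs, sp)
  p0 <- as.numeric(sp@keys == "1,0")
  expect_identical(evolveDistribution(W, p0, 0), p0)
  pt <- evolveDistribution(W, p0, 1)
  expect_equal(pt[match("0,1", sp@keys)], 1 - exp(-1), tolerance = 1e-9)
  expect_true(all(pt > -1e-12))
  expect_equal(sum(pt), 1, tolerance = 1e-9)
  expect_error(evolveDistribution(W, p0 * 2, 1), "distribution")
  ## birth-death stationary law is truncated Poisson(k/d)
  bd <- birthDeathRuleset(k = 2, d = 1)
  spA <- enumerateStates(species = "A", caps = 20)
  Wbd <- buildGenerator(bd, spA)
  p0 <- c(1, rep(0, 20))
  pt <- evolveDistribution(Wbd, p0, 60)
  pois <- dpois(0:20, 2); pois <- pois / sum(pois)
  expect_lt(tvDistance(pt, pois), 1e-6)
})

test_that("enlarging caps changes interior probabilities negligibly", {
  bd <- birthDeathRuleset(k = 2, d = 1)
  p1 <- evolveDistribution(buildGenerator(bd, enumerateStates(species = "A",
                                                              caps = 15)),
                           c(1, rep(0, 15)), 3)
  p2 <- evolveDistribution(buildGenerator(bd, enumerateStates(species = "A",
                                                              caps = 25)),
                           c(1, rep(0, 25)), 3)
  expect_lt(max(abs(p1[1:10] - p2[1:10])), 1e-8)
})

test_that("graph-rule flow matrices agree with match-and-fire by hand", {
  sp <- enumerateStates(nVertices = 2, labels = c("A", "B"))
  rl <- relabelRule("A", "B", rate = 1.5)
  M <- buildRuleFlowMatrix(rl, sp)@mat
  ## from the state with two A vertices and no edges, flow goes to the two
  ## single-relabel states at rate 1.5 each
  from <- match(dggsim:::poolGraphKey(twoVertexPool(c("A", "A")), 2), sp@keys)
  toBA <- match(dggsim:::poolGraphKey(twoVertexPool(c("B", "A")), 2), sp@keys)
  toAB <- match(dggsim:::poolGraphKey(twoVertexPool(c("A", "B")), 2), sp@keys)
  expect_equal(M[toBA, from], 1.5)
  expect_equal(M[toAB, from], 1.5)
  expect_equal(sum(M[, from]), 3)
  ## generator over the relabel ruleset conserves probability
  W <- buildGenerator(relabelRuleset(), sp)@mat
  expect_lt(max(abs(Matrix::colSums(W))), 1e-12)
})
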