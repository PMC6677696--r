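test_that("vertex allocation uses a LIFO free list and grows on demand", {
  g <- poolGraph(2)
  a1 <- allocateVertex(g, "A"); g <- a1$state
  expect_identical(a1$index, 1L)
  expect_true(g@active[1])
  a2 <- allocateVertex(g, "B"); g <- a2$state
  expect_false(a2$index == a1$index)
  ## growth beyond initial capacity
  a3 <- allocateVertex(g, "A"); g <- a3$state
  expect_identical(a3$index, 3L)
  ## deallocate then reallocate reuses the freed index first
  g <- deallocateVertex(g, a2$index)
  a4 <- allocateVertex(g, "B")
  expect_identical(a4$index, a2$index)
})

test_that("deallocation erases labels, parameters and all incident edges", {
  g <- poolGraph(4)
  for (lb in c("A", "B", "A", "B")) g <- allocateVertex(g, lb)$state
  g <- addEdge(g, 1, 2); g <- addEdge(g, 1, 3); g <- addEdge(g, 4, 1)
  expect_equal(sum(g@adj[1, ] + g@adj[, 1]), 6)  # 3 undirected pairs
  g2 <- deallocateVertex(g, 1)
  expect_equal(sum(g2@adj[1, ] + g2@adj[, 1]), 0)
  expect_true(is.na(g2@label[1]))
  expect_length(checkStateInvariants(g2), 0L)
  ## isolated vertex: state differs only at that vertex
  g3 <- deallocateVertex(g, 4)
  expect_identical(g3@adj[1:3, 1:3], g@adj[1:3, 1:3])
  ## erasure on an inactive vertex is a warning no-op
  expect_warning(g4 <- deallocateVertex(g2, 1), "no-op")
  expect_identical(g4@active, g2@active)
})

test_that("invariant checker flags labels on inactive vertices and hanging edges", {
  g <- randomPoolGraph()
  expect_length(checkStateInvariants(g), 0L)
  gBad <- g
  inact <- which(!gBad@active)[1]
  act <- which(gBad@active)[1]
  gBad@adj[act, inact] <- 1L
  v <- checkStateInvariants(gBad)
  expect_match(v, "\\(b\\)", all = FALSE)
  gBad2 <- g
  gBad2@label[inact] <- "A"
  expect_match(checkStateInvariants(gBad2), "\\(a\\)", all = FALSE)
})

test_that("invariants survive long random runs under full cleanup", {
  set.seed(31)
  rules <- replicate(4, randomGraphRule(maxK = 2), simplify = FALSE)
  rs <- ruleset(rules)
  g <- randomPoolGraph(nVertices = 5)
  res <- suppressWarnings(simulateSSA(rs, g, tmax = Inf, maxEvents = 300))
  expect_length(checkStateInvariants(res$state), 0L)
})
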