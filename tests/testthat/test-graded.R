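mkSlice <- function(labels, edges, lv = NULL, dv = NULL, directed = FALSE) {
  n <- length(labels)
  g <- poolGraph(n, directed = directed)
  for (i in seq_len(n)) {
    pars <- list()
    if (!is.null(lv)) pars$l <- lv[i]
    if (!is.null(dv)) pars$d <- dv[i]
    g <- allocateVertex(g, labels[i], pars)$state
  }
  for (e in edges) {
    g@adj[e[1], e[2]] <- 1L
    if (!directed) g@adj[e[2], e[1]] <- 1L
  }
  g
}

test_that("slice validators implement the per-kind edge predicates", {
  graded <- sliceKind("graded", directed = TRUE)
  g <- mkSlice(c("s", "s"), list(c(1, 2)), lv = c(0, 1), directed = TRUE)
  expect_length(validateSliceGraph(g, graded), 0L)
  gBad <- mkSlice(c("s", "s"), list(c(1, 2)), lv = c(0, 2), directed = TRUE)
  expect_match(validateSliceGraph(gBad, graded), "violates", all = FALSE)
  ## directed graded rejects level-lowering edges, undirected allows them
  gDown <- mkSlice(c("s", "s"), list(c(1, 2)), lv = c(1, 0), directed = TRUE)
  expect_length(validateSliceGraph(gDown, graded), 1L)
  expect_length(validateSliceGraph(mkSlice(c("s", "s"), list(c(1, 2)),
                                           lv = c(1, 0)),
                                   sliceKind("graded")), 0L)
  ## stratified directed: dimension cannot increase along an edge
  strat <- sliceKind("stratified", D = 2, directed = TRUE)
  expect_length(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), dv = c(2, 0), directed = TRUE),
    strat), 0L)
  expect_length(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), dv = c(0, 2), directed = TRUE),
    strat), 1L)
  ## abstract cell complex: dimension drops by exactly 0 or 1
  acc <- sliceKind("acc", D = 2, directed = TRUE)
  expect_length(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), dv = c(2, 1), directed = TRUE),
    acc), 0L)
  expect_length(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), dv = c(2, 0), directed = TRUE),
    acc), 1L)
  ## graded-stratified: level and dimension cannot both change on one edge
  cd <- sliceKind("graded_stratified", D = 2)
  expect_length(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), lv = c(0, 1), dv = c(1, 1)), cd), 0L)
  expect_match(validateSliceGraph(
    mkSlice(c("s", "s"), list(c(1, 2)), lv = c(0, 1), dv = c(1, 2)), cd),
    "violates", all = FALSE)
  ## missing labels are a schema error
  expect_error(validateSliceGraph(mkSlice(c("s"), list()), graded),
               "schema")
})

test_that("graded-stratified graphs project to valid graded and stratified graphs", {
  set.seed(88)
  kind <- sliceKind("graded_stratified", D = 2)
  for (i in 1:20) {
    g <- randomSliceGraph(kind, nVertices = 6)
    expect_length(validateSliceGraph(g, kind), 0L)
    expect_length(validateSliceGraph(g, sliceKind("graded")), 0L)
    expect_length(validateSliceGraph(g, sliceKind("stratified", D = 2)), 0L)
  }
})

test_that("strata extraction finds constant-dimension components and contacts", {
  ## two 2-D patches joined only through a shared 1-D chain
  g <- mkSlice(rep("s", 7), list(c(1, 2), c(3, 4), c(5, 6), c(6, 7),
                                 c(2, 5), c(3, 6)),
               dv = c(2, 2, 2, 2, 1, 1, 1))
  sg <- extractStrataGraph(g)
  expect_length(sg@dims, 3L)
  expect_setequal(sg@dims, c(2, 2, 1))
  expect_equal(nrow(sg@edges), 2L)  # each patch contacts the chain
  expect_true(all(sg@dims[sg@edges[, 1]] > sg@dims[sg@edges[, 2]]))
  ## a connected constant-dimension graph is one stratum with no contacts
  g1 <- mkSlice(rep("s", 3), list(c(1, 2), c(2, 3)), dv = c(1, 1, 1))
  sg1 <- extractStrataGraph(g1)
  expect_length(sg1@dims, 1L)
  expect_equal(nrow(sg1@edges), 0L)
  ## per-dimension restriction of the strata DAG is edgeless
  expect_true(all(sg@dims[sg@edges[, 1]] != sg@dims[sg@edges[, 2]]))
})

test_that("slice-rule lowering restores levels and gates invalid labelings", {
  slice <- meshRefinementGrammar(slice = TRUE)
  low <- lowerRuleset(slice, sliceKind("graded"))
  r <- low@rules[[1]]
  expect_identical(r@sliceKind, "")
  ## every vertex of the lowered rule carries an explicit level pattern
  for (side in list(r@lhs, r@rhs))
    for (p in side@params) expect_true("l" %in% names(p))
  ## on a valid match both gates are 1 and the rate is unchanged
  mesh <- makeTriangleMesh(1)
  m <- findMatches(r@lhs, mesh)[[1]]
  expect_equal(rulePropensity(r, m, mesh, low@params),
               rulePropensity(slice@rules[[1]],
                              findMatches(slice@rules[[1]]@lhs, mesh)[[1]],
                              mesh, slice@params))
})

test_that("slice-level and lowered simulations commute with the semantics", {
  slice <- meshRefinementGrammar(slice = TRUE)
  low <- lowerRuleset(slice, sliceKind("graded"))
  mesh <- makeTriangleMesh(1)
  a <- suppressWarnings(simulateSSA(slice, mesh, 0.4, seed = 7,
                                    maxEvents = 10))
  b <- suppressWarnings(simulateSSA(low, mesh, 0.4, seed = 7,
                                    maxEvents = 10))
  expect_identical(a$log@events, b$log@events)
  expect_identical(a$state@adj, b$state@adj)
  expect_identical(a$state@label, b$state@label)
  expect_identical(a$state@params, b$state@params)
})

test_that("gated runs keep every intermediate state slice-valid", {
  rs <- meshRefinementGrammar(lmax = 1)
  kind <- sliceKind("graded")
  out <- runToQuiescence(rs, makeTriangleMesh(2), seed = 3,
                         validator = function(s) validateSliceGraph(s, kind))
  expect_gt(out$events, 0L)
  expect_equal(sum(lengths(out$reports)), 0L)
})
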