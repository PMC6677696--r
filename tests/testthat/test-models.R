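test_that("stem-cell division conserves volume and splits symmetrically", {
  rs <- stemCellGrammar(c = 0.1, d = 2)
  pool <- makeStemCellPool(2, V0 = 2, d = 2)
  res <- simulateSSA(rs, pool, 6, seed = 9)
  expect_gt(length(res$log), 0L)
  expect_equal(totalVolume(res$state), 4, tolerance = 1e-12)
  ## every division adds exactly one cell and one TAcell
  cc <- poolCounts(res$state)
  expect_equal(unname(cc[["TAcell"]]), length(res$log))
  expect_equal(length(res$state), 2 + length(res$log))
  expect_error(stemCellGrammar(d = 5), "dimension")
  expect_error(stemCellGrammar(c = -1), "nonnegative")
})

test_that("the refinement grammar ships four graded rules", {
  rs <- meshRefinementGrammar()
  expect_length(rs@rules, 4L)
  expect_true(all(vapply(rs@rules, function(r) is(r, "GraphRule"),
                         logical(1))))
})

test_that("one full refinement of a fan mesh yields 4T triangles", {
  rs <- meshRefinementGrammar(lmax = 1)
  kind <- sliceKind("graded")
  for (Tn in 1:2) {
    out <- runToQuiescence(rs, makeTriangleMesh(Tn), seed = Tn,
                           validator = function(s)
                             validateSliceGraph(s, kind))
    expect_equal(sum(lengths(out$reports)), 0L)
    cnt <- meshLevelCounts(out$state, 1)
    expect_equal(cnt$triangles, 4 * Tn)
  }
})

test_that("refinement order does not change the refined mesh (confluence)", {
  rs <- meshRefinementGrammar(lmax = 1)
  counts <- lapply(1:4, function(s) {
    out <- runToQuiescence(rs, makeTriangleMesh(2), seed = s)
    c(meshLevelCounts(out$state, 1), events = out$events)
  })
  for (ct in counts[-1]) expect_identical(ct, counts[[1]])
})

test_that("microtubule events change segment counts by their rule deltas", {
  rs <- microtubuleGrammar()
  deltas <- mtSegmentDeltas()
  set.seed(21)
  state <- makeMtFiber(3)
  inst <- dggsim:::collectInstances(rs, state)
  for (rep in 1:120) {
    inst <- dggsim:::collectInstances(rs, state)
    props <- vapply(inst, function(x) x$prop, numeric(1))
    if (!length(props) || sum(props) <= 0) break
    x <- inst[[which(runif(1) * sum(props) <= cumsum(props))[1]]]
    before <- sum(state@active)
    state <- fireGraphRule(state, x$rule, x$match, checkMatch = FALSE,
                           params = rs@params)$state
    expect_identical(sum(state@active) - before,
                     as.integer(deltas[[x$rule@ruleId]]))
  }
  ## labels never leave the four declared values
  expect_true(all(state@label[state@active] %in%
                  c("internal", "grow_end", "retract_end", "junct")))
  expect_length(checkStateInvariants(state), 0L)
})

test_that("every free fiber extremity carries a growing or retracting cap", {
  rs <- microtubuleGrammar()
  for (seed in 1:3) {
    res <- suppressWarnings(simulateSSA(rs, makeMtFiber(3), tmax = 20,
                                        seed = seed, maxEvents = 400))
    expect_length(mtEndLabelCheck(res$state), 0L)
  }
})

test_that("breakable springs are continuous at the break and force-free beyond", {
  sp <- data.frame(p = 1, q = 2, k = 2, l = 1, dl = 0.5)
  atRest <- springEnergy(rbind(c(0, 0), c(1, 0)), sp)
  expect_equal(atRest$energy, -0.5 * 2 * 0.5^2)   # unbroken branch chosen
  expect_equal(max(abs(atRest$gradient)), 0)
  atBreak <- springEnergy(rbind(c(0, 0), c(1.5, 0)), sp)
  expect_equal(atBreak$energy, 0)                  # both branches meet at 0
  beyond <- springEnergy(rbind(c(0, 0), c(2, 0)), sp)
  expect_equal(beyond$energy, 0)
  expect_equal(max(abs(beyond$gradient)), 0)
  ## coincident endpoints: finite energy, well-defined (zero) force
  co <- springEnergy(rbind(c(0, 0), c(0, 0)),
                     data.frame(p = 1, q = 2, k = 1, l = 0.3, dl = 0.5))
  expect_true(is.finite(co$energy))
  expect_true(all(is.finite(co$gradient)))
})

test_that("energy is non-increasing along overdamped spring relaxation", {
  sp <- data.frame(p = c(1, 2), q = c(2, 3), k = c(2, 1), l = c(1, 1),
                   dl = c(0.5, 0.5))
  pos0 <- rbind(c(0, 0), c(1.4, 0.1), c(2.1, -0.2))
  m <- springDriftModel(pos0, sp)
  res <- simulateHybrid(m$ruleset, m$pool, 4, tol = 1e-9)
  tr <- res$trajectory
  ## node coordinate columns in the flattened layout: (id, x[2]) per node,
  ## then spring parameter terms
  posAt <- function(row) rbind(c(tr[row, 3], tr[row, 4]),
                               c(tr[row, 6], tr[row, 7]),
                               c(tr[row, 9], tr[row, 10]))
  Es <- vapply(seq_len(nrow(tr)), function(i)
    springEnergy(posAt(i), sp)$energy, numeric(1))
  expect_true(all(diff(Es) <= 1e-7))
  ## relaxation approaches resting lengths
  pf <- springPositions(res$state)
  expect_equal(sqrt(sum((pf[1, ] - pf[2, ])^2)), 1, tolerance = 1e-3)
  expect_equal(sqrt(sum((pf[2, ] - pf[3, ])^2)), 1, tolerance = 1e-3)
})

test_that("fixture generation is seed-deterministic and validator-clean", {
  f1 <- randomFixtures(seed = 0, n = 4)
  f2 <- randomFixtures(seed = 0, n = 4)
  expect_identical(f1, f2)
  for (g in f1$poolGraphs) expect_length(checkStateInvariants(g), 0L)
  kind <- sliceKind("graded_stratified", D = 2)
  for (g in f1$sliceGraphs) expect_length(validateSliceGraph(g, kind), 0L)
  for (rs in f1$pureRulesets) expect_length(validateRule(rs), 0L)
  for (r in f1$graphRules) expect_length(validateRule(r), 0L)
})
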