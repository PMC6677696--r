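test_that("propensities follow falling-factorial combinatorics", {
  pair <- pureRule(c(A = 2), NULL, rate = 3, ruleId = "ann")
  expect_equal(rulePropensity(pair, state = c(A = 4)), 12 * 3)
  expect_equal(rulePropensity(pair, state = c(A = 1)), 0)
  ## parameterized: rate rho(V) = V on a volume-2 cell
  r <- paramRule(list(termPattern("stemcell", "x", "V")),
                 list(termPattern("stemcell", "x", "V")),
                 rate = "V", ruleId = "lin")
  pool <- addTerm(termPool(), "stemcell", list(0, 2))
  m <- matchTermPatterns(r@lhs, pool)[[1]]
  expect_equal(rulePropensity(r, m, pool), 2)
})

test_that("SSA is deterministic under a fixed seed and inert without rules", {
  rs <- relabelRuleset()
  g <- twoVertexPool(c("A", "A"))
  r1 <- simulateSSA(rs, g, 2, seed = 5)
  r2 <- simulateSSA(rs, g, 2, seed = 5)
  expect_identical(r1$log@events, r2$log@events)
  r3 <- simulateSSA(rs, g, 2, seed = 6)
  expect_false(identical(r1$log@events, r3$log@events))
  ## empty ruleset: no events, state unchanged
  r0 <- simulateSSA(ruleset(list()), g, 2, seed = 1)
  expect_length(r0$log, 0L)
  expect_identical(r0$state@label, g@label)
})

test_that("birth-death SSA matches the stationary Poisson mean", {
  rs <- birthDeathRuleset(k = 2, d = 1)
  set.seed(101)
  means <- vapply(1:32, function(i) {
    res <- simulateSSA(rs, c(A = 0), 120)
    ev <- as.data.frame(res$log)
    ## time-average of n over [40, 120] from the event log
    times <- c(ev$time, 120)
    ns <- cumsum(c(0, ifelse(ev$ruleId == "birth", 1, -1)))
    keep <- times >= 40
    sum(ns[keep] * diff(c(40, times[keep]))) / 80
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2), 3 * se + 1e-9)
})

test_that("single-particle decay has unit mean extinction time", {
  rs <- ruleset(pureRule(c(A = 1), NULL, rate = 1, ruleId = "die"))
  set.seed(7)
  ts <- vapply(1:4000, function(i) {
    res <- simulateSSA(rs, c(A = 1), Inf)
    res$log@events[[1]]$time
  }, numeric(1))
  expect_lt(abs(mean(ts) - 1), 3 * sd(ts) / sqrt(length(ts)))
})

test_that("hybrid integration reproduces exponential decay exactly", {
  rs <- ruleset(odeRule(list(termPattern("p", "x")),
                        list(list(term = 1, slot = 1, expr = "-x")),
                        ruleId = "decay"))
  pool <- addTerm(termPool(), "p", list(1))
  res <- simulateHybrid(rs, pool, 1, tol = 1e-10)
  expect_equal(res$state@terms[[1]]$args[[1]], exp(-1), tolerance = 1e-6)
  expect_length(res$log, 0L)  # rate-0 discrete part: pure ODE trajectory
})

test_that("hybrid event timing solves the integrated hazard exactly", {
  ## dx/dt = 1 from x(0)=0 with hazard x: T = sqrt(2E), E ~ Exp(1), so
  ## E[T] = sqrt(pi/2)
  rs <- ruleset(odeRule(list(termPattern("p", "x")),
                        list(list(term = 1, slot = 1, expr = "1")),
                        ruleId = "drift"),
                paramRule(list(termPattern("p", "x")),
                          list(termPattern("done", "x")),
                          rate = "x", ruleId = "fire"))
  set.seed(13)
  ts <- vapply(1:1500, function(i) {
    pool <- addTerm(termPool(), "p", list(0))
    r <- simulateHybrid(rs, pool, 10, saveTrajectory = FALSE)
    r$log@events[[1]]$time
  }, numeric(1))
  expect_lt(abs(mean(ts) - sqrt(pi / 2)), 3 * sd(ts) / sqrt(length(ts)))
})

test_that("with zero drift the hybrid event times match plain SSA", {
  ## constant hazard 1: event times are Exp(1) in both simulators
  rsH <- ruleset(odeRule(list(termPattern("p", "x")),
                         list(list(term = 1, slot = 1, expr = "0")),
                         ruleId = "still"),
                 paramRule(list(termPattern("p", "x")),
                           list(termPattern("done", "x")),
                           rate = 1, ruleId = "fire"))
  set.seed(19)
  tH <- vapply(1:400, function(i) {
    pool <- addTerm(termPool(), "p", list(0))
    simulateHybrid(rsH, pool, 50, saveTrajectory = FALSE)$log@events[[1]]$time
  }, numeric(1))
  rsS <- ruleset(pureRule(c(p = 1), c(done = 1), rate = 1, ruleId = "fire"))
  tS <- vapply(1:400, function(i) {
    simulateSSA(rsS, c(p = 1, done = 0), 50)$log@events[[1]]$time
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(tH, tS))
  expect_gt(ks$p.value, 0.01)
})
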