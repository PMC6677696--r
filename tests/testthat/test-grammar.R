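test_that("expression ASTs evaluate recursively under bindings", {
  ast <- parseExpression("sqrt(x^2 + y^2)")
  expect_equal(evalExpression(ast, list(x = 5, y = 12)), 13)
  expect_equal(evalExpression(ast, list(x = 0, y = 0)), 0)
  expect_equal(evalExpression(parseExpression("x*y + 1"),
                              list(x = 2, y = 3)), 7)
  expect_error(evalExpression(ast, list(x = 1)), "unbound")
  suppressWarnings(
    expect_error(evalExpression(parseExpression("sqrt(x)"), list(x = -1)),
                 "NaN|domain"))
})

test_that("the DSL parses pure, parameterized, ODE and graph rules", {
  rs <- parseRuleset(c(
    "param k = 2",
    "r1: A + B -> C with k",
    "div: stemcell[x, V] -> TAcell[x + dx, V/2], stemcell[x - dx, V/2] with rho(V) * normal(dx; c * V^(1/2))",
    "relax: point[x] -> point[x] with ode d(x)/dt = -x",
    "graph rel {",
    "  lhs { 1 A }",
    "  rhs { 1 B }",
    "  rate 1",
    "  cleanup full",
    "}"))
  expect_length(rs@rules, 4L)
  r1 <- rs[["r1"]]
  expect_s4_class(r1, "PureRule")
  expect_equal(r1@lhs, c(A = 1, B = 1))
  expect_equal(r1@rhs, c(C = 1))
  expect_identical(r1@rate, "k")
  div <- rs[["div"]]
  expect_s4_class(div, "ParamRule")
  expect_length(div@lhs, 1L)
  expect_length(div@rhs, 2L)
  expect_length(div@samplers, 1L)
  expect_identical(div@samplers[[1]]$var, "dx")
  expect_s4_class(rs[["relax"]], "ODERule")
  expect_s4_class(rs[["rel"]], "GraphRule")
})

test_that("malformed input and SDE noise terms are rejected", {
  expect_error(parseRuleset("A + -> B with 1"), "syntax error")
  expect_error(parseRuleset("r: p[x] -> p[x] with ode d(x)/dt = -x + w dB_t"),
               "unsupported")
  expect_error(parseRuleset(c("species A B",
                              "r1: A -> C with 1")), "undeclared")
})

test_that("parse/unparse round trip is the identity on generated rulesets", {
  models <- list(
    parseRuleset(c("param k = 2", "r1: A + 2 B -> C with k",
                   "r2: 0 -> A with 1.5")),
    stemCellGrammar(),
    meshRefinementGrammar(lmax = 1),
    meshRefinementGrammar(slice = TRUE),
    microtubuleGrammar())
  for (rs in models) {
    txt <- formatRuleset(rs)
    rs2 <- parseRuleset(txt)
    expect_identical(formatRuleset(rs2), txt)
    expect_equal(length(rs2), length(rs))
  }
})

test_that("arrow reversal swaps sides, renames the rate, and is an involution", {
  r <- pureRule(c(A = 1, B = 1), c(C = 1), rate = "k", ruleId = "bind")
  rev1 <- reverseRule(r)
  expect_equal(rev1@lhs, r@rhs)
  expect_equal(rev1@rhs, r@lhs)
  expect_false(identical(rev1@rate, r@rate))
  rev2 <- reverseRule(rev1)
  expect_equal(rev2@lhs, r@lhs)
  expect_equal(rev2@rhs, r@rhs)
  ## empty-side case
  b <- pureRule(NULL, c(A = 1), rate = "k", ruleId = "birth")
  rb <- reverseRule(b)
  expect_equal(rb@lhs, c(A = 1))
  expect_length(rb@rhs, 0L)
  ## unsupported variant
  expect_error(reverseRule(relabelRule("A", "B")), "unsupported")
})

test_that("validateRule reports violated invariants as diagnostics", {
  bad <- new("PureRule", ruleId = "neg", lhs = c(A = -1),
             rhs = c(B = 1), rate = 1)
  expect_match(validateRule(bad), "negative stoichiometry", all = FALSE)
  ## required and prohibited edge on the same pair
  gp <- graphPattern(2, list(`1` = list(label = "A"),
                             `2` = list(label = "A")),
                     edges = list(c(1, 2)), forbid = list(c(1, 2)))
  gr <- graphRule(gp, gp, ruleId = "contr")
  expect_match(validateRule(gr), "unsatisfiable", all = FALSE)
  ## RHS variable with no LHS binding nor sampler
  orphan <- paramRule(list(termPattern("a", "x")),
                      list(termPattern("b", "x + dz")), rate = 1,
                      ruleId = "orphan")
  expect_match(validateRule(orphan), "sampler", all = FALSE)
  ## well-formed rules of the shipped grammars produce no diagnostics
  expect_length(validateRule(stemCellGrammar()), 0L)
  expect_length(validateRule(meshRefinementGrammar()), 0L)
  expect_length(validateRule(microtubuleGrammar()), 0L)
})
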