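## shared fixtures for the test suite (built in code, seed-deterministic)

birthDeathRuleset <- function(k = 2, d = 1) {
  ruleset(pureRule(NULL, c(A = 1), rate = k, ruleId = "birth"),
          pureRule(c(A = 1), NULL, rate = d, ruleId = "death"))
}

## one-vertex relabel rule with concrete labels
relabelRule <- function(from, to, rate = 1, id = paste0(from, to)) {
  graphRule(graphPattern(1, setNames(list(list(label = from)), "1")),
            graphPattern(1, setNames(list(list(label = to)), "1")),
            rate = rate, ruleId = id)
}

## two-state relabel model on a fixed small vertex pool
relabelRuleset <- function(kAB = 1, kBA = 0.5) {
  ruleset(relabelRule("A", "B", kAB, "ab"), relabelRule("B", "A", kBA, "ba"))
}

twoVertexPool <- function(labels = c("A", "A")) {
  poolGraphFromConfig(labels, matrix(0L, length(labels), length(labels)))
}

## restrict a full bit-space realization to the physical (one-hot) states
## of an enumerated graph space
validBitIndices <- function(space) {
  nv <- space@meta$nVertices
  vapply(space@states, dggsim:::poolGraphBitIndex,
         nVertices = nv, labels = space@meta$labels, integer(1)) + 1L
}

tvDistance <- function(p, q) 0.5 * sum(abs(p - q))
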