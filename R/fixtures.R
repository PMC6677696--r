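## Seed-deterministic random fixtures for property tests: pure rulesets,
## graph rules, pool graphs, and slice graphs built construct-by-predicate
## so that every generated object passes its validator.

#' Random pure-reaction ruleset
#'
#' @param nSpecies,nRules sizes; @param maxStoich maximum stoichiometry.
#' @return a [Ruleset-class] of [PureRule-class] with numeric rates.
#' @export
randomPureRuleset <- function(nSpecies = 3L, nRules = 3L, maxStoich = 2L) {
  sp <- LETTERS[seq_len(nSpecies)]
  rules <- lapply(seq_len(nRules), function(r) {
    repeat {
      m <- setNames(sample(0:maxStoich, nSpecies, replace = TRUE), sp)
      n <- setNames(sample(0:maxStoich, nSpecies, replace = TRUE), sp)
      if (sum(m) + sum(n) > 0 && sum(m) <= 3 && sum(n) <= 3) break
    }
    pureRule(m[m > 0], n[n > 0], rate = round(runif(1, 0.1, 2), 3),
             ruleId = paste0("r", r))
  })
  ruleset(rules)
}

#' Random graph rewrite rule with concrete labels
#'
#' @param labels label alphabet.
#' @param maxK maximum shared-numbering size.
#' @param pEdge edge probability; @param pForbid prohibited-edge
#'   probability.
#' @param cleanupMode cleanup mode of the generated rule.
#' @param rate numeric rate.
#' @return a [GraphRule-class].
#' @export
randomGraphRule <- function(labels = c("A", "B"), maxK = 3L, pEdge = 0.4,
                            pForbid = 0.15, cleanupMode = "full", rate = 1) {
  k <- sample(seq_len(maxK), 1)
  nl <- sample(0:k, 1); nr <- sample(0:k, 1)
  if (nl == 0 && nr == 0) nl <- 1L
  lhsV <- sort(sample(seq_len(k), nl))
  rhsV <- sort(sample(seq_len(k), nr))
  mkSide <- function(vs) {
    if (!length(vs))
      return(graphPattern(k, list()))
    verts <- setNames(lapply(vs, function(v)
      list(label = sample(labels, 1))), as.character(vs))
    edges <- list(); forbid <- list()
    if (length(vs) >= 2) {
      pr <- utils::combn(vs, 2)
      for (ci in seq_len(ncol(pr))) {
        u <- runif(1)
        if (u < pEdge) edges <- c(edges, list(pr[, ci]))
        else if (u < pEdge + pForbid) forbid <- c(forbid, list(pr[, ci]))
      }
    }
    graphPattern(k, verts, edges = if (length(edges)) edges else NULL,
                 forbid = if (length(forbid)) forbid else NULL,
                 directed = FALSE)
  }
  rule <- graphRule(mkSide(lhsV), mkSide(rhsV), rate = rate,
                    cleanupMode = cleanupMode,
                    ruleId = paste0("g", sample.int(1e6, 1)))
  ## rule hygiene: an RHS-created edge between two kept vertices must be
  ## declared absent on the LHS (prohibited edge), otherwise the rule is
  ## ambiguous on states where the edge already exists (the inflow
  ## operator vanishes there, since creation on an occupied edge bit is
  ## zero)
  kept <- intersect(lhsV, rhsV)
  for (a in kept) for (b in kept) {
    if (a == b) next
    if (rule@rhs@adj[a, b] == 1L && rule@lhs@adj[a, b] == 0L)
      rule@lhs@forbid[a, b] <- 1L
    ## likewise an RHS-prohibited edge between kept vertices that the rule
    ## does not delete must already be absent on the LHS
    if (rule@rhs@forbid[a, b] == 1L && rule@lhs@adj[a, b] == 0L)
      rule@lhs@forbid[a, b] <- 1L
  }
  rule
}

#' Random pool graph satisfying the state invariants
#'
#' @param nVertices universe size; @param labels label alphabet;
#' @param pActive activation probability; @param pEdge edge probability
#'   among active vertices; @param directed directedness.
#' @export
randomPoolGraph <- function(nVertices = 6L, labels = c("A", "B"),
                            pActive = 0.7, pEdge = 0.3, directed = FALSE) {
  lab <- ifelse(runif(nVertices) < pActive,
                sample(labels, nVertices, replace = TRUE), NA_character_)
  adj <- matrix(0L, nVertices, nVertices)
  act <- which(!is.na(lab))
  if (length(act) >= 2) {
    pr <- utils::combn(act, 2)
    for (ci in seq_len(ncol(pr))) {
      if (runif(1) < pEdge) {
        adj[pr[1, ci], pr[2, ci]] <- 1L
        adj[pr[2, ci], pr[1, ci]] <- 1L
      }
    }
  }
  poolGraphFromConfig(lab, adj, directed = directed)
}

#' Random slice graph of a given kind (construct-by-predicate)
#'
#' Vertices get random levels/dimensions; candidate edges are kept only
#' when the kind's edge predicate holds, so the result always passes
#' [validateSliceGraph()].
#'
#' @param kind a [SliceKind-class].
#' @param nVertices vertex count; @param maxLevel maximum level;
#' @param pEdge candidate edge probability.
#' @export
randomSliceGraph <- function(kind, nVertices = 6L, maxLevel = 3L,
                             pEdge = 0.5) {
  g <- poolGraph(capacity = nVertices, directed = kind@directed)
  lv <- sample(0:maxLevel, nVertices, replace = TRUE)
  dv <- sample(0:kind@D, nVertices, replace = TRUE)
  for (i in seq_len(nVertices)) {
    pars <- list()
    if (needsLevel(kind@kind)) pars$l <- lv[i]
    if (needsDim(kind@kind)) pars$d <- dv[i]
    al <- allocateVertex(g, "s", pars)
    g <- al$state
  }
  for (i in seq_len(nVertices)) for (j in seq_len(nVertices)) {
    if (i == j) next
    if (!kind@directed && i > j) next
    if (runif(1) < pEdge &&
        sliceEdgeOK(kind@kind, kind@directed, lv[i], dv[i], lv[j], dv[j]))
      g <- addEdge(g, i, j)
  }
  g
}

#' Seed-deterministic bundle of random fixtures
#'
#' @param seed integer seed.
#' @param n number of each fixture kind.
#' @return list with `pureRulesets`, `graphRules`, `poolGraphs`,
#'   `sliceGraphs`.
#' @export
randomFixtures <- function(seed = 0L, n = 5L) {
  set.seed(seed)
  list(
    pureRulesets = replicate(n, randomPureRuleset(), simplify = FALSE),
    graphRules = replicate(n, randomGraphRule(), simplify = FALSE),
    poolGraphs = replicate(n, randomPoolGraph(), simplify = FALSE),
    sliceGraphs = replicate(n, randomSliceGraph(sliceKind("graded_stratified",
                                                          D = 2L)),
                            simplify = FALSE))
}
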