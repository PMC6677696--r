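## Triangular mesh refinement as a graded graph grammar.
##
## A triangle at level l is a 3-clique of level-l vertices.  Refining a
## triangle keeps its three corners, creates level-(l+1) copies of the
## corners and midpoints of the three sides, connects each corner to its
## copy by a level-raising edge, builds the four sub-triangle cliques at
## the new level (9 new-level edges over 6 new-level vertices), and deletes
## the level-l side edges -- so a refined triangle can never re-fire, and a
## neighbouring triangle sees a "refined side" as: side edge absent, corner
## copies and midpoint present.  Four rules cover triangles with 0, 1, 2 or
## 3 already-refined sides; all preserve the graded-graph constraint that
## edges change level by at most one.

meshVertex <- function(lvlExpr = NULL) {
  if (is.null(lvlExpr)) list(label = "v")
  else list(label = "v", params = list(l = lvlExpr))
}

## build one refinement rule; `nref` = number of already-refined sides.
## Shared numbering: 1,2,3 corners (level l); 4,5,6 corner copies of
## 1,2,3; 7,8,9 midpoints of sides 12, 13, 23 (level l+1).
meshRule <- function(nref, slice = FALSE) {
  lv <- function(v) {
    if (slice) return(meshVertex())
    meshVertex(if (v <= 3) "l" else "(l + 1)")
  }
  cross <- list(c(1, 4), c(2, 5), c(3, 6))
  sideE <- list(`12` = c(1, 2), `13` = c(1, 3), `23` = c(2, 3))
  copyMid <- list(`12` = list(c(4, 7), c(5, 7)),
                  `13` = list(c(4, 8), c(6, 8)),
                  `23` = list(c(5, 9), c(6, 9)))
  midOf <- c(`12` = 7, `13` = 8, `23` = 9)
  copiesOf <- list(`12` = c(4, 5), `13` = c(4, 6), `23` = c(5, 6))
  refined <- names(sideE)[seq_len(nref)]      # sides already refined
  unrefined <- setdiff(names(sideE), refined)

  lhsV <- c(1, 2, 3)
  lhsEdges <- list(); lhsForbid <- list()
  for (s in unrefined) lhsEdges <- c(lhsEdges, list(sideE[[s]]))
  for (s in refined) {
    lhsV <- union(lhsV, c(copiesOf[[s]], midOf[[s]]))
    lhsEdges <- c(lhsEdges, copyMid[[s]])
    lhsForbid <- c(lhsForbid, list(sideE[[s]]))
  }
  for (v in intersect(lhsV, 4:6)) lhsEdges <- c(lhsEdges, cross[v - 3])
  if (nref == 3L)  # nothing else distinguishes a fully-surrounded
    lhsForbid <- c(lhsForbid, list(c(7, 8), c(7, 9), c(8, 9)))  # unrefined

  rhsV <- 1:9
  rhsEdges <- c(cross,
                copyMid[["12"]], copyMid[["13"]], copyMid[["23"]],
                list(c(7, 8), c(7, 9), c(8, 9)))

  mkPat <- function(vs, edges, forbid = NULL) {
    verts <- setNames(lapply(vs, lv), as.character(vs))
    delta <- NULL
    if (slice && length(edges)) {
      delta <- lapply(edges, function(e) {
        d <- if (e[1] <= 3 && e[2] >= 4) 1 else 0  # corner -> copy raises l
        c(e[1], e[2], d)
      })
    }
    graphPattern(9L, verts, edges = if (length(edges)) edges else NULL,
                 forbid = if (length(forbid)) forbid else NULL,
                 directed = FALSE, edgeDelta = delta)
  }
  rate <- if (slice) "kref" else "kref * ind(l < lmax)"
  graphRule(mkPat(lhsV, lhsEdges, lhsForbid),
            mkPat(rhsV, rhsEdges),
            rate = rate, cleanupMode = "full",
            sliceKind = if (slice) "graded" else "",
            ruleId = paste0("refine", nref))
}

#' Triangular mesh refinement grammar (graded graph rules)
#'
#' Four graph rewrite rules, one per count of already-refined sides
#' (0, 1, 2, 3). Each consumes a level-`l` triangle configuration and
#' produces the four level-`(l+1)` sub-triangles, sharing the kept corner
#' vertices; all rules preserve the graded-graph constraints on level
#' numbers.
#'
#' @param kref refinement rate constant.
#' @param lmax maximum refinement level: the rate is gated to zero on
#'   triangles at `l >= lmax` (ignored for slice-level rules, which carry
#'   no level variables by construction).
#' @param slice build the rules at the slice (graded-graph) level: vertex
#'   levels are dropped and edges carry level increments instead; see
#'   [lowerSliceRule()].
#' @return a [Ruleset-class] with four rules.
#' @export
meshRefinementGrammar <- function(kref = 1, lmax = 1, slice = FALSE) {
  ruleset(lapply(0:3, meshRule, slice = slice),
          params = list(kref = kref, lmax = lmax))
}

#' Build an initial triangle mesh
#'
#' A fan of `n` triangles sharing consecutive sides (for `n = 1`, a single
#' triangle), all vertices at level 0.
#'
#' @param n number of triangles.
#' @return a [PoolGraph-class] (undirected; symmetric edge pairs).
#' @export
makeTriangleMesh <- function(n = 1L) {
  g <- poolGraph(capacity = n + 2L, directed = FALSE)
  ids <- integer(n + 2L)
  for (i in seq_len(n + 2L)) {
    al <- allocateVertex(g, "v", list(l = 0))
    g <- al$state; ids[i] <- al$index
  }
  for (t in seq_len(n)) {
    tri <- ids[c(t, t + 1L, t + 2L)]
    g <- addEdge(g, tri[1], tri[2])
    g <- addEdge(g, tri[1], tri[3])
    g <- addEdge(g, tri[2], tri[3])
  }
  g
}

#' Run a ruleset to quiescence (no enabled instance remains)
#'
#' Fires SSA events until the total propensity is zero or `maxEvents` is
#' reached; returns the final state, the event count, and the per-event
#' validator reports collected with `validator`.
#'
#' @param rs a [Ruleset-class].
#' @param state0 initial state.
#' @param seed integer seed.
#' @param maxEvents guard.
#' @param validator optional function(state) returning a character vector
#'   of violations, called after every firing.
#' @export
runToQuiescence <- function(rs, state0, seed = 1L, maxEvents = 1000L,
                            validator = NULL) {
  set.seed(seed)
  state <- state0
  nev <- 0L
  reports <- list()
  repeat {
    inst <- collectInstances(rs, state)
    if (!length(inst)) break
    props <- vapply(inst, function(x) x$prop, numeric(1))
    total <- sum(props)
    if (total <= 0) break
    pick <- which(runif(1) * total <= cumsum(props))[1L]
    x <- inst[[pick]]
    fr <- fireGraphRule(state, x$rule, x$match, checkMatch = FALSE,
                        params = rs@params)
    state <- fr$state
    nev <- nev + 1L
    if (!is.null(validator))
      reports[[nev]] <- validator(state)
    if (nev >= maxEvents) break
  }
  list(state = state, events = nev, reports = reports)
}

#' Count level-l vertices, level-l edges, and level-l triangles of a mesh
#' @param g a [PoolGraph-class] with vertex levels `l`.
#' @param level the level to count at.
#' @return `list(vertices, edges, triangles)`.
#' @export
meshLevelCounts <- function(g, level) {
  idx <- which(g@active)
  lv <- vapply(idx, function(i) g@params[[i]][["l"]] %||% NA_real_, numeric(1))
  atL <- idx[!is.na(lv) & lv == level]
  sub <- g@adj[atL, atL, drop = FALSE]
  nEdges <- sum(sub) / 2  # undirected: symmetric pairs
  nTri <- 0L
  if (length(atL) >= 3) {
    combs <- utils::combn(seq_along(atL), 3)
    for (ci in seq_len(ncol(combs))) {
      a <- combs[1, ci]; b <- combs[2, ci]; cc <- combs[3, ci]
      if (sub[a, b] == 1L && sub[a, cc] == 1L && sub[b, cc] == 1L)
        nTri <- nTri + 1L
    }
  }
  list(vertices = length(atL), edges = nEdges, triangles = nTri)
}
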