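## Cortical microtubule (CMT) dynamics as a dynamical graph grammar.
## Fibers are chains of segment super-particles (center-of-mass position x,
## unit orientation u, both 2-D) with a four-valued status label
## {internal, grow_end, retract_end, junct}.  Processes covered:
## nucleation, treadmilling (growth at the plus end, retraction at the
## minus end), catastrophe/rescue switching of the plus end, and
## low-angle zippering into a bundle.

#' Microtubule dynamics grammar
#'
#' Builds the ruleset:
#' \itemize{
#'   \item nucleation: an isolated two-segment fiber
#'     (retract_end -- grow_end) appears at a uniform random position with
#'     uniform random orientation (+2 segments);
#'   \item growth: `grow_end[x,u]` becomes `internal[x,u]` linked to a new
#'     `grow_end[x + L u, u]` (+1);
#'   \item retraction: a `retract_end` adjacent to an `internal` is deleted
#'     (full cleanup) and the internal becomes the new retract_end (-1);
#'   \item catastrophe / rescue: `grow_end` and `retract_end` relabel into
#'     each other (0);
#'   \item zippering: a `grow_end` within capture radius `delta` of a
#'     non-adjacent `internal` segment of relative line angle below
#'     `thetac` relabels to `junct`, connects to that segment and
#'     reorients (up to sign) along it (0).
#' }
#'
#' @param knuc,kgrow,kret,kcat,kres,kzip process rates (>= 0).
#' @param L segment length.
#' @param thetac zippering angle threshold in (0, pi/2).
#' @param delta capture radius for zippering.
#' @param Ldom side of the square nucleation domain.
#' @return a [Ruleset-class].
#' @export
microtubuleGrammar <- function(knuc = 0.05, kgrow = 1, kret = 1.5,
                               kcat = 0.3, kres = 0.3, kzip = 0.2,
                               L = 0.5, thetac = pi / 5, delta = 0.6,
                               Ldom = 10) {
  rates <- c(knuc = knuc, kgrow = kgrow, kret = kret, kcat = kcat,
             kres = kres, kzip = kzip)
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (thetac <= 0 || thetac >= pi / 2) stop("thetac must lie in (0, pi/2)")
  if (L <= 0 || delta <= 0) stop("L and delta must be positive")

  nuc <- graphRule(
    graphPattern(2L, list()),
    graphPattern(2L, list(
      `1` = list(label = "retract_end",
                 params = list(x = "xn", u = "un")),
      `2` = list(label = "grow_end",
                 params = list(x = "xn + Lseg * un", u = "un"))),
      edges = list(c(1, 2))),
    rate = "knuc",
    samplers = list(sampler("xn", "uniform", "0", "Ldom", dim = 2L),
                    sampler("un", "unitvec", dim = 2L)),
    ruleId = "nucleate")

  grow <- graphRule(
    graphPattern(2L, list(
      `1` = list(label = "grow_end", params = list(x = "x", u = "u")))),
    graphPattern(2L, list(
      `1` = list(label = "internal"),
      `2` = list(label = "grow_end",
                 params = list(x = "x + Lseg * u", u = "u"))),
      edges = list(c(1, 2))),
    rate = "kgrow", ruleId = "grow")

  retract <- graphRule(
    graphPattern(2L, list(
      `1` = list(label = "retract_end"),
      `2` = list(label = "internal")),
      edges = list(c(1, 2))),
    graphPattern(2L, list(`2` = list(label = "retract_end"))),
    rate = "kret", cleanupMode = "full", ruleId = "retract")

  catastrophe <- graphRule(
    graphPattern(1L, list(`1` = list(label = "grow_end"))),
    graphPattern(1L, list(`1` = list(label = "retract_end"))),
    rate = "kcat", ruleId = "catastrophe")

  rescue <- graphRule(
    graphPattern(1L, list(`1` = list(label = "retract_end"))),
    graphPattern(1L, list(`1` = list(label = "grow_end"))),
    rate = "kres", ruleId = "rescue")

  ## Zippering consumes the colliding tip: it becomes a junction segment
  ## attached to the hit fiber, reoriented (up to sign) along it.  The
  ## bundle's continued elongation is carried by the host fiber's own
  ## growing end, so zippering changes no segment count.
  zipper <- graphRule(
    graphPattern(2L, list(
      `1` = list(label = "grow_end", params = list(x = "x1", u = "u1")),
      `2` = list(label = "internal", params = list(x = "x2", u = "u2"))),
      forbid = list(c(1, 2))),
    graphPattern(2L, list(
      `1` = list(label = "junct", params = list(u = "ua")),
      `2` = list(label = "internal")),
      edges = list(c(1, 2))),
    rate = paste0("kzip * ind(norm2(x1 - x2) < delta & ",
                  "acos(min(abs(dot(u1, u2)), 1)) < thetac)"),
    samplers = list(sampler("ua", "delta",
                            "u2 * (2 * ind(dot(u1, u2) >= 0) - 1)", dim = 2L)),
    ruleId = "zipper")

  ruleset(nuc, grow, retract, catastrophe, rescue, zipper,
          params = c(as.list(rates),
                     list(Lseg = L, thetac = thetac, delta = delta,
                          Ldom = Ldom)))
}

#' Segment-count change per event for the microtubule grammar
#'
#' @return named integer vector: the expected change in active segment
#'   count per firing of each rule.
#' @export
mtSegmentDeltas <- function() {
  c(nucleate = 2L, grow = 1L, retract = -1L, catastrophe = 0L,
    rescue = 0L, zipper = 0L)
}

#' Build a single straight microtubule fiber
#'
#' A chain retract_end -- internal ... internal -- grow_end of
#' `nSegments` segments spaced `L` apart along direction `u`.
#'
#' @param nSegments number of segments (>= 2).
#' @param x0 position of the minus end.
#' @param u unit direction vector.
#' @param L segment length.
#' @export
makeMtFiber <- function(nSegments = 3L, x0 = c(0, 0), u = c(1, 0), L = 0.5) {
  stopifnot(nSegments >= 2L)
  g <- poolGraph(capacity = nSegments, directed = FALSE)
  prev <- NA_integer_
  for (i in seq_len(nSegments)) {
    lab <- if (i == 1L) "retract_end"
           else if (i == nSegments) "grow_end" else "internal"
    al <- allocateVertex(g, lab, list(x = x0 + (i - 1) * L * u, u = u))
    g <- al$state
    if (!is.na(prev)) g <- addEdge(g, prev, al$index)
    prev <- al$index
  }
  g
}

#' Check the end-label invariant of a microtubule state
#'
#' Walks every maximal chain of non-junct segments: each free extremity (a
#' chain-end segment with no junct neighbour) must carry a `grow_end` or
#' `retract_end` label, and every non-end chain segment must be `internal`.
#'
#' @param state a [PoolGraph-class] from a microtubule simulation.
#' @return character vector of violations (empty when the invariant holds).
#' @export
mtEndLabelCheck <- function(state) {
  out <- character(0)
  idx <- which(state@active)
  if (!length(idx)) return(out)
  lab <- state@label
  nonj <- idx[lab[idx] != "junct"]
  if (!length(nonj)) return(out)
  sub <- state@adj[nonj, nonj, drop = FALSE]
  ## connected components of the non-junct subgraph
  comp <- rep(0L, length(nonj)); cid <- 0L
  for (s in seq_along(nonj)) {
    if (comp[s] > 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(sub[v, ] == 1L & comp == 0L))
    }
  }
  for (ci in seq_len(cid)) {
    mem <- which(comp == ci)
    deg <- rowSums(sub[mem, mem, drop = FALSE])
    for (mi in seq_along(mem)) {
      v <- nonj[mem[mi]]
      hasJunct <- any(state@adj[v, idx[lab[idx] == "junct"]] == 1L)
      if (deg[mi] <= 1 && !hasJunct) {
        ## free extremity
        if (!lab[v] %in% c("grow_end", "retract_end"))
          out <- c(out, paste0("free chain end ", v, " labeled ", lab[v]))
      } else if (deg[mi] >= 2) {
        if (lab[v] != "internal")
          out <- c(out, paste0("chain-interior segment ", v,
                               " labeled ", lab[v]))
      }
    }
  }
  out
}
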