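## Breakable-spring biomechanics.  Each spring (p,q) contributes
##   V_pq = (1/2) k_pq c_pq [ (|x_p - x_q| - l_pq)^2 - dl_pq^2 ],
## where c_pq in {0,1} is chosen to minimize V: the spring is unbroken
## (c = 1) exactly when (|x_p - x_q| - l_pq)^2 <= dl_pq^2, i.e. when the
## bracket is <= 0.  At stretch l + dl the two branches meet at zero, so
## the potential is continuous at the breaking point; broken springs exert
## no force.  Overdamped motion dx/dt = -grad V is expressed as an
## ODE-bearing rule over node and spring terms.

#' Breakable-spring potential energy and gradient
#'
#' @param positions numeric matrix (n x d) of node positions.
#' @param springs data.frame with columns `p`, `q` (node indices), `k`
#'   (spring constant > 0), `l` (resting length), `dl` (breaking stretch
#'   > 0).
#' @return `list(energy, gradient)`; the gradient is an n x d matrix, zero
#'   for broken springs, with a fixed direction convention (zero force)
#'   for coincident endpoints.
#' @export
springEnergy <- function(positions, springs) {
  positions <- as.matrix(positions)
  grad <- matrix(0, nrow(positions), ncol(positions))
  energy <- 0
  for (r in seq_len(nrow(springs))) {
    p <- springs$p[r]; q <- springs$q[r]
    k <- springs$k[r]; l <- springs$l[r]; dl <- springs$dl[r]
    stopifnot(k > 0, dl > 0)
    dx <- positions[p, ] - positions[q, ]
    rr <- sqrt(sum(dx^2))
    bracket <- (rr - l)^2 - dl^2
    if (bracket <= 0) {               # unbroken branch minimizes V
      energy <- energy + 0.5 * k * bracket
      dir <- if (rr > 0) dx / rr else rep(0, length(dx))
      f <- k * (rr - l) * dir
      grad[p, ] <- grad[p, ] + f
      grad[q, ] <- grad[q, ] - f
    }
    ## broken branch: energy 0, force 0
  }
  list(energy = energy, gradient = grad)
}

#' Overdamped spring relaxation as an ODE-bearing rule
#'
#' Builds a term pool of `node[id, x]` and `spring[p, q, k, l, dl]` terms
#' and an ODE rule whose matches (one per spring) contribute the spring
#' force to both endpoint nodes: `dx/dt = -grad V`.
#'
#' @param positions n x d matrix of initial node positions.
#' @param springs spring table as in [springEnergy()].
#' @return `list(ruleset, pool)` ready for [simulateHybrid()].
#' @export
springDriftModel <- function(positions, springs) {
  positions <- as.matrix(positions)
  pool <- termPool()
  for (i in seq_len(nrow(positions)))
    pool <- addTerm(pool, "node", list(i, unname(positions[i, ])))
  for (r in seq_len(nrow(springs)))
    pool <- addTerm(pool, "spring",
                    list(springs$p[r], springs$q[r], springs$k[r],
                         springs$l[r], springs$dl[r]))
  force <- paste0(
    "-ks * ind((norm2(xp - xq) - ls)^2 <= dls^2) * ",
    "(norm2(xp - xq) - ls) * (xp - xq) / max(norm2(xp - xq), 1e-12)")
  drift <- odeRule(
    terms = list(termPattern("spring", "p", "q", "ks", "ls", "dls"),
                 termPattern("node", "p", "xp"),
                 termPattern("node", "q", "xq")),
    drifts = list(list(term = 2, slot = 2, expr = force),
                  list(term = 3, slot = 2,
                       expr = paste0("-(", force, ")"))),
    ruleId = "spring_drift")
  list(ruleset = ruleset(drift), pool = pool)
}

#' Node positions of a spring model pool
#' @param pool a [TermPool-class] from [springDriftModel()].
#' @return matrix of positions ordered by node id.
#' @export
springPositions <- function(pool) {
  nodes <- Filter(function(t) t$type == "node", pool@terms)
  ids <- vapply(nodes, function(t) t$args[[1]], numeric(1))
  do.call(rbind, lapply(nodes[order(ids)], function(t) t$args[[2]]))
}
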