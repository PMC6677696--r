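## Hybrid jump-ODE simulation by operator splitting with exact
## integrated-hazard event timing: between discrete events all continuous
## term parameters evolve under the summed drifts of every matching ODE
## rule, while the cumulative hazard H(t) = int lambda_total(x(s)) ds is
## co-integrated; the next event fires when H crosses an Exp(1) threshold
## (root-found by the integrator), which samples the exact inhomogeneous
## waiting-time distribution.

## flatten the numeric arguments of all pool terms into one vector;
## returns list(y, index) with index[[term]][[slot]] = positions in y
flattenPool <- function(pool) {
  y <- numeric(0); index <- vector("list", length(pool@terms))
  for (ti in seq_along(pool@terms)) {
    args <- pool@terms[[ti]]$args
    index[[ti]] <- vector("list", length(args))
    for (si in seq_along(args)) {
      v <- args[[si]]
      if (is.numeric(v) && length(v)) {
        index[[ti]][[si]] <- length(y) + seq_along(v)
        y <- c(y, v)
      }
    }
  }
  list(y = y, index = index)
}

unflattenPool <- function(pool, y, index) {
  for (ti in seq_along(pool@terms))
    for (si in seq_along(index[[ti]]))
      if (!is.null(index[[ti]][[si]]))
        pool@terms[[ti]]$args[[si]] <- unname(y[index[[ti]][[si]]])
  pool
}

## variable -> y-position map for one match (variables bound to whole slots)
matchVarIndex <- function(patterns, match, index) {
  out <- list()
  for (p in seq_along(patterns)) {
    ti <- match$idx[p]
    for (s in seq_along(patterns[[p]]@args)) {
      a <- patterns[[p]]@args[[s]]
      if (isVar(a)) out[[as.character(a)]] <- index[[ti]][[s]]
    }
  }
  out
}

bindingsAt <- function(varIdx, constBnd, y) {
  b <- constBnd
  for (nm in names(varIdx)) b[[nm]] <- y[varIdx[[nm]]]
  b
}

#' Hybrid jump-ODE simulation
#'
#' @param rs a [Ruleset-class] mixing ODE rules with discrete
#'   (pure/parameterized) rules.
#' @param state0 a [TermPool-class].
#' @param tmax horizon.
#' @param seed integer seed (`NULL` = current RNG state).
#' @param tol relative/absolute integration tolerance.
#' @param maxEvents guard.
#' @param saveTrajectory record the continuous state at integrator steps.
#' @return `list(log = EventLog, state = final TermPool,
#'   trajectory = data.frame(time, y1..))`.
#' @export
simulateHybrid <- function(rs, state0, tmax, seed = NULL, tol = 1e-8,
                           maxEvents = 1e4, saveTrajectory = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(is(state0, "TermPool"))
  odeRules <- Filter(function(r) is(r, "ODERule"), rs@rules)
  discRules <- Filter(function(r) is(r, "ParamRule") || is(r, "PureRule"),
                      rs@rules)
  pool <- state0
  t <- 0
  events <- list()
  traj <- list()
  params <- rs@params
  while (t < tmax) {
    fp <- flattenPool(pool)
    y <- fp$y; index <- fp$index
    ## ODE drift contributions: per match, per drift spec, target positions
    driftSpecs <- list()
    for (r in odeRules) {
      for (m in matchTermPatterns(r@terms, pool)) {
        vi <- matchVarIndex(r@terms, m, index)
        for (d in r@drifts) {
          tgt <- index[[m$idx[d$term]]][[d$slot]]
          if (is.null(tgt)) next
          driftSpecs[[length(driftSpecs) + 1L]] <-
            list(expr = d$expr, tgt = tgt, varIdx = vi, bnd = m$bindings)
        }
      }
    }
    ## discrete instances with propensity expressions over y
    discSpecs <- list()
    for (r in discRules) {
      if (is(r, "PureRule")) {
        p <- rulePropensity(r, NULL, pool, params)
        if (p > 0)
          discSpecs[[length(discSpecs) + 1L]] <-
            list(rule = r, match = NULL, const = p)
      } else {
        for (m in matchTermPatterns(r@lhs, pool)) {
          vi <- matchVarIndex(r@lhs, m, index)
          discSpecs[[length(discSpecs) + 1L]] <-
            list(rule = r, match = m, varIdx = vi, bnd = m$bindings)
        }
      }
    }
    hazardAt <- function(y) {
      vapply(discSpecs, function(sp) {
        if (!is.null(sp$const)) return(sp$const)
        v <- evalExpression(sp$rule@rateExpr,
                            c(bindingsAt(sp$varIdx, sp$bnd, y), params))
        max(v, 0)
      }, numeric(1))
    }
    ## threshold drawn before integration (draw order: threshold,
    ## selection, RHS samples)
    E <- rexp(1)
    ny <- length(y)
    deriv <- function(tt, st, parms) {
      yy <- st[seq_len(ny)]
      dy <- numeric(ny)
      for (sp in driftSpecs) {
        val <- evalExpression(sp$expr,
                              c(bindingsAt(sp$varIdx, sp$bnd, yy), params))
        dy[sp$tgt] <- dy[sp$tgt] + val
      }
      list(c(dy, sum(hazardAt(yy))))
    }
    rootf <- function(tt, st, parms) st[ny + 1L] - E
    res <- tryCatch(
      deSolve::lsodar(y = c(y, 0), times = c(t, tmax), func = deriv,
                      rootfunc = rootf, rtol = tol, atol = tol),
      error = function(e) stop("integration failure at t = ", t, ": ",
                               conditionMessage(e), call. = FALSE))
    tEnd <- res[nrow(res), 1]
    yEnd <- as.numeric(res[nrow(res), 1 + seq_len(ny)])
    if (saveTrajectory && ny > 0) {
      tr <- res[, c(1, 1 + seq_len(ny)), drop = FALSE]
      traj[[length(traj) + 1L]] <- tr
    }
    pool <- unflattenPool(pool, yEnd, index)
    rootHit <- !is.null(attr(res, "iroot")) ||
      (tEnd < tmax - 1e-12)
    t <- tEnd
    if (!rootHit || t >= tmax) { t <- max(t, tmax); break }
    ## select and fire a discrete instance at the event time
    props <- hazardAt(yEnd)
    total <- sum(props)
    if (total <= 0) next
    pick <- which(runif(1) * total <= cumsum(props))[1L]
    sp <- discSpecs[[pick]]
    if (is(sp$rule, "PureRule")) {
      pool <- firePureOnPool(pool, sp$rule)
      samples <- list(); draws <- 0L
    } else {
      ## refresh the match bindings to the integrated parameter values
      m <- sp$match
      m$bindings <- bindingsAt(sp$varIdx, sp$bnd, yEnd)
      fr <- fireParamRule(pool, sp$rule, m, params = params)
      pool <- fr$state; samples <- fr$samples; draws <- fr$draws
    }
    events[[length(events) + 1L]] <-
      list(time = t, ruleId = sp$rule@ruleId,
           match = if (is.null(sp$match)) list() else list(idx = sp$match$idx),
           samples = samples, draws = draws)
    if (length(events) >= maxEvents) {
      warning("maxEvents guard reached at t = ", t)
      break
    }
  }
  trajectory <- if (length(traj)) {
    df <- as.data.frame(do.call(rbind, traj))
    names(df) <- c("time", paste0("y", seq_len(ncol(df) - 1L)))
    df
  } else data.frame(time = numeric(0))
  list(log = new("EventLog", events = events), state = pool,
       trajectory = trajectory)
}
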