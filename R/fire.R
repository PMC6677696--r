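## Rule firing: apply a matched rule instance to the state.

## draw from a sampler spec; returns list(value, draws = number of rng draws)
drawSampler <- function(s, bindings) {
  argv <- lapply(s$args, evalExpression, bindings = bindings)
  d <- s$dim
  switch(s$dist,
         normal = {
           sd <- argv[[1]]
           list(value = rnorm(d, 0, sd), draws = d)
         },
         uniform = {
           list(value = runif(d, argv[[1]], argv[[2]]), draws = d)
         },
         unitvec = {
           ang <- runif(1, 0, 2 * pi)
           if (d == 2L) list(value = c(cos(ang), sin(ang)), draws = 1L)
           else {
             v <- rnorm(d); list(value = v / sqrt(sum(v^2)), draws = d)
           }
         },
         delta = list(value = argv[[1]], draws = 0L),
         stop("unknown sampler distribution: ", s$dist))
}

runSamplers <- function(samplers, bindings) {
  samples <- list(); draws <- 0L
  for (s in samplers) {
    d <- drawSampler(s, bindings)
    bindings[[s$var]] <- d$value
    samples[[s$var]] <- d$value
    draws <- draws + d$draws
  }
  list(bindings = bindings, samples = samples, draws = draws)
}

#' Fire a parameterized rule on a term pool
#'
#' Removes the matched terms, draws RHS-only variables from the rule's
#' conditional samplers, instantiates the RHS term patterns and inserts
#' them into the pool.
#'
#' @param state a [TermPool-class].
#' @param rule a [ParamRule-class].
#' @param match one element of [matchTermPatterns()] output.
#' @param params named list of global parameter bindings.
#' @return `list(state, samples, draws)`.
#' @export
fireParamRule <- function(state, rule, match, params = list()) {
  sm <- runSamplers(rule@samplers, c(match$bindings, params))
  bnd <- sm$bindings
  keep <- setdiff(seq_along(state@terms), match$idx)
  terms <- state@terms[keep]
  for (tp in rule@rhs) {
    args <- lapply(tp@args, function(a) {
      if (is.numeric(a)) a else evalExpression(a, bnd)
    })
    terms <- c(terms, list(list(type = tp@type, args = args)))
  }
  state@terms <- terms
  list(state = state, samples = sm$samples, draws = sm$draws)
}

## restore slice labels (levels) onto RHS vertices of a slice-level rule by
## propagating edge level-marks from vertices whose level is known
sliceRhsLevels <- function(rule, state, match, sliceLevelParam = "l") {
  rhs <- rule@rhs
  incl <- rhs@included
  lev <- setNames(rep(NA_real_, length(incl)), as.character(incl))
  for (v in intersect(incl, rule@lhs@included)) {
    sv <- match$assign[[as.character(v)]]
    l <- state@params[[sv]][[sliceLevelParam]]
    if (!is.null(l)) lev[[as.character(v)]] <- l
  }
  repeat {
    changed <- FALSE
    for (a in incl) for (b in incl) {
      if (a == b || is.na(rhs@edgeDelta[a, b])) next
      ka <- as.character(a); kb <- as.character(b)
      if (!is.na(lev[[ka]]) && is.na(lev[[kb]])) {
        lev[[kb]] <- lev[[ka]] + rhs@edgeDelta[a, b]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lev
}

#' Fire a graph rewrite rule on a pool graph
#'
#' Vertices numbered on both sides keep their state index and receive the
#' RHS labels/parameters; LHS-only vertices are deallocated subject to the
#' rule's cleanup mode (`"full"`: all incident edges erased; `"none"`: edges
#' left hanging; `"custom"`: per the cleanup spec); RHS-only vertices are
#' freshly allocated (never reusing an index freed by the same firing);
#' exactly the RHS pattern edges among matched/created vertices are created.
#' Edges incident to kept vertices and not mentioned by the rule persist.
#'
#' @param state a [PoolGraph-class].
#' @param rule a [GraphRule-class].
#' @param match one element of [findMatches()] output for `rule@lhs`.
#' @param checkMatch re-verify the match against the current state and stop
#'   with a stale-match error if it no longer applies.
#' @param params named list of global parameter bindings.
#' @return `list(state, samples, draws, newIndices)`.
#' @export
fireGraphRule <- function(state, rule, match, checkMatch = TRUE,
                          params = list()) {
  if (checkMatch && !matchIsCurrent(rule, state, match))
    stop("stale match: state changed since the match was found")
  sm <- runSamplers(rule@samplers, c(match$bindings, params))
  bnd <- sm$bindings
  lhsI <- rule@lhs@included; rhsI <- rule@rhs@included
  kept <- intersect(lhsI, rhsI)
  lhsOnly <- setdiff(lhsI, rhsI)
  rhsOnly <- setdiff(rhsI, lhsI)
  assign <- match$assign  # named by shared number

  isSlice <- nzchar(rule@sliceKind)
  if (isSlice) levels <- sliceRhsLevels(rule, state, match)

  ## 1. allocate RHS-only vertices first, from the pre-firing free list,
  ##    so indices freed by this same firing are never reused within it
  for (v in rhsOnly) {
    pos <- base::match(v, rhsI)
    lb <- rule@rhs@labels[[pos]]
    lbv <- if (is.character(lb)) lb else as.character(evalExpression(lb, bnd))
    pars <- lapply(rule@rhs@params[[pos]], function(a)
      if (is.numeric(a)) a else evalExpression(a, bnd))
    if (isSlice && !is.na(levels[[as.character(v)]]))
      pars[["l"]] <- levels[[as.character(v)]]
    al <- allocateVertex(state, lbv, pars)
    state <- al$state
    assign[[as.character(v)]] <- al$index
  }

  ## 2. annihilate LHS pattern edges
  for (a in lhsI) for (b in lhsI) {
    if (rule@lhs@adj[a, b] == 1L)
      state@adj[assign[[as.character(a)]], assign[[as.character(b)]]] <- 0L
  }

  ## 3. deallocate LHS-only vertices with cleanup
  for (v in lhsOnly) {
    i <- assign[[as.character(v)]]
    state@active[i] <- FALSE
    state@label[i] <- NA_character_
    state@params[[i]] <- list()
    state@freeList <- c(i, state@freeList)
    if (rule@cleanupMode == "full") {
      state@adj[i, ] <- 0L
      state@adj[, i] <- 0L
    } else if (rule@cleanupMode == "custom") {
      cs <- rule@cleanupSpec
      if (v %in% (cs$B %||% integer(0))) {
        excl <- vapply((cs$Bbar %||% list())[[as.character(v)]] %||% integer(0),
                       function(q) assign[[as.character(q)]], integer(1))
        keep <- setdiff(seq_len(ncol(state@adj)), i)
        state@adj[i, setdiff(keep, excl)] <- 0L
      }
      if (v %in% (cs$C %||% integer(0))) {
        excl <- vapply((cs$Cbar %||% list())[[as.character(v)]] %||% integer(0),
                       function(q) assign[[as.character(q)]], integer(1))
        keep <- setdiff(seq_len(nrow(state@adj)), i)
        state@adj[setdiff(keep, excl), i] <- 0L
      }
    }
    ## cleanup "none": edges left hanging (invariant (b) may break; the
    ## validator reports it)
  }

  ## 4. relabel kept vertices and update their parameters
  for (v in kept) {
    pos <- base::match(v, rhsI)
    i <- assign[[as.character(v)]]
    lb <- rule@rhs@labels[[pos]]
    if (is.character(lb)) state@label[i] <- lb
    else state@label[i] <- as.character(evalExpression(lb, bnd))
    pp <- rule@rhs@params[[pos]]
    for (nm in names(pp)) {
      a <- pp[[nm]]
      state@params[[i]][[nm]] <- if (is.numeric(a)) a else evalExpression(a, bnd)
    }
  }

  ## 5. create RHS pattern edges
  for (a in rhsI) for (b in rhsI) {
    if (a != b && rule@rhs@adj[a, b] == 1L)
      state@adj[assign[[as.character(a)]], assign[[as.character(b)]]] <- 1L
  }

  list(state = state, samples = sm$samples, draws = sm$draws,
       newIndices = vapply(as.character(rhsOnly),
                           function(v) assign[[v]], integer(1)))
}
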