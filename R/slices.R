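## Graded graphs, stratified graphs, abstract cell complexes and their
## combinations, as slice-constrained labeled graphs: vertices carry a
## level number l and/or a stratum dimension d, and every edge must satisfy
## the target graph H's edge predicate. Strata extraction and lowering of
## slice-level rewrite rules to ordinary gated graph rules.

#' Construct a slice kind
#'
#' @param kind `"graded"` (levels; edges change level by at most one),
#'   `"stratified"` (dimensions; directed edges go from higher to lower
#'   dimension), `"acc"` (abstract cell complex; dimension drops by exactly
#'   0 or 1), `"graded_stratified"`, `"graded_acc"`.
#' @param D maximum dimension.
#' @param directed logical.
#' @return a [SliceKind-class].
#' @export
sliceKind <- function(kind = c("graded", "stratified", "acc",
                               "graded_stratified", "graded_acc"),
                      D = 3L, directed = FALSE) {
  kind <- match.arg(kind)
  new("SliceKind", kind = kind, D = as.integer(D), directed = directed)
}

needsLevel <- function(kind) kind %in% c("graded", "graded_stratified",
                                         "graded_acc")
needsDim <- function(kind) kind %in% c("stratified", "acc",
                                       "graded_stratified", "graded_acc")

## edge predicate of a slice kind on (l_src, d_src) -> (l_tgt, d_tgt);
## self-connections (equal endpoints) are always permitted
sliceEdgeOK <- function(kind, directed, ls, ds, lt, dt) {
  dl <- lt - ls; dd <- dt - ds
  dimOK <- switch(kind,
                  stratified = , graded_stratified =
                    if (directed) ds >= dt else TRUE,
                  acc = , graded_acc =
                    if (directed) dd %in% c(0, -1) else abs(dd) <= 1,
                  TRUE)
  levOK <- if (directed) dl %in% c(0, 1) else abs(dl) <= 1
  switch(kind,
         graded = levOK,
         stratified = , acc = dimOK,
         graded_stratified = , graded_acc =
           ## level and dimension cannot both change along one edge
           (dl == 0 && dimOK) || (abs(dl) == 1 && levOK && dd == 0))
}

#' Validate a pool graph against a slice kind
#'
#' @param g a [PoolGraph-class] whose vertex parameters include `l`
#'   (level) and/or `d` (dimension) as the kind requires.
#' @param kind a [SliceKind-class].
#' @return character vector describing violating edges (empty iff valid);
#'   missing required labels raise an error.
#' @export
validateSliceGraph <- function(g, kind) {
  stopifnot(is(kind, "SliceKind"))
  viol <- character(0)
  idx <- which(g@active)
  getp <- function(i, nm) {
    v <- g@params[[i]][[nm]]
    if (is.null(v))
      stop("schema error: active vertex ", i, " lacks required label ", sQuote(nm))
    v
  }
  lv <- dv <- setNames(rep(0, length(g@active)), NULL)
  for (i in idx) {
    if (needsLevel(kind@kind)) lv[i] <- getp(i, "l")
    if (needsDim(kind@kind)) {
      dv[i] <- getp(i, "d")
      if (dv[i] < 0 || dv[i] > kind@D)
        viol <- c(viol, paste0("vertex ", i, ": dimension ", dv[i],
                               " outside 0..", kind@D))
    }
  }
  e <- which(g@adj == 1L, arr.ind = TRUE)
  seen <- character(0)
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1]; j <- e[r, 2]
    if (!kind@directed) {
      key <- paste(sort(c(i, j)), collapse = "-")
      if (key %in% seen) next
      seen <- c(seen, key)
    }
    if (!sliceEdgeOK(kind@kind, kind@directed, lv[i], dv[i], lv[j], dv[j]))
      viol <- c(viol, paste0("edge ", i, "->", j, " violates ", kind@kind,
                             " predicate (dl=", lv[j] - lv[i],
                             if (needsDim(kind@kind))
                               paste0(", dd=", dv[j] - dv[i]) else "", ")"))
  }
  viol
}

#' Extract the graph of strata of a stratified pool graph
#'
#' Deletes every edge joining vertices of different dimension, takes the
#' connected components that remain (the strata), and connects two strata
#' by a contact edge, directed from higher to lower dimension, whenever
#' some original edge joins their members. The per-dimension restriction
#' of the result is edgeless, so the strata graph is a DAG.
#'
#' @param g a [PoolGraph-class] valid for a stratified (or richer) kind.
#' @return a [StrataGraph-class].
#' @export
extractStrataGraph <- function(g) {
  idx <- which(g@active)
  if (!length(idx))
    return(new("StrataGraph", dims = integer(0), members = list(),
               edges = matrix(integer(0), 0, 2)))
  dv <- vapply(idx, function(i) {
    v <- g@params[[i]][["d"]]
    if (is.null(v)) stop("schema error: vertex ", i, " lacks dimension d")
    as.numeric(v)
  }, numeric(1))
  e <- which(g@adj == 1L, arr.ind = TRUE)
  same <- e[dv[base::match(e[, 1], idx)] == dv[base::match(e[, 2], idx)], ,
            drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(same[, 1]),
                   to = as.character(same[, 2])),
    directed = FALSE,
    vertices = data.frame(name = as.character(idx)))
  comp <- igraph::components(ig)$membership
  stratum <- comp[as.character(idx)]
  ns <- max(stratum)
  members <- lapply(seq_len(ns), function(s) idx[stratum == s])
  dims <- vapply(seq_len(ns), function(s) as.integer(dv[stratum == s][1]),
                 integer(1))
  ## contact edges between strata of unequal dimension, higher -> lower
  se <- matrix(integer(0), 0, 2)
  if (nrow(e)) {
    s1 <- stratum[as.character(e[, 1])]; s2 <- stratum[as.character(e[, 2])]
    diffD <- dims[s1] != dims[s2]
    if (any(diffD)) {
      pr <- unique(t(apply(cbind(s1[diffD], s2[diffD]), 1, function(p) {
        if (dims[p[1]] >= dims[p[2]]) p else rev(p)
      })))
      se <- matrix(as.integer(pr), ncol = 2)
      se <- unique(se)
    }
  }
  new("StrataGraph", dims = dims, members = members, edges = se)
}

setMethod("show", "StrataGraph", function(object) {
  cat(sprintf("StrataGraph: %d strata (dims %s), %d contact edge(s)\n",
              length(object@dims), paste(object@dims, collapse = ","),
              nrow(object@edges)))
})

#' Lower a slice-level rewrite rule to an ordinary gated graph rule
#'
#' Restores explicit level variables onto the vertices of a slice-level
#' rule (whose patterns carry level increments on edges instead) and
#' multiplies the rate by gating indicators that vanish whenever the LHS or
#' RHS labeling violates the slice kind's validity predicate. On valid
#' matches both gates equal one and the rate is unchanged.
#'
#' @param rule a [GraphRule-class] with `sliceKind` set and `edgeDelta`
#'   marks on its pattern edges.
#' @param kind a [SliceKind-class] (currently the graded family).
#' @param gateLhs include the LHS gate (can be disabled when the initial
#'   state is certified valid).
#' @return an ordinary [GraphRule-class] with explicit `l` parameters.
#' @export
lowerSliceRule <- function(rule, kind, gateLhs = TRUE) {
  stopifnot(is(rule, "GraphRule"), nzchar(rule@sliceKind))
  if (!needsLevel(kind@kind))
    stop("lowering is implemented for the graded kinds (level labels)")
  lhs <- rule@lhs; rhs <- rule@rhs
  allV <- sort(union(lhs@included, rhs@included))
  ## assign a level variable to each shared vertex; propagate equality
  ## constraints along Delta-marked edges of both sides so that connected
  ## vertices share one base variable plus an integer offset
  base <- setNames(as.character(allV), as.character(allV))
  offset <- setNames(rep(0, length(allV)), as.character(allV))
  repeat {
    changed <- FALSE
    for (side in list(lhs, rhs)) {
      for (a in side@included) for (b in side@included) {
        if (a == b || side@adj[a, b] != 1L || is.na(side@edgeDelta[a, b]))
          next
        ka <- as.character(a); kb <- as.character(b)
        if (base[[ka]] != base[[kb]]) {
          ## merge: b's class joins a's
          old <- base[[kb]]
          shift <- offset[[ka]] + side@edgeDelta[a, b] - offset[[kb]]
          for (v in names(base)) if (base[[v]] == old) {
            base[[v]] <- base[[ka]]
            offset[[v]] <- offset[[v]] + shift
          }
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lvar <- function(v) {
    k <- as.character(v)
    bs <- paste0("l", base[[k]])
    if (offset[[k]] == 0) bs
    else paste0("(", bs, " + ", offset[[k]], ")")
  }
  addLevels <- function(side) {
    for (pos in seq_along(side@included)) {
      v <- side@included[pos]
      side@params[[pos]][["l"]] <- parseExpression(lvar(v))
    }
    side@edgeDelta <- matrix(NA_real_, side@k, side@k)
    side
  }
  ## the RHS gate: every RHS edge must satisfy the predicate given the
  ## (symbolic) level assignment; with integer offsets this is decidable
  ## now, but we keep it as a runtime indicator on the bound levels, per
  ## the gating semantics
  gateOf <- function(side) {
    conds <- character(0)
    for (a in side@included) for (b in side@included) {
      if (a == b || side@adj[a, b] != 1L) next
      dl <- paste0("(", lvar(b), " - ", lvar(a), ")")
      cond <- if (kind@directed) paste0("(", dl, " == 0 | ", dl, " == 1)")
      else paste0("(", dl, " >= -1 & ", dl, " <= 1)")
      conds <- c(conds, cond)
    }
    if (!length(conds)) "1" else
      paste0("ind(", paste(conds, collapse = " & "), ")")
  }
  rateTxt <- paste0(
    if (gateLhs) paste0(gateOf(lhs), " * ") else "",
    gateOf(rhs), " * (", formatExpression(rule@rateExpr), ")")
  graphRule(addLevels(lhs), addLevels(rhs),
            rate = parseExpression(rateTxt),
            samplers = rule@samplers, cleanupMode = rule@cleanupMode,
            cleanupSpec = rule@cleanupSpec, sliceKind = "",
            directed = rule@directed,
            ruleId = paste0(rule@ruleId, "_lowered"))
}

#' Lower every slice-level rule of a ruleset
#' @param rs a [Ruleset-class]; @param kind a [SliceKind-class].
#' @param gateLhs see [lowerSliceRule()].
#' @export
lowerRuleset <- function(rs, kind, gateLhs = TRUE) {
  rs@rules <- lapply(rs@rules, function(r) {
    if (is(r, "GraphRule") && nzchar(r@sliceKind)) {
      low <- lowerSliceRule(r, kind, gateLhs)
      low@ruleId <- r@ruleId  # keep ids so event logs are comparable
      low
    } else r
  })
  rs
}
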