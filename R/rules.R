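## Rule validation, the arrow-reversal meta-rule, and small pattern helpers.

isWildcard <- function(a) is.symbol(a) && identical(as.character(a), ".")
isVar <- function(a) is.symbol(a) && !isWildcard(a)
isConst <- function(a) is.numeric(a) || is.character(a)

## variables bound by matching a list of term patterns on the LHS
lhsBoundVars <- function(patterns) {
  out <- character(0)
  for (tp in patterns)
    for (a in tp@args) if (isVar(a)) out <- c(out, as.character(a))
  unique(out)
}

graphLhsBoundVars <- function(pat) {
  out <- character(0)
  for (i in seq_along(pat@included)) {
    lb <- pat@labels[[i]]
    if (is.symbol(lb)) out <- c(out, as.character(lb))
    for (a in pat@params[[i]]) if (isVar(a)) out <- c(out, as.character(a))
  }
  unique(out)
}

#' Reverse a pure reaction rule (arrow-reversal meta-rule)
#'
#' Swaps LHS and RHS stoichiometries and gives the reversed rule a fresh
#' rate symbol, enabling detailed-balance pairs to be written from one
#' direction only. Reversal is an involution on the stoichiometries.
#'
#' @param rule a [PureRule-class].
#' @param newId id for the reversed rule (default `<id>_rev`).
#' @return the reversed [PureRule-class].
#' @export
reverseRule <- function(rule, newId = paste0(rule@ruleId, "_rev")) {
  if (!is(rule, "PureRule"))
    stop("unsupported rule variant: arrow reversal is defined for pure ",
         "reaction rules (graph-rule reversal may leave cleanup ill-defined)")
  rateName <- if (is.character(rule@rate)) rule@rate else
    paste0("k_", rule@ruleId)
  new("PureRule", ruleId = newId, lhs = rule@rhs, rhs = rule@lhs,
      rate = paste0(rateName, "_prime"))
}

#' Validate a rule (or ruleset), returning diagnostics
#'
#' Checks the type invariants of each rule variant and returns a character
#' vector of human-readable diagnostics (empty when all invariants hold).
#' Diagnostics are returned, never thrown.
#'
#' @param rule a rule object or a [Ruleset-class].
#' @param known names that count as bound besides the LHS bindings
#'   (global model parameters); filled automatically for rulesets.
#' @return character vector of diagnostics.
#' @export
validateRule <- function(rule, known = character(0)) {
  if (is(rule, "Ruleset")) {
    known <- unique(c(known, names(rule@params)))
    out <- unlist(lapply(rule@rules, validateRule, known = known))
    ids <- vapply(rule@rules, function(r) r@ruleId, character(1))
    if (anyDuplicated(ids))
      out <- c(out, paste0("duplicate rule id: ",
                           paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    return(out %||% character(0))
  }
  diags <- character(0)
  add <- function(msg) diags <<- c(diags, paste0(rule@ruleId, ": ", msg))
  if (is(rule, "PureRule")) {
    if (any(rule@lhs < 0) || any(rule@rhs < 0))
      add("negative stoichiometry")
    if (any(rule@lhs != round(rule@lhs)) || any(rule@rhs != round(rule@rhs)))
      add("non-integer stoichiometry")
    if (is.numeric(rule@rate) && rule@rate < 0)
      add("negative rate")
  } else if (is(rule, "ParamRule")) {
    bound <- c(lhsBoundVars(rule@lhs), known)
    sampled <- vapply(rule@samplers, function(s) s$var, character(1))
    rateVars <- expressionVars(rule@rateExpr)
    free <- setdiff(rateVars, bound)
    if (length(free))
      add(paste0("propensity expression uses variables not bound on the LHS: ",
                 paste(free, collapse = ", ")))
    for (tp in rule@rhs) for (a in tp@args) {
      if (isWildcard(a)) add("wildcard in RHS term pattern")
      vs <- if (is.symbol(a) || is.call(a)) expressionVars(a) else character(0)
      uncov <- setdiff(vs, c(bound, sampled))
      if (length(uncov))
        add(paste0("RHS variable(s) not bound on LHS nor covered by a sampler: ",
                   paste(uncov, collapse = ", ")))
    }
  } else if (is(rule, "ODERule")) {
    bound <- c(lhsBoundVars(rule@terms), known)
    for (d in rule@drifts) {
      if (d$term < 1 || d$term > length(rule@terms))
        add("drift references a nonexistent term")
      free <- setdiff(expressionVars(d$expr), bound)
      if (length(free))
        add(paste0("drift references unbound parameter(s): ",
                   paste(free, collapse = ", ")))
    }
  } else if (is(rule, "GraphRule")) {
    for (side in list(lhs = rule@lhs, rhs = rule@rhs)) {
      if (nrow(side@adj) != side@k || ncol(side@adj) != side@k)
        add("adjacency matrix size does not match shared numbering")
      if (is.unsorted(side@included, strictly = TRUE))
        add("vertex numbering map is not strictly increasing")
    }
    both <- which(rule@lhs@adj == 1L & rule@lhs@forbid == 1L, arr.ind = TRUE)
    if (nrow(both))
      add(paste0("unsatisfiable: required and prohibited edge at (",
                 paste(apply(both, 1, paste, collapse = ","), collapse = "); ("),
                 ")"))
    bound <- c(graphLhsBoundVars(rule@lhs), known)
    sampled <- vapply(rule@samplers, function(s) s$var, character(1))
    for (i in seq_along(rule@rhs@included)) {
      lb <- rule@rhs@labels[[i]]
      vs <- character(0)
      if (is.symbol(lb)) vs <- as.character(lb)
      for (a in rule@rhs@params[[i]])
        if (is.symbol(a) || is.call(a)) vs <- c(vs, expressionVars(a))
      uncov <- setdiff(vs, c(bound, sampled))
      if (length(uncov))
        add(paste0("RHS label/parameter variable(s) without LHS binding or sampler: ",
                   paste(uncov, collapse = ", ")))
    }
    if (!rule@cleanupMode %in% c("full", "none", "custom"))
      add("unknown cleanup mode")
  } else {
    add("unknown rule variant")
  }
  diags
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Infer the symbol table (species / labels / term types) of a ruleset.
rulesetSymbols <- function(rs) {
  if (length(rs@symbols)) return(rs@symbols)
  syms <- character(0)
  for (r in rs@rules) {
    if (is(r, "PureRule")) syms <- c(syms, names(r@lhs), names(r@rhs))
    else if (is(r, "ParamRule"))
      syms <- c(syms, vapply(c(r@lhs, r@rhs), function(tp) tp@type, character(1)))
    else if (is(r, "ODERule"))
      syms <- c(syms, vapply(r@terms, function(tp) tp@type, character(1)))
    else if (is(r, "GraphRule"))
      for (side in list(r@lhs, r@rhs))
        for (lb in side@labels) if (is.character(lb)) syms <- c(syms, lb)
  }
  unique(syms)
}
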