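## Stem-cell asymmetric division grammar: a single parameterized rule in
## which a stem cell of volume V divides into a transit-amplifying cell and
## a stem cell, each of volume V/2, displaced symmetrically about the
## mother position by a Gaussian offset whose scale is set by cell volume.

#' Stem-cell division grammar
#'
#' One parameterized rule
#' `stemcell[x, V] -> TAcell[x + dx, V/2], stemcell[x - dx, V/2]`
#' with LHS propensity `rhoHat(V)` and `dx` drawn from a zero-mean Gaussian
#' with diagonal covariance of scale `c * V^(1/d)` (a lengthscale set by
#' cell volume). The two daughters receive exactly opposite displacements,
#' so the propensity depends on position only through the displacement
#' (Galilean invariance) and the daughter midpoint is the mother position;
#' total volume is conserved exactly per firing.
#'
#' @param rhoHat propensity expression in `V` (character). The default is a
#'   saturating Hill form `V^h / (V^h + K^h)`.
#' @param c displacement scale coefficient (>= 0).
#' @param d spatial dimension (1, 2 or 3).
#' @param h,K Hill exponent and half-saturation volume of the default
#'   propensity.
#' @return a [Ruleset-class] with the division rule.
#' @export
stemCellGrammar <- function(rhoHat = "V^h / (V^h + K^h)", c = 0.1, d = 2L,
                            h = 4, K = 1) {
  if (!d %in% 1:3) stop("invalid dimension d (must be 1, 2 or 3)")
  if (c < 0) stop("displacement scale c must be nonnegative")
  div <- paramRule(
    lhs = list(termPattern("stemcell", "x", "V")),
    rhs = list(termPattern("TAcell", "x + dx", "V/2"),
               termPattern("stemcell", "x - dx", "V/2")),
    rate = rhoHat,
    samplers = list(sampler("dx", "normal", "cdisp * V^(1/ddim)", dim = d)),
    ruleId = "divide")
  ruleset(div, params = list(cdisp = c, ddim = as.numeric(d),
                             h = h, K = K))
}

#' Initial stem-cell pool
#' @param n number of stem cells; @param V0 initial volume; @param d
#'   spatial dimension.
#' @export
makeStemCellPool <- function(n = 1L, V0 = 2, d = 2L) {
  pool <- termPool()
  for (i in seq_len(n))
    pool <- addTerm(pool, "stemcell", list(rep(0, d), V0))
  pool
}

#' Total volume of a cell pool (conserved by division)
#' @param pool a [TermPool-class] of `stemcell`/`TAcell` terms.
#' @export
totalVolume <- function(pool) {
  sum(vapply(pool@terms, function(t) t$args[[2]], numeric(1)))
}
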