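## Normal-form symbolic algebra of graph rewrite rule operators.
##
## The state algebra lives on an indexed collection of binary state
## variables ("bits"): one bit per (vertex index, label) pair and one per
## ordered vertex pair (directed edge occupancy).  On a single bit the six
## nonzero deterministic conditional assignments
##
##   z    = |0><0|            (require 0, leave 0;  Z = I - ahat a)
##   ahat = |1><0|            (require 0, set 1;    creation)
##   a    = |0><1|            (require 1, set 0;    annihilation)
##   n    = |1><1|            (require 1, leave 1;  number/presence check)
##   e    = |0><0| + |0><1|   (no requirement, set 0;  erasure E = Z + a)
##   f    = |1><0| + |1><1|   (no requirement, set 1;  F = ahat + N)
##
## are closed under composition (with zero), so a normal-form term carries
## exactly ONE generator per touched bit and products of terms never expand
## into per-bit sums.  A term additionally carries a set of abstract vertex
## indices constrained pairwise distinct (the sum over distinct ordered
## index tuples) and symbolic erasure ranges: products of E factors over
## every partner index outside an exclusion set, which realize vertex
## deallocation cleanup without enumerating the index universe.

.genInfo <- list(z = c(0L, 0L), ahat = c(0L, 1L), a = c(1L, 0L),
                 n = c(1L, 1L), e = c(-1L, 0L), f = c(-1L, 1L))
.genName <- c("0,0" = "z", "0,1" = "ahat", "1,0" = "a", "1,1" = "n",
              "-1,0" = "e", "-1,1" = "f")

## compose two single-bit generators: `before` acts first, `after` second.
## Returns the composed generator name, or NULL when the product vanishes.
composeGen <- function(after, before) {
  if (is.null(before)) return(after)
  if (is.null(after)) return(before)
  b <- .genInfo[[before]]; a <- .genInfo[[after]]
  if (a[1] != -1L && a[1] != b[2]) return(NULL)
  .genName[[paste(b[1], a[2], sep = ",")]]
}

vkey <- function(i, lab) paste0("v:", i, ":", lab)
ekey <- function(i, j) paste0("e:", i, ":", j)

nfTerm <- function(coef = 1, rates = character(0), k = 0L,
                   fac = character(0), eranges = list()) {
  list(coef = coef, rates = rates, k = as.integer(k), fac = fac,
       eranges = eranges)
}

parseKey <- function(key) strsplit(key, ":", fixed = TRUE)[[1]]

## does an erasure range cover an edge bit key? returns the partner index
## (>0) when covered, else 0
erangeCovers <- function(er, key) {
  p <- parseKey(key)
  if (p[1] != "e") return(0L)
  i <- as.integer(p[2]); j <- as.integer(p[3])
  dir <- er$dir %||% "both"
  if (er$p == i && !(j %in% er$excl) && dir %in% c("both", "out")) return(j)
  if (er$p == j && !(i %in% er$excl) && dir %in% c("both", "in")) return(i)
  0L
}

## Build one normal-form term from an operator word.  `word` is a list in
## OPERATOR ORDER (first element acts last); each element is either
## list(type="gen", gen=, key=) or list(type="erange", p=, excl=, dir=).
## Returns NULL when the word vanishes.
nfTermFromWord <- function(word, k, coef = 1, rates = character(0)) {
  fac <- character(0)
  eranges <- list()
  applyGen <- function(gen, key) {
    ## materialize any pending range that covers this bit (ranges already
    ## in `eranges` act before the incoming factor)
    for (ri in seq_along(eranges)) {
      prt <- erangeCovers(eranges[[ri]], key)
      if (prt > 0L) {
        cur <- if (key %in% names(fac)) fac[[key]] else NULL
        fac[[key]] <<- composeGen("e", cur)
        eranges[[ri]]$excl <<- sort(unique(c(eranges[[ri]]$excl, prt)))
      }
    }
    cur <- if (key %in% names(fac)) fac[[key]] else NULL
    res <- composeGen(gen, cur)
    if (is.null(res)) return(FALSE)
    fac[[key]] <<- res
    TRUE
  }
  for (w in rev(word)) {          # rightmost factor acts first
    if (w$type == "gen") {
      if (!applyGen(w$gen, w$key)) return(NULL)
    } else if (w$type == "erange") {
      er <- list(p = as.integer(w$p),
                 excl = sort(unique(as.integer(w$excl %||% integer(0)))),
                 dir = w$dir %||% "both")
      ## the range acts after all factors processed so far: compose E onto
      ## every explicit edge bit it covers
      for (key in names(fac)) {
        prt <- erangeCovers(er, key)
        if (prt > 0L) {
          fac[[key]] <- composeGen("e", fac[[key]])
          er$excl <- sort(unique(c(er$excl, prt)))
        }
      }
      eranges[[length(eranges) + 1L]] <- er
    } else stop("unknown word element type")
  }
  nfTerm(coef = coef, rates = rates, k = k, fac = fac, eranges = eranges)
}

## ---------------------------------------------------------------------------
## Canonicalization: subpermutation invariance
## ---------------------------------------------------------------------------

renameTermIndices <- function(term, perm) {
  ## perm[i] = new name of abstract index i
  fac <- term$fac
  if (length(fac)) {
    keys <- vapply(names(fac), function(key) {
      p <- parseKey(key)
      if (p[1] == "v") vkey(perm[as.integer(p[2])], p[3])
      else ekey(perm[as.integer(p[2])], perm[as.integer(p[3])])
    }, character(1))
    names(fac) <- keys
  }
  term$fac <- fac
  term$eranges <- lapply(term$eranges, function(er) {
    er$p <- perm[er$p]
    er$excl <- sort(perm[er$excl])
    er
  })
  term
}

serializeTerm <- function(term) {
  fs <- if (length(term$fac))
    paste(sort(paste0(names(term$fac), "=", unlist(term$fac))), collapse = ";")
  else ""
  es <- if (length(term$eranges))
    paste(sort(vapply(term$eranges, function(er)
      paste0("R", er$dir %||% "both", ":", er$p, "<",
             paste(er$excl, collapse = ",")), character(1))), collapse = ";")
  else ""
  paste0("k", term$k, "|", fs, "|", es, "|",
         paste(sort(term$rates), collapse = "*"))
}

## invariant signature of each abstract index (two rounds of neighbourhood
## refinement), used to prune the permutation search
indexSignatures <- function(term) {
  k <- term$k
  if (k == 0L) return(character(0))
  base <- rep("", k)
  vOf <- vector("list", k); eOut <- vector("list", k); eIn <- vector("list", k)
  for (key in names(term$fac)) {
    p <- parseKey(key); g <- term$fac[[key]]
    if (p[1] == "v") {
      i <- as.integer(p[2])
      vOf[[i]] <- c(vOf[[i]], paste0(p[3], "=", g))
    } else {
      i <- as.integer(p[2]); j <- as.integer(p[3])
      eOut[[i]] <- c(eOut[[i]], list(c(j, g)))
      eIn[[j]] <- c(eIn[[j]], list(c(i, g)))
    }
  }
  for (i in seq_len(k)) {
    rflag <- vapply(term$eranges, function(er)
      if (er$p == i) paste0("R", er$dir %||% "both", "#", length(er$excl))
      else if (i %in% er$excl) "Rx" else "", character(1))
    base[i] <- paste0(paste(sort(vOf[[i]] %||% character(0)), collapse = ","),
                      "|", paste(sort(rflag[nzchar(rflag)]), collapse = ","))
  }
  sig <- base
  for (round in 1:2) {
    sig2 <- character(k)
    for (i in seq_len(k)) {
      nb <- c(vapply(eOut[[i]] %||% list(), function(x)
        paste0(">", x[2], ":", sig[as.integer(x[1])]), character(1)),
        vapply(eIn[[i]] %||% list(), function(x)
          paste0("<", x[2], ":", sig[as.integer(x[1])]), character(1)))
      sig2[i] <- paste0(sig[i], "{", paste(sort(nb), collapse = ";"), "}")
    }
    sig <- sig2
  }
  sig
}

## minimize the lexicographic serialization over index permutations that
## respect the signature classes
canonicalTerm <- function(term, permLimit = 50000L) {
  k <- term$k
  if (k <= 1L) {
    attr(term, "key") <- serializeTerm(term)
    return(term)
  }
  sig <- indexSignatures(term)
  classes <- split(seq_len(k), sig)
  classes <- classes[order(names(classes))]
  nperm <- prod(vapply(classes, function(cl) factorial(length(cl)), numeric(1)))
  if (nperm > permLimit)
    stop("canonicalization permutation explosion (", nperm, " candidates)")
  permsOf <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permsOf(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  ## target positions: indices of class 1 get ranks 1..n1 etc.
  classPerms <- lapply(classes, permsOf)
  combos <- expand.grid(lapply(classPerms, seq_along))
  best <- NULL; bestKey <- NULL
  for (ci in seq_len(nrow(combos))) {
    perm <- integer(k)  # perm[old] = new
    rank <- 0L
    for (g in seq_along(classes)) {
      ord <- classPerms[[g]][[combos[ci, g]]]
      perm[ord] <- rank + seq_along(ord)
      rank <- rank + length(ord)
    }
    cand <- renameTermIndices(term, perm)
    key <- serializeTerm(cand)
    if (is.null(bestKey) || key < bestKey) { best <- cand; bestKey <- key }
  }
  attr(best, "key") <- bestKey
  best
}

## canonicalize a list of terms, merging equal ones and dropping zeros
canonicalOperator <- function(terms, zap = 1e-12) {
  acc <- list()
  for (t in terms) {
    ct <- canonicalTerm(t)
    key <- attr(ct, "key")
    if (is.null(acc[[key]])) acc[[key]] <- ct
    else acc[[key]]$coef <- acc[[key]]$coef + ct$coef
  }
  keep <- Filter(function(t) abs(t$coef) > zap, acc)
  keep <- keep[order(names(keep))]
  new("NormalFormOperator", terms = unname(keep))
}

formatNFTerm <- function(t) {
  fs <- if (length(t$fac))
    paste(vapply(sort(names(t$fac)), function(key)
      paste0(t$fac[[key]], "[", key, "]"), character(1)), collapse = " ")
  else "I"
  es <- if (length(t$eranges))
    paste(vapply(t$eranges, function(er)
      paste0(" E-range(", er$p,
             if (length(er$excl)) paste0(" excl ", paste(er$excl, collapse = ","))
             else "", ")"), character(1)), collapse = "")
  else ""
  rt <- if (length(t$rates)) paste0(" * ", paste(t$rates, collapse = "*")) else ""
  sprintf("%+g%s %s%s (k=%d)", t$coef, rt, fs, es, t$k)
}

#' Number of terms of a normal-form operator
#' @param x a [NormalFormOperator-class].
#' @export
setMethod("length", "NormalFormOperator", function(x) length(x@terms))

#' Normal-order a sequence of elementary generators
#'
#' Takes a word in the generators `a`, `ahat`, `E`, `Z`, `N`, `F` on
#' concrete or abstract vertex-label/edge bits (plus erasure ranges) and
#' returns the equal operator in normal form. The first list element acts
#' last (operator order, read right to left).
#'
#' @param word list of `list(type="gen", gen=, key=)` /
#'   `list(type="erange", p=, excl=, dir=)` elements; `key` is
#'   `"v:<i>:<label>"` or `"e:<i>:<j>"`.
#' @param k number of abstract indices (pairwise distinct).
#' @param coef scalar weight.
#' @param rates character vector of symbolic rate factors.
#' @return a [NormalFormOperator-class] (possibly empty when the word
#'   vanishes, e.g. `a Z = 0`).
#' @export
normalOrder <- function(word, k, coef = 1, rates = character(0)) {
  t <- nfTermFromWord(word, k = k, coef = coef, rates = rates)
  if (is.null(t)) return(new("NormalFormOperator", terms = list()))
  canonicalOperator(list(t))
}

## convenience constructors for word elements
genFactor <- function(gen, key) list(type = "gen", gen = gen, key = key)
erangeFactor <- function(p, excl = integer(0), dir = "both")
  list(type = "erange", p = p, excl = excl, dir = dir)

## ---------------------------------------------------------------------------
## Rule operators
## ---------------------------------------------------------------------------

## encode a pure reaction rule as a (vertex-only) graph rule: reactant and
## product particle instances are paired up as relabeled (kept) vertices
## as far as possible; surplus reactants become deleted vertices and
## surplus products freshly allocated ones
pureToGraphRule <- function(rule) {
  lhsLabs <- rep(names(rule@lhs), times = rule@lhs)
  rhsLabs <- rep(names(rule@rhs), times = rule@rhs)
  nl <- length(lhsLabs); nr <- length(rhsLabs)
  k <- max(nl, nr, 1L)
  lv <- setNames(lapply(lhsLabs, function(lb) list(label = lb)),
                 as.character(seq_len(nl)))
  rv <- setNames(lapply(rhsLabs, function(lb) list(label = lb)),
                 as.character(seq_len(nr)))
  rate <- if (is.character(rule@rate)) parseExpression(rule@rate) else rule@rate
  graphRule(graphPattern(k, lv), graphPattern(k, rv),
            rate = rate, cleanupMode = "full", ruleId = rule@ruleId)
}

#' Symbolic probability-inflow operator of a rule
#'
#' Transcribes a graph rewrite rule (or a pure reaction rule, encoded as a
#' vertex-only graph rule) into a normal-form operator: RHS edge/label
#' creations, LHS edge/label annihilations, `Z` factors for prohibited
#' edges, and -- depending on `form` -- erasure ranges implementing vertex
#' deallocation cleanup (`"eq13"`: full cleanup for every LHS-only vertex;
#' `"eq15"`: no cleanup post-factors; `"eq16"`: custom cleanup sets from the
#' rule's cleanup spec).
#'
#' @param rule a [GraphRule-class] with concrete labels and a numeric or
#'   single-symbol rate, or a [PureRule-class].
#' @param form `"eq13"`, `"eq15"`, or `"eq16"`.
#' @param nullVertices extra shared vertex numbers required to carry the
#'   free-vertex (null) label on both sides; used by [diagonalPart()] so
#'   that the outflow operator of an allocating rule counts free indices.
#' @return a [NormalFormOperator-class].
#' @export
opFromRule <- function(rule, form = c("eq13", "eq15", "eq16"),
                       nullVertices = integer(0)) {
  form <- match.arg(form)
  if (is(rule, "PureRule")) rule <- pureToGraphRule(rule)
  stopifnot(is(rule, "GraphRule"))
  lhsI <- rule@lhs@included; rhsI <- rule@rhs@included
  allV <- sort(union(union(lhsI, rhsI), nullVertices))
  k <- length(allV)
  aid <- setNames(seq_len(k), as.character(allV))  # shared number -> index
  lab <- function(side, v) {
    lb <- side@labels[[base::match(v, side@included)]]
    if (!is.character(lb))
      stop("symbolic operator construction requires concrete labels")
    lb
  }
  coef <- 1; rates <- character(0)
  rx <- rule@rateExpr
  if (is.numeric(rx)) coef <- rx
  else if (is.symbol(rx)) rates <- as.character(rx)
  else stop("symbolic operator construction requires a numeric or ",
            "single-symbol rate")
  word <- list()
  push <- function(x) word[[length(word) + 1L]] <<- x
  lhsOnly <- setdiff(lhsI, rhsI)
  if (form == "eq13") {
    for (v in lhsOnly) push(erangeFactor(aid[[as.character(v)]]))
  } else if (form == "eq16") {
    cs <- rule@cleanupSpec
    if (!length(cs)) cs <- list(B = lhsOnly, C = lhsOnly)
    for (v in (cs$B %||% integer(0)))
      push(erangeFactor(aid[[as.character(v)]],
                        excl = vapply((cs$Bbar %||% list())[[as.character(v)]] %||%
                                        integer(0),
                                      function(q) aid[[as.character(q)]],
                                      integer(1)),
                        dir = "out"))
    for (v in (cs$C %||% integer(0)))
      push(erangeFactor(aid[[as.character(v)]],
                        excl = vapply((cs$Cbar %||% list())[[as.character(v)]] %||%
                                        integer(0),
                                      function(q) aid[[as.character(q)]],
                                      integer(1)),
                        dir = "in"))
  }
  ## RHS edge creations, then RHS prohibited-edge Z factors
  for (p in rhsI) for (q in rhsI)
    if (p != q && rule@rhs@adj[p, q] == 1L)
      push(genFactor("ahat", ekey(aid[[as.character(p)]], aid[[as.character(q)]])))
  for (p in rhsI) for (q in rhsI)
    if (p != q && rule@rhs@forbid[p, q] == 1L)
      push(genFactor("z", ekey(aid[[as.character(p)]], aid[[as.character(q)]])))
  ## RHS vertex-label creations; deleted vertices return to the free
  ## (null-labeled) state, so allocation bookkeeping is part of the algebra
  for (v in rhsI)
    push(genFactor("ahat", vkey(aid[[as.character(v)]], lab(rule@rhs, v))))
  for (v in setdiff(lhsI, rhsI))
    push(genFactor("ahat", vkey(aid[[as.character(v)]], .nullLabel)))
  for (v in nullVertices)
    push(genFactor("ahat", vkey(aid[[as.character(v)]], .nullLabel)))
  ## LHS edge annihilations, then LHS prohibited-edge Z factors
  for (p in lhsI) for (q in lhsI)
    if (p != q && rule@lhs@adj[p, q] == 1L)
      push(genFactor("a", ekey(aid[[as.character(p)]], aid[[as.character(q)]])))
  for (p in lhsI) for (q in lhsI)
    if (p != q && rule@lhs@forbid[p, q] == 1L)
      push(genFactor("z", ekey(aid[[as.character(p)]], aid[[as.character(q)]])))
  ## LHS vertex-label annihilations; created vertices consume a free
  ## (null-labeled) index
  for (v in lhsI)
    push(genFactor("a", vkey(aid[[as.character(v)]], lab(rule@lhs, v))))
  for (v in setdiff(rhsI, lhsI))
    push(genFactor("a", vkey(aid[[as.character(v)]], .nullLabel)))
  for (v in nullVertices)
    push(genFactor("a", vkey(aid[[as.character(v)]], .nullLabel)))
  normalOrder(word, k = k, coef = coef, rates = rates)
}

#' Diagonal (probability-outflow) operator of a rule
#'
#' `D_r` equals the inflow operator of the rule whose LHS and RHS are both
#' the LHS of `r`; its realization is diagonal and equals
#' `diag(1 . realize(What_r))`.
#'
#' @param rule a [GraphRule-class] or [PureRule-class].
#' @param form as in [opFromRule()].
#' @return a [NormalFormOperator-class].
#' @export
diagonalPart <- function(rule, form = "eq13") {
  if (is(rule, "PureRule")) rule <- pureToGraphRule(rule)
  dr <- graphRule(rule@lhs, rule@lhs, rate = rule@rateExpr,
                  cleanupMode = rule@cleanupMode,
                  cleanupSpec = rule@cleanupSpec,
                  directed = rule@directed,
                  ruleId = paste0(rule@ruleId, "_diag"))
  ## vertices allocated by r must be free for r to fire; they appear in
  ## the outflow operator as null-label presence checks
  opFromRule(dr, form = form,
             nullVertices = setdiff(rule@rhs@included, rule@lhs@included))
}

## ---------------------------------------------------------------------------
## Products and commutators
## ---------------------------------------------------------------------------

## all injective partial matchings of 1..k2 into 1..k1, as integer vectors
## m (length k2) with m[v] = matched index in 1..k1 or 0
injectiveMatchings <- function(k1, k2) {
  out <- list()
  recurse <- function(v, m) {
    if (v > k2) { out[[length(out) + 1L]] <<- m; return(invisible()) }
    recurse(v + 1L, c(m, 0L))
    for (u in setdiff(seq_len(k1), m)) recurse(v + 1L, c(m, u))
  }
  recurse(1L, integer(0))
  out
}

## effective generator of a term on a bit: explicit factor, else "e" when an
## erasure range covers the bit, else NULL (identity)
effGen <- function(term, key) {
  if (key %in% names(term$fac)) return(term$fac[[key]])
  for (er in term$eranges) if (erangeCovers(er, key) > 0L) return("e")
  NULL
}

## multiply two normal-form terms under a given index matching; t1 acts
## AFTER t2.  Returns the merged term or NULL when the product vanishes.
multiplyTerms <- function(t1, t2, matching) {
  k1 <- t1$k; k2 <- t2$k
  nNew <- sum(matching == 0L)
  map2 <- integer(k2); nxt <- k1
  for (v in seq_len(k2)) {
    if (matching[v] > 0L) map2[v] <- matching[v]
    else { nxt <- nxt + 1L; map2[v] <- nxt }
  }
  t2r <- renameTermIndices(t2, map2)
  keys <- union(names(t1$fac), names(t2r$fac))
  fac <- character(0)
  for (key in keys) {
    g1 <- effGen(t1, key)   # acts second
    g2 <- effGen(t2r, key)  # acts first
    g <- composeGen(g1, g2)
    if (is.null(g)) {
      if (is.null(g1) && is.null(g2)) next
      return(NULL)
    }
    fac[[key]] <- g
  }
  eranges <- c(t1$eranges, t2r$eranges)
  ## maintain the invariant: every explicit bit with an endpoint of a range
  ## is excluded from that range (its E action is already in the factor)
  if (length(eranges)) {
    for (ri in seq_along(eranges)) {
      er <- eranges[[ri]]
      for (key in names(fac)) {
        prt <- erangeCovers(er, key)
        if (prt > 0L) er$excl <- sort(unique(c(er$excl, prt)))
      }
      eranges[[ri]] <- er
    }
  }
  nfTerm(coef = t1$coef * t2$coef, rates = c(t1$rates, t2$rates),
         k = k1 + nNew, fac = fac, eranges = eranges)
}

#' Product of two normal-form operators
#'
#' Expands the product of two sums over pairwise-distinct abstract index
#' tuples by case-splitting on every pattern of index identification
#' between the two operands, composes the per-bit generators (with erasure
#' ranges materialized on the bits they meet), and canonicalizes the
#' result. `W2` acts first.
#'
#' @param W1,W2 [NormalFormOperator-class] objects.
#' @param maxTerms guard on the intermediate term count.
#' @return a [NormalFormOperator-class] in normal form.
#' @export
opProduct <- function(W1, W2, maxTerms = 20000L) {
  out <- list()
  for (t1 in W1@terms) for (t2 in W2@terms) {
    for (m in injectiveMatchings(t1$k, t2$k)) {
      prod <- multiplyTerms(t1, t2, m)
      if (!is.null(prod)) {
        out[[length(out) + 1L]] <- prod
        if (length(out) > maxTerms)
          stop("operator product term-count explosion (> ", maxTerms, ")")
      }
    }
  }
  canonicalOperator(out)
}

#' Commutator of two normal-form operators
#'
#' `[W1, W2] = W1 W2 - W2 W1`, canonicalized so that cancelling summands
#' are removed (the commutator of an operator with itself is the empty
#' sum).
#'
#' @inheritParams opProduct
#' @return a [NormalFormOperator-class].
#' @export
opCommutator <- function(W1, W2, maxTerms = 20000L) {
  p12 <- opProduct(W1, W2, maxTerms)
  p21 <- opProduct(W2, W1, maxTerms)
  neg <- lapply(p21@terms, function(t) { t$coef <- -t$coef; t })
  canonicalOperator(c(p12@terms, neg))
}

#' Sum and scalar multiple of normal-form operators
#' @param W1,W2 operators; @param s scalar.
#' @export
opSum <- function(W1, W2) canonicalOperator(c(W1@terms, W2@terms))

#' @rdname opSum
#' @param W an operator.
#' @export
opScale <- function(W, s) {
  canonicalOperator(lapply(W@terms, function(t) { t$coef <- s * t$coef; t }))
}

#' The identity operator
#' @export
opIdentity <- function() canonicalOperator(list(nfTerm(coef = 1, k = 0L)))

## ---------------------------------------------------------------------------
## Realization on a finite pool of binary state variables
## ---------------------------------------------------------------------------

## the free-vertex label: every vertex of a physical (one-hot) state
## carries exactly one label bit, with "." marking an unallocated index
.nullLabel <- "."

poolBitLayout <- function(nVertices, labels) {
  labels <- union(.nullLabel, labels)
  L <- length(labels)
  pairs <- expand.grid(i = seq_len(nVertices), j = seq_len(nVertices))
  pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  ebit <- matrix(NA_integer_, nVertices, nVertices)
  for (r in seq_len(nrow(pairs)))
    ebit[pairs$i[r], pairs$j[r]] <- nVertices * L + r - 1L
  list(L = L, labels = labels, nv = nVertices,
       vbit = function(i, lab) (i - 1L) * L + base::match(lab, labels) - 1L,
       ebit = ebit,
       nBits = nVertices * L + nrow(pairs))
}

#' Realize a normal-form operator as an explicit matrix
#'
#' Instantiates abstract index sums over all distinct concrete vertex
#' tuples of a finite pool; each single-bit generator acts as a conditional
#' bit assignment on the full binary state space of `nVertices * L`
#' vertex-label bits and `nVertices * (nVertices - 1)` directed edge bits.
#'
#' @param op a [NormalFormOperator-class].
#' @param nVertices pool size (small; the state space is `2^nBits`).
#' @param labels label alphabet.
#' @param rates named numeric vector giving values to symbolic rates.
#' @param maxBits guard on the bit count.
#' @return a sparse matrix of dimension `2^nBits`; basis states are bit
#'   vectors with bit b of the integer state index.
#' @export
realizeOperator <- function(op, nVertices, labels, rates = numeric(0),
                            maxBits = 16L) {
  lay <- poolBitLayout(nVertices, labels)
  B <- lay$nBits
  if (B > maxBits)
    stop("state space too large: ", B, " bits exceed guard ", maxBits)
  NS <- 2^B
  s <- 0:(NS - 1L)
  ii <- list(); jj <- list(); xx <- list()
  for (t in op@terms) {
    coefv <- t$coef
    for (r in t$rates) {
      if (!r %in% names(rates))
        stop("no numeric value supplied for rate symbol ", r)
      coefv <- coefv * rates[[r]]
    }
    if (t$k > nVertices) next  # no injective assignment exists
    assigns <- orderedTuples(seq_len(nVertices), t$k)
    for (asg in assigns) {
      ## concrete generator per bit
      gens <- character(0)
      ok <- TRUE
      for (key in names(t$fac)) {
        p <- parseKey(key)
        bit <- if (p[1] == "v") {
          lb <- p[3]
          if (!lb %in% lay$labels) { ok <- FALSE; break }
          lay$vbit(asg[as.integer(p[2])], lb)
        } else lay$ebit[asg[as.integer(p[2])], asg[as.integer(p[3])]]
        gens[[as.character(bit)]] <- t$fac[[key]]
      }
      if (!ok) next
      for (er in t$eranges) {
        pc <- asg[er$p]
        others <- setdiff(seq_len(lay$nv), c(pc, asg[er$excl]))
        dir <- er$dir %||% "both"
        for (u in others) {
          bits <- integer(0)
          if (dir %in% c("both", "out")) bits <- c(bits, lay$ebit[pc, u])
          if (dir %in% c("both", "in")) bits <- c(bits, lay$ebit[u, pc])
          for (bit in bits) {
            kb <- as.character(bit)
            gens[[kb]] <- if (!kb %in% names(gens)) "e"
                          else composeGen("e", gens[[kb]])
          }
        }
      }
      ## masks
      req1 <- 0; req0 <- 0; touched <- 0; ones <- 0
      for (kb in names(gens)) {
        bit <- as.integer(kb); g <- .genInfo[[gens[[kb]]]]
        w <- 2^bit
        if (g[1] == 1L) req1 <- req1 + w
        if (g[1] == 0L) req0 <- req0 + w
        touched <- touched + w
        if (g[2] == 1L) ones <- ones + w
      }
      cond <- bitwAnd(s, as.integer(req1)) == as.integer(req1) &
        bitwAnd(s, as.integer(req0)) == 0L
      src <- s[cond]
      if (!length(src)) next
      tgt <- bitwAnd(src, bitwNot(as.integer(touched))) + as.integer(ones)
      ii[[length(ii) + 1L]] <- tgt + 1L
      jj[[length(jj) + 1L]] <- src + 1L
      xx[[length(xx) + 1L]] <- rep(coefv, length(src))
    }
  }
  Matrix::sparseMatrix(i = unlist(ii) %||% integer(0),
                       j = unlist(jj) %||% integer(0),
                       x = unlist(xx) %||% numeric(0),
                       dims = c(NS, NS))
}

## integer bit-state index (0-based) of a pool-graph configuration
poolGraphBitIndex <- function(g, nVertices, labels) {
  lay <- poolBitLayout(nVertices, labels)
  s <- 0
  for (i in seq_len(nVertices)) {
    s <- s + 2^lay$vbit(i, if (g@active[i]) g@label[i] else .nullLabel)
  }
  e <- which(g@adj[seq_len(nVertices), seq_len(nVertices), drop = FALSE] == 1L,
             arr.ind = TRUE)
  for (r in seq_len(nrow(e))) s <- s + 2^lay$ebit[e[r, 1], e[r, 2]]
  as.integer(s)
}
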