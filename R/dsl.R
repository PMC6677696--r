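## The textual rule DSL (.dgg files).
##
## One rule per statement:
##   r1: A + 2 B -> C with k                        (pure mass action)
##   div: stemcell[x, V] -> TAcell[x + dx, V/2], stemcell[x - dx, V/2]
##        with rho(V) * normal(dx; c * V^(1/3))     (parameterized; the
##        rate is factored into an LHS propensity times conditional
##        samplers, written sampler(var; params...; dim))
##   relax: point[x] -> point[x] with ode d(x)/dt = -x
##   param k = 2.5       species A B C              (declarations)
## and a block syntax for graph rules listing numbered vertices, labels
## and edge lists:
##   graph grow {
##     lhs { 1 grow_end[x = x, u = u] }
##     rhs { 1 internal; 2 grow_end[x = x + L * u, u = u]; edges 1-2 }
##     rate kgrow
##     cleanup full
##   }
## Edges: `1-2` undirected, `1->2` directed, `1+>2` undirected with a
## slice level-raising mark (slice rules declare `slice graded`).

.samplerDists <- c("normal", "uniform", "unitvec", "delta")

## split `text` on `sep` at bracket/paren depth 0
splitTop <- function(text, sep) {
  out <- character(0); depth <- 0L; cur <- ""
  chars <- strsplit(text, "")[[1]]
  for (ch in chars) {
    if (ch %in% c("(", "[")) depth <- depth + 1L
    if (ch %in% c(")", "]")) depth <- depth - 1L
    if (ch == sep && depth == 0L) { out <- c(out, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  c(out, cur)
}

trimAll <- function(x) trimws(x)

dslError <- function(line, msg) {
  stop("DSL syntax error at line ", line, ": ", msg, call. = FALSE)
}

## parse one term `type[arg1, ...]` or bare `type`; LHS slots become
## variables/constants/wildcards, RHS slots may be expressions
parseTerm <- function(text, line) {
  m <- regmatches(text, regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\[(.*)\\])?$",
                                text))[[1]]
  if (!length(m)) dslError(line, paste0("malformed term ", sQuote(text)))
  type <- m[2]
  args <- list()
  if (nzchar(m[3])) {
    for (a in trimAll(splitTop(m[4], ","))) {
      if (!nzchar(a)) dslError(line, "empty term argument")
      args <- c(args, list(if (a == "_") quote(.) else parseExpression(a)))
    }
  }
  new("TermPattern", type = type, args = args)
}

## parse a rule side: comma-separated terms, or `0` for the empty side;
## returns list(terms=..., pure=named stoich or NULL)
parseSide <- function(text, line) {
  text <- trimAll(text)
  if (text == "0" || text == "")
    return(list(terms = list(), pure = setNames(numeric(0), character(0))))
  if (grepl("\\[", text)) {
    parts <- trimAll(splitTop(text, ","))
    if (any(!nzchar(parts))) dslError(line, "empty term in term list")
    return(list(terms = lapply(parts, parseTerm, line = line), pure = NULL))
  }
  ## pure side: `A + 2 B`
  if (grepl("^\\+|\\+\\s*$", text))
    dslError(line, paste0("empty summand in ", sQuote(text)))
  parts <- trimAll(strsplit(text, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(parts)))
    dslError(line, paste0("empty summand in ", sQuote(text)))
  st <- setNames(numeric(0), character(0))
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$",
                               p))[[1]]
    if (!length(m)) dslError(line, paste0("malformed species term ",
                                          sQuote(p)))
    cnt <- if (nzchar(m[2])) as.numeric(m[2]) else 1
    cur <- if (m[3] %in% names(st)) st[[m[3]]] else 0
    st[m[3]] <- cur + cnt
  }
  list(terms = NULL, pure = st)
}

## parse a `with` clause of a non-graph rule: product of rate factors and
## sampler factors `dist(var; arg; ...)`
parseRateClause <- function(text, line) {
  factors <- trimAll(splitTop(text, "*"))
  rateFacs <- character(0); samplers <- list()
  for (f in factors) {
    m <- regmatches(f, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$", f))[[1]]
    isSampler <- length(m) > 0 && m[2] %in% .samplerDists &&
      grepl(";", m[3], fixed = TRUE) || (length(m) > 0 && m[2] == "unitvec")
    if (isSampler) {
      bits <- trimAll(splitTop(m[3], ";"))
      var <- bits[1]
      dim <- 1L
      rest <- bits[-1]
      if (length(rest) && grepl("^[0-9]+$", rest[length(rest)]) &&
          m[2] != "delta") {
        dim <- as.integer(rest[length(rest)])
        rest <- rest[-length(rest)]
      }
      samplers[[length(samplers) + 1L]] <-
        do.call(sampler, c(list(var = var, dist = m[2]), as.list(rest),
                           list(dim = dim)))
    } else rateFacs <- c(rateFacs, f)
  }
  rate <- if (!length(rateFacs)) quote(1)
          else parseExpression(paste(rateFacs, collapse = " * "))
  list(rate = rate, samplers = samplers)
}

parseOdeClause <- function(text, terms, line) {
  if (grepl("dB", text))
    dslError(line, "unsupported: stochastic (dB) noise terms are not part of ODE rules")
  eqs <- trimAll(splitTop(text, ","))
  drifts <- list()
  for (eq in eqs) {
    m <- regmatches(eq, regexec(
      "^d\\(([A-Za-z_][A-Za-z0-9_]*)\\)\\s*/\\s*dt\\s*=\\s*(.+)$", eq))[[1]]
    if (!length(m)) dslError(line, paste0("malformed ODE ", sQuote(eq)))
    var <- m[2]; expr <- parseExpression(m[3])
    found <- FALSE
    for (ti in seq_along(terms)) for (si in seq_along(terms[[ti]]@args)) {
      a <- terms[[ti]]@args[[si]]
      if (isVar(a) && as.character(a) == var) {
        drifts[[length(drifts) + 1L]] <-
          list(term = ti, slot = si, expr = expr)
        found <- TRUE
      }
    }
    if (!found) dslError(line, paste0("ODE variable ", var,
                                      " is not a term parameter"))
  }
  drifts
}

## parse the body of a graph-rule side block:
## `1 label[p = expr]; 2 ?L; edges 1-2, 1->3, 1+>4; forbid 2-3`
parseGraphSide <- function(text, k, directed, line) {
  stmts <- trimAll(splitTop(gsub("\n", ";", text), ";"))
  verts <- list(); edges <- list(); forbid <- list(); deltas <- list()
  for (s in stmts) {
    if (!nzchar(s)) next
    if (grepl("^edges\\b", s) || grepl("^forbid\\b", s)) {
      isF <- grepl("^forbid\\b", s)
      lst <- trimAll(splitTop(sub("^(edges|forbid)\\s*", "", s), ","))
      for (e in lst) {
        m <- regmatches(e, regexec("^([0-9]+)\\s*(->|\\+>|-)\\s*([0-9]+)$",
                                   e))[[1]]
        if (!length(m)) dslError(line, paste0("malformed edge ", sQuote(e)))
        pr <- c(as.integer(m[2]), as.integer(m[4]))
        if (isF) forbid <- c(forbid, list(pr))
        else {
          edges <- c(edges, list(pr))
          if (m[3] == "+>") deltas <- c(deltas, list(c(pr, 1)))
          else deltas <- c(deltas, list(c(pr, 0)))
        }
      }
    } else {
      m <- regmatches(s, regexec(
        "^([0-9]+)\\s+(\\??[A-Za-z_][A-Za-z0-9_]*)(\\[(.*)\\])?$", s))[[1]]
      if (!length(m)) dslError(line, paste0("malformed vertex ", sQuote(s)))
      lab <- if (startsWith(m[3], "?")) as.symbol(substring(m[3], 2)) else m[3]
      pars <- list()
      if (nzchar(m[4])) {
        for (p in trimAll(splitTop(m[5], ","))) {
          pm <- regmatches(p, regexec(
            "^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", p))[[1]]
          if (!length(pm)) dslError(line, paste0("malformed vertex parameter ",
                                                 sQuote(p)))
          pars[[pm[2]]] <- parseExpression(pm[3])
        }
      }
      verts[[m[2]]] <- list(label = lab, params = pars)
    }
  }
  useDeltas <- any(vapply(deltas, function(d) d[3] != 0, logical(1)))
  graphPattern(k, verts, edges = if (length(edges)) edges else NULL,
               forbid = if (length(forbid)) forbid else NULL,
               directed = directed,
               edgeDelta = if (useDeltas) deltas else NULL)
}

parseGraphBlock <- function(id, body, line) {
  grab <- function(name) {
    m <- regmatches(body, regexec(paste0("\\b", name,
                                         "\\s*\\{([^{}]*)\\}"), body))[[1]]
    if (length(m)) m[2] else NULL
  }
  grabLine <- function(name) {
    m <- regmatches(body, regexec(paste0("\\b", name, "\\s+([^\n]+)"),
                                  body))[[1]]
    if (length(m)) trimAll(m[2]) else NULL
  }
  lhsT <- grab("lhs"); rhsT <- grab("rhs")
  if (is.null(lhsT) || is.null(rhsT))
    dslError(line, "graph rule must declare lhs { } and rhs { }")
  directed <- identical(grabLine("directed"), "true")
  cleanup <- grabLine("cleanup") %||% "full"
  slice <- grabLine("slice") %||% ""
  rateT <- grabLine("rate") %||% "1"
  rc <- parseRateClause(rateT, line)
  scanNums <- function(side) {
    nums <- integer(0)
    for (s in trimAll(splitTop(gsub("\n", ";", side), ";"))) {
      if (!nzchar(s)) next
      if (grepl("^(edges|forbid)\\b", s)) {
        ee <- trimAll(splitTop(sub("^(edges|forbid)\\s*", "", s), ","))
        for (e in ee)
          nums <- c(nums, as.integer(unlist(regmatches(
            e, gregexpr("[0-9]+", e)))))
      } else {
        m <- regmatches(s, regexec("^([0-9]+)\\s", s))[[1]]
        if (length(m)) nums <- c(nums, as.integer(m[2]))
      }
    }
    nums
  }
  k <- max(c(scanNums(lhsT), scanNums(rhsT), 1L))
  graphRule(parseGraphSide(lhsT, k, directed, line),
            parseGraphSide(rhsT, k, directed, line),
            rate = rc$rate, samplers = rc$samplers,
            cleanupMode = cleanup, sliceKind = slice,
            directed = directed, ruleId = id)
}

#' Parse a ruleset from DSL text
#'
#' @param text character scalar (or vector of lines) of DSL source.
#' @return a [Ruleset-class]. Syntax errors report the offending line;
#'   if a `species`/`labels` declaration is present, referencing an
#'   undeclared symbol is an error.
#' @export
parseRuleset <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- sub("#.*$", "", lines)
  rules <- list(); params <- list(); symbols <- character(0)
  i <- 1L; autoId <- 0L
  while (i <= length(lines)) {
    ln <- trimAll(lines[i])
    if (!nzchar(ln)) { i <- i + 1L; next }
    if (grepl("^graph\\s", ln)) {
      m <- regmatches(ln, regexec("^graph\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*\\{",
                                  ln))[[1]]
      if (!length(m)) dslError(i, "malformed graph rule header")
      depth <- nchar(gsub("[^{]", "", ln)) - nchar(gsub("[^}]", "", ln))
      body <- sub("^graph\\s+[A-Za-z_][A-Za-z0-9_]*\\s*\\{", "", ln)
      start <- i
      while (depth > 0L) {
        i <- i + 1L
        if (i > length(lines)) dslError(start, "unterminated graph block")
        body <- paste(body, lines[i], sep = "\n")
        depth <- depth + nchar(gsub("[^{]", "", lines[i])) -
          nchar(gsub("[^}]", "", lines[i]))
      }
      body <- sub("\\}\\s*$", "", body)
      rules[[length(rules) + 1L]] <- parseGraphBlock(m[2], body, start)
      i <- i + 1L; next
    }
    if (grepl("^param\\s", ln)) {
      m <- regmatches(ln, regexec(
        "^param\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))[[1]]
      if (!length(m)) dslError(i, "malformed param declaration")
      params[[m[2]]] <- evalExpression(parseExpression(m[3]), params)
      i <- i + 1L; next
    }
    if (grepl("^(species|labels)\\s", ln)) {
      symbols <- c(symbols,
                   strsplit(trimAll(sub("^(species|labels)\\s+", "", ln)),
                            "\\s+")[[1]])
      i <- i + 1L; next
    }
    ## rule statement: `[id:] LHS -> RHS with CLAUSE`
    m <- regmatches(ln, regexec(
      "^(([A-Za-z_][A-Za-z0-9_]*)\\s*:)?\\s*(.*?)->(.*?)(\\swith\\s(.*))?$",
      ln))[[1]]
    if (!length(m) || !grepl("->", ln))
      dslError(i, paste0("unrecognized statement ", sQuote(ln)))
    autoId <- autoId + 1L
    id <- if (nzchar(m[3])) m[3] else paste0("rule", autoId)
    lhs <- parseSide(m[4], i); rhs <- parseSide(m[5], i)
    clause <- trimAll(m[7])
    if (grepl("^ode\\b", clause)) {
      if (is.null(lhs$terms)) dslError(i, "ODE rules need term patterns")
      drifts <- parseOdeClause(sub("^ode\\s*", "", clause), lhs$terms, i)
      rules[[length(rules) + 1L]] <-
        odeRule(lhs$terms, drifts, ruleId = id)
    } else if (!is.null(lhs$pure) && !is.null(rhs$pure)) {
      rate <- if (!nzchar(clause)) 1
              else if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", clause)) clause
              else evalExpression(parseExpression(clause), params)
      rules[[length(rules) + 1L]] <-
        pureRule(lhs$pure, rhs$pure, rate = rate, ruleId = id)
    } else {
      toTerms <- function(side) {
        if (!is.null(side$terms)) return(side$terms)
        unlist(lapply(names(side$pure), function(sp)
          replicate(side$pure[[sp]], termPattern(sp), simplify = FALSE)),
          recursive = FALSE) %||% list()
      }
      rc <- parseRateClause(clause, i)
      rules[[length(rules) + 1L]] <-
        paramRule(toTerms(lhs), toTerms(rhs), rate = rc$rate,
                  samplers = rc$samplers, ruleId = id)
    }
    i <- i + 1L
  }
  rs <- ruleset(rules, params = params, symbols = unique(symbols))
  if (length(rs@symbols)) {
    used <- rulesetSymbols(new("Ruleset", rules = rs@rules, params = list(),
                               symbols = character(0)))
    bad <- setdiff(used, rs@symbols)
    if (length(bad))
      stop("undeclared symbol(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  rs
}

#' Read a ruleset from a .dgg file
#' @param path file path.
#' @export
readRuleset <- function(path) parseRuleset(readLines(path, warn = FALSE))

## ---------------------------------------------------------------------------
## Unparser
## ---------------------------------------------------------------------------

formatTermPattern <- function(tp) {
  if (!length(tp@args)) return(tp@type)
  args <- vapply(tp@args, function(a) {
    if (isWildcard(a)) "_" else formatExpression(a)
  }, character(1))
  paste0(tp@type, "[", paste(args, collapse = ", "), "]")
}

formatSampler <- function(s) {
  args <- vapply(s$args, formatExpression, character(1))
  bits <- c(s$var, args)
  if (s$dim != 1L && s$dist != "delta") bits <- c(bits, s$dim)
  paste0(s$dist, "(", paste(bits, collapse = "; "), ")")
}

formatPureSide <- function(st) {
  if (!length(st)) return("0")
  paste(ifelse(st == 1, names(st), paste(st, names(st))), collapse = " + ")
}

formatGraphSide <- function(pat, directed) {
  bits <- character(0)
  for (pos in seq_along(pat@included)) {
    v <- pat@included[pos]
    lb <- pat@labels[[pos]]
    lbT <- if (is.character(lb)) lb else paste0("?", as.character(lb))
    pp <- pat@params[[pos]]
    pT <- if (length(pp))
      paste0("[", paste(vapply(names(pp), function(nm)
        paste0(nm, " = ", formatExpression(pp[[nm]])), character(1)),
        collapse = ", "), "]")
    else ""
    bits <- c(bits, paste0(v, " ", lbT, pT))
  }
  edgeTxt <- function(mat, marks = NULL, sym) {
    out <- character(0)
    for (a in seq_len(nrow(mat))) for (b in seq_len(ncol(mat))) {
      if (mat[a, b] != 1L) next
      if (!directed && a > b) next
      op <- sym
      if (!is.null(marks) && !is.na(marks[a, b]) && marks[a, b] == 1) op <- "+>"
      out <- c(out, paste0(a, op, b))
    }
    out
  }
  et <- edgeTxt(pat@adj, pat@edgeDelta, if (directed) "->" else "-")
  if (length(et)) bits <- c(bits, paste("edges", paste(et, collapse = ", ")))
  ft <- edgeTxt(pat@forbid, NULL, if (directed) "->" else "-")
  if (length(ft)) bits <- c(bits, paste("forbid", paste(ft, collapse = ", ")))
  paste(bits, collapse = "; ")
}

#' Serialize a ruleset back to DSL text
#'
#' `parseRuleset(formatRuleset(rs))` reproduces `rs` up to whitespace.
#'
#' @param rs a [Ruleset-class].
#' @return character scalar of DSL source.
#' @export
formatRuleset <- function(rs) {
  out <- character(0)
  if (length(rs@symbols))
    out <- c(out, paste("species", paste(rs@symbols, collapse = " ")))
  for (nm in names(rs@params))
    out <- c(out, paste0("param ", nm, " = ",
                         format(rs@params[[nm]], digits = 17)))
  for (r in rs@rules) {
    if (is(r, "PureRule")) {
      rate <- if (is.character(r@rate)) r@rate else
        format(r@rate, digits = 17)
      out <- c(out, sprintf("%s: %s -> %s with %s", r@ruleId,
                            formatPureSide(r@lhs), formatPureSide(r@rhs),
                            rate))
    } else if (is(r, "ParamRule")) {
      facs <- formatExpression(r@rateExpr)
      for (s in r@samplers) facs <- paste(facs, "*", formatSampler(s))
      out <- c(out, sprintf("%s: %s -> %s with %s", r@ruleId,
                            paste(vapply(r@lhs, formatTermPattern,
                                         character(1)), collapse = ", "),
                            paste(vapply(r@rhs, formatTermPattern,
                                         character(1)), collapse = ", "),
                            facs))
    } else if (is(r, "ODERule")) {
      odes <- vapply(r@drifts, function(d) {
        var <- r@terms[[d$term]]@args[[d$slot]]
        paste0("d(", as.character(var), ")/dt = ", formatExpression(d$expr))
      }, character(1))
      tt <- paste(vapply(r@terms, formatTermPattern, character(1)),
                  collapse = ", ")
      out <- c(out, sprintf("%s: %s -> %s with ode %s", r@ruleId, tt, tt,
                            paste(odes, collapse = ", ")))
    } else if (is(r, "GraphRule")) {
      rate <- formatExpression(r@rateExpr)
      for (s in r@samplers) rate <- paste(rate, "*", formatSampler(s))
      blk <- c(paste0("graph ", r@ruleId, " {"),
               paste0("  lhs { ", formatGraphSide(r@lhs, r@directed), " }"),
               paste0("  rhs { ", formatGraphSide(r@rhs, r@directed), " }"),
               paste0("  rate ", rate),
               paste0("  cleanup ", r@cleanupMode),
               if (r@directed) "  directed true",
               if (nzchar(r@sliceKind)) paste0("  slice ", r@sliceKind),
               "}")
      out <- c(out, blk)
    }
  }
  paste(out, collapse = "\n")
}

#' Write a ruleset to a .dgg file
#' @param rs a [Ruleset-class]; @param path output path.
#' @export
writeRuleset <- function(rs, path) {
  writeLines(formatRuleset(rs), path)
  invisible(path)
}
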