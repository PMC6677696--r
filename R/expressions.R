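## Rate and parameter expressions are stored as base-R `language` objects
## (abstract syntax trees as produced by the R parser).  Evaluation is done
## in a closed environment containing only arithmetic, comparison and a small
## set of named mathematical functions, so a rate expression cannot reach
## into the calling frame.

.exprFunEnv <- local({
  e <- new.env(parent = emptyenv())
  funs <- c("+", "-", "*", "/", "^", "(", "sqrt", "exp", "log", "abs",
            "sin", "cos", "tan", "acos", "asin", "atan", "atan2",
            "min", "max", "pmin", "pmax", "floor", "ceiling", "round",
            "==", "!=", "<", "<=", ">", ">=", "&", "|", "!",
            "ifelse", "sum", "prod", "length", "c", "[")
  for (f in funs) assign(f, get(f, baseenv()), envir = e)
  ## indicator of a logical condition (the Theta gate of slice-rule lowering)
  assign("ind", function(x) as.numeric(x), envir = e)
  ## Euclidean norm and dot product, used by geometric rate expressions
  assign("norm2", function(x) sqrt(sum(x * x)), envir = e)
  assign("dot", function(x, y) sum(x * y), envir = e)
  assign("pi", pi, envir = e)
  e
})

#' Parse a textual expression into an AST
#'
#' Thin wrapper around the base-R parser; the resulting `language` object is
#' the expression AST used throughout rate and parameter expressions.
#'
#' @param text a single character string.
#' @return a `language` object (or atomic constant / symbol).
#' @export
parseExpression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  out <- tryCatch(str2lang(text),
                  error = function(e) stop("expression syntax error in ",
                                           sQuote(text), ": ",
                                           conditionMessage(e), call. = FALSE))
  out
}

#' Variables appearing in an expression AST
#' @param ast a `language` object, symbol or constant.
#' @return character vector of variable names (excluding known functions).
#' @export
expressionVars <- function(ast) {
  setdiff(all.vars(ast), "pi")
}

#' Evaluate an expression AST under variable bindings
#'
#' Every variable in the expression must be bound; evaluation takes place in
#' an environment exposing only arithmetic and a fixed set of mathematical
#' functions (plus `ind()`, the 0/1 indicator used for rate gating).
#'
#' @param ast expression AST (`language`, symbol, or constant).
#' @param bindings named list of values.
#' @return the value of the expression.
#' @export
evalExpression <- function(ast, bindings = list()) {
  if (is.numeric(ast)) return(ast)
  vars <- expressionVars(ast)
  missing <- setdiff(vars, names(bindings))
  if (length(missing))
    stop("unbound variable(s) in expression: ", paste(missing, collapse = ", "),
         call. = FALSE)
  ## bind variables and any user-supplied functions referenced by name
  used <- intersect(names(bindings), all.names(ast))
  env <- list2env(bindings[used], parent = .exprFunEnv)
  val <- eval(ast, env)
  if (is.numeric(val) && length(val) >= 1L && any(is.nan(val)))
    stop("expression evaluated to NaN (domain error): ",
         deparse1(ast), call. = FALSE)
  val
}

## deparse an AST back to canonical text (used by the DSL unparser)
formatExpression <- function(ast) {
  paste(deparse(ast, width.cutoff = 500L), collapse = " ")
}
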