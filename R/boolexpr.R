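## Boolean expression trees: the update functions f_i of a logical model.
##
## A BoolExpr is a lightweight recursive list with an `op` field:
##   var   -- list(op = "var",   name = <identifier>)
##   const -- list(op = "const", value = 0L or 1L)
##   not   -- list(op = "not",   child = <BoolExpr>)
##   and   -- list(op = "and",   children = <list of >= 2 BoolExpr>)
##   or    -- list(op = "or",    children = <list of >= 2 BoolExpr>)
## And/Or children are kept flattened: no and directly under and, no or
## directly under or.

.bexpr <- function(x) {
  class(x) <- "BoolExpr"
  x
}

#' Construct Boolean expression nodes
#'
#' Low-level constructors for Boolean expression trees. `bVar` makes a
#' variable reference, `bConst` a 0/1 constant, `bNot` a negation, and
#' `bAnd`/`bOr` n-ary conjunctions and disjunctions. `bAnd` and `bOr`
#' flatten nested nodes of the same operator and collapse to their single
#' child when given one argument, so trees stay in canonical flattened form.
#'
#' @param name Variable identifier; must match `[A-Za-z0-9_]+`.
#' @param value Constant value, 0 or 1.
#' @param child,... Child expressions (`BoolExpr` objects).
#' @return A `BoolExpr`.
#' @seealso [parseRule()] for building expressions from rule text.
#' @examples
#' bOr(bAnd(bVar("A"), bNot(bVar("B"))), bVar("C"))
#' @export
bVar <- function(name) {
  if (!is.character(name) || length(name) != 1L || !grepl("^[A-Za-z0-9_]+$", name))
    stop("variable name must be a single token matching [A-Za-z0-9_]+, got: ",
         deparse(name))
  .bexpr(list(op = "var", name = name))
}

#' @rdname bVar
#' @export
bConst <- function(value) {
  value <- as.integer(value)
  if (length(value) != 1L || is.na(value) || !value %in% c(0L, 1L))
    stop("constant must be 0 or 1")
  .bexpr(list(op = "const", value = value))
}

#' @rdname bVar
#' @export
bNot <- function(child) {
  stopifnot(inherits(child, "BoolExpr"))
  .bexpr(list(op = "not", child = child))
}

.flatten <- function(op, args) {
  out <- list()
  for (a in args) {
    stopifnot(inherits(a, "BoolExpr"))
    if (a$op == op) out <- c(out, a$children) else out <- c(out, list(a))
  }
  out
}

#' @rdname bVar
#' @export
bAnd <- function(...) {
  kids <- .flatten("and", list(...))
  if (length(kids) == 0L) stop("bAnd needs at least one child")
  if (length(kids) == 1L) return(kids[[1L]])
  .bexpr(list(op = "and", children = kids))
}

#' @rdname bVar
#' @export
bOr <- function(...) {
  kids <- .flatten("or", list(...))
  if (length(kids) == 0L) stop("bOr needs at least one child")
  if (length(kids) == 1L) return(kids[[1L]])
  .bexpr(list(op = "or", children = kids))
}

## ---- parsing ----------------------------------------------------------

.tokenizeRule <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("&", "|", "!", "(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, pos = i)
      i <- i + 1L
      next
    }
    if (grepl("^[A-Za-z0-9_]$", ch)) {
      j <- i
      while (j <= n && grepl("^[A-Za-z0-9_]$", substr(text, j, j))) j <- j + 1L
      word <- substr(text, i, j - 1L)
      toks[[length(toks) + 1L]] <- list(type = "ident", text = word, pos = i)
      i <- j
      next
    }
    stop(sprintf("rule syntax error at position %d: unexpected character '%s'",
                 i, ch))
  }
  toks
}

#' Parse a Boolean rule string
#'
#' Parses rule text in the standard Boolean-network grammar: identifiers,
#' the constants `0` and `1`, negation `!`, conjunction `&`, disjunction
#' `|`, and parentheses. Operator precedence is `!` > `&` > `|`, binary
#' operators are left-associative, and parentheses override precedence --
#' the convention shared by common Boolean-rule file formats.
#'
#' @param text A single nonempty rule string, e.g. `"A & !B | C"`.
#' @return A `BoolExpr` expression tree.
#' @examples
#' parseRule("GATA1 & !PU1")
#' ruleToString(parseRule("A & (B | C)"))
#' @export
parseRule <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("rule text must be a single string")
  toks <- .tokenizeRule(text)
  if (length(toks) == 0L) stop("rule syntax error: empty rule")
  pos <- 1L

  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  fail <- function(msg) {
    t <- peek()
    where <- if (is.null(t)) paste0("end of input (position ", nchar(text) + 1L, ")")
             else sprintf("position %d near '%s'", t$pos, t$text)
    stop(sprintf("rule syntax error at %s: %s", where, msg))
  }

  parseOr <- function() {
    kids <- list(parseAnd())
    while (!is.null(peek()) && peek()$type == "|") {
      advance()
      kids[[length(kids) + 1L]] <- parseAnd()
    }
    do.call(bOr, kids)
  }
  parseAnd <- function() {
    kids <- list(parseNot())
    while (!is.null(peek()) && peek()$type == "&") {
      advance()
      kids[[length(kids) + 1L]] <- parseNot()
    }
    do.call(bAnd, kids)
  }
  parseNot <- function() {
    if (!is.null(peek()) && peek()$type == "!") {
      advance()
      return(bNot(parseNot()))
    }
    parseAtom()
  }
  parseAtom <- function() {
    t <- peek()
    if (is.null(t)) fail("expected identifier, constant or '('")
    if (t$type == "(") {
      advance()
      e <- parseOr()
      t2 <- peek()
      if (is.null(t2) || t2$type != ")") fail("expected ')'")
      advance()
      return(e)
    }
    if (t$type == "ident") {
      advance()
      if (t$text %in% c("0", "1")) return(bConst(as.integer(t$text)))
      return(bVar(t$text))
    }
    fail("expected identifier, constant or '('")
  }

  e <- parseOr()
  if (!is.null(peek())) fail("trailing input after complete rule")
  e
}

#' Serialize a Boolean expression to rule text
#'
#' Emits a rule string in the same grammar [parseRule()] reads, with minimal
#' parentheses under the precedence `!` > `&` > `|`. Parsing the result
#' yields an expression equivalent to the input.
#'
#' @param expr A `BoolExpr`.
#' @return A single rule string.
#' @export
ruleToString <- function(expr) {
  stopifnot(inherits(expr, "BoolExpr"))
  prec <- c(or = 1L, and = 2L, not = 3L, var = 4L, const = 4L)
  render <- function(e, parentPrec) {
    p <- prec[[e$op]]
    s <- switch(e$op,
      var   = e$name,
      const = as.character(e$value),
      not   = paste0("!", render(e$child, prec[["not"]])),
      and   = paste(vapply(e$children, render, "", parentPrec = p), collapse = " & "),
      or    = paste(vapply(e$children, render, "", parentPrec = p), collapse = " | "))
    if (p < parentPrec) paste0("(", s, ")") else s
  }
  render(expr, 0L)
}

#' @export
print.BoolExpr <- function(x, ...) {
  cat("<BoolExpr> ", ruleToString(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.BoolExpr <- function(x, ...) ruleToString(x)

## Syntactic variables, in first-appearance order.
.syntacticVars <- function(expr) {
  out <- character(0)
  walk <- function(e) {
    switch(e$op,
      var   = out[[length(out) + 1L]] <<- e$name,
      const = NULL,
      not   = walk(e$child),
      and   = ,
      or    = for (k in e$children) walk(k))
    invisible(NULL)
  }
  walk(expr)
  unique(out)
}

## Vectorised evaluation: `columns` is a function(name) -> 0/1 vector (all
## the same length). Returns an integer 0/1 vector.
.evalColumns <- function(expr, columns, len) {
  rec <- function(e) {
    switch(e$op,
      var   = columns(e$name),
      const = rep.int(e$value, len),
      not   = 1L - rec(e$child),
      and   = {
        acc <- rec(e$children[[1L]])
        for (k in e$children[-1L]) acc <- acc & rec(k)
        as.integer(acc)
      },
      or    = {
        acc <- rec(e$children[[1L]])
        for (k in e$children[-1L]) acc <- acc | rec(k)
        as.integer(acc)
      })
  }
  as.integer(rec(expr))
}

#' Evaluate a Boolean expression under an assignment
#'
#' Evaluates `expr` under `state`, a named 0/1 vector (one state) or a 0/1
#' matrix with named columns (one state per row, evaluated vectorised).
#' Every variable in the expression's support must be assigned.
#'
#' @param expr A `BoolExpr`.
#' @param state Named numeric/integer vector of 0/1 values, or a matrix with
#'   one column per node.
#' @return Integer 0/1 scalar (vector input) or vector (matrix input).
#' @examples
#' evalRule(parseRule("A & !B"), c(A = 1, B = 0))
#' @export
evalRule <- function(expr, state) {
  stopifnot(inherits(expr, "BoolExpr"))
  if (is.matrix(state)) {
    len <- nrow(state)
    columns <- function(name) {
      if (!name %in% colnames(state))
        stop("evaluation error: variable '", name, "' is not assigned")
      as.integer(state[, name])
    }
  } else {
    len <- 1L
    columns <- function(name) {
      if (is.null(names(state)) || !name %in% names(state))
        stop("evaluation error: variable '", name, "' is not assigned")
      as.integer(state[[name]])
    }
  }
  v <- .evalColumns(expr, columns, len)
  if (any(is.na(v)) || any(!v %in% c(0L, 1L)))
    stop("evaluation error: state values must be 0 or 1")
  v
}

## All 2^k assignments over `vars`, as a function giving each variable's
## column; assignment s (0-based) sets var j to bit j of s.
.assignmentColumns <- function(vars) {
  k <- length(vars)
  nStates <- bitwShiftL(1L, k)
  function(name) {
    j <- match(name, vars)
    if (is.na(j))
      stop("evaluation error: variable '", name, "' is not assigned")
    period <- bitwShiftL(1L, j - 1L)
    rep(rep(c(0L, 1L), each = period), length.out = nStates)
  }
}

## Truth table of expr over an explicit variable ordering.
.truthTable <- function(expr, vars) {
  nStates <- bitwShiftL(1L, length(vars))
  .evalColumns(expr, .assignmentColumns(vars), nStates)
}

#' Semantic support of a Boolean expression
#'
#' Returns the variables that can actually change the expression's output:
#' `v` is in the support iff some assignment exists where flipping `v` flips
#' the result. Variables absorbed by simplification (e.g. `B` in
#' `A | (A & B)`) are excluded, as is everything in a contradiction like
#' `A & !A`.
#'
#' @param expr A `BoolExpr`.
#' @param cap Maximum number of syntactic variables for the exhaustive test
#'   (default 20).
#' @return Character vector of node identifiers (sorted).
#' @export
exprSupport <- function(expr, cap = 20L) {
  vars <- .syntacticVars(expr)
  if (length(vars) == 0L) return(character(0))
  if (length(vars) > cap)
    stop("support computation exceeds cap of ", cap, " variables (",
         length(vars), " present)")
  tt <- .truthTable(expr, vars)
  nStates <- length(tt)
  idx <- seq_len(nStates) - 1L
  keep <- vapply(seq_along(vars), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    any(tt[idx + 1L] != tt[bitwXor(idx, bit) + 1L])
  }, logical(1))
  sort(vars[keep])
}

#' Infer regulator signs by exhaustive flip testing
#'
#' Classifies each regulator of a target as `activator`, `inhibitor`,
#' `dual`, or `none` from the rule's semantics. A regulator `r` is an
#' activator if some assignment has the rule going 0 to 1 when `r` goes
#' 0 to 1 (and never the reverse), an inhibitor if only the reverse
#' witness exists, `dual` if both, and `none` if flipping `r` never changes
#' the output. Semantic testing is the default because syntactic negation
#' can misreport signs after rule simplification; for supports above `cap`
#' use `method = "syntactic"`, which flags a regulator as inhibitory when
#' any of its occurrences sits under an odd number of negations.
#'
#' @param expr A `BoolExpr` rule.
#' @param target Target node identifier (copied into the result).
#' @param cap Maximum support size for the exhaustive test (default 16).
#' @param method `"semantic"` (exhaustive flip test) or `"syntactic"`.
#' @return A data.frame with columns `regulator`, `target`, `sign`, ordered
#'   by regulator.
#' @examples
#' inferSigns(parseRule("A & !B"), "C")
#' @export
inferSigns <- function(expr, target, cap = 16L,
                       method = c("semantic", "syntactic")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "BoolExpr"))
  if (method == "syntactic") return(.syntacticSigns(expr, target))
  vars <- .syntacticVars(expr)
  if (length(vars) > cap)
    stop("sign inference exceeds cap of ", cap, " variables (", length(vars),
         " present); use method = \"syntactic\" for the odd-negation fallback")
  if (length(vars) == 0L)
    return(data.frame(regulator = character(0), target = character(0),
                      sign = character(0), stringsAsFactors = FALSE))
  tt <- .truthTable(expr, vars)
  idx0 <- seq_len(length(tt)) - 1L
  signs <- vapply(seq_along(vars), function(j) {
    bit <- bitwShiftL(1L, j - 1L)
    low <- idx0[bitwAnd(idx0, bit) == 0L]
    f0 <- tt[low + 1L]
    f1 <- tt[low + bit + 1L]
    up <- any(f0 < f1)
    down <- any(f0 > f1)
    if (up && down) "dual" else if (up) "activator"
    else if (down) "inhibitor" else "none"
  }, character(1))
  out <- data.frame(regulator = vars, target = target, sign = signs,
                    stringsAsFactors = FALSE)
  out <- out[order(out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.syntacticSigns <- function(expr, target) {
  pos <- character(0); neg <- character(0)
  walk <- function(e, depth) {
    switch(e$op,
      var   = if (depth %% 2L == 1L) neg <<- c(neg, e$name)
              else pos <<- c(pos, e$name),
      const = NULL,
      not   = walk(e$child, depth + 1L),
      and   = ,
      or    = for (k in e$children) walk(k, depth))
    invisible(NULL)
  }
  walk(expr, 0L)
  vars <- sort(unique(c(pos, neg)))
  signs <- vapply(vars, function(v) {
    p <- v %in% pos; n <- v %in% neg
    if (p && n) "dual" else if (n) "inhibitor" else "activator"
  }, character(1))
  out <- data.frame(regulator = vars, target = target, sign = unname(signs),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Test two Boolean expressions for semantic equivalence
#'
#' True iff the two expressions agree on every assignment over the union of
#' their supports, checked exhaustively.
#'
#' @param a,b `BoolExpr` objects.
#' @param cap Maximum size of the union support (default 20).
#' @return Logical scalar.
#' @export
exprsEquivalent <- function(a, b, cap = 20L) {
  stopifnot(inherits(a, "BoolExpr"), inherits(b, "BoolExpr"))
  vars <- unique(c(.syntacticVars(a), .syntacticVars(b)))
  if (length(vars) > cap)
    stop("equivalence check exceeds cap of ", cap, " variables (",
         length(vars), " present)")
  identical(.truthTable(a, vars), .truthTable(b, vars))
}

## Rename variables in an expression; `map` is a named character vector
## old -> new. Names not in the map pass through.
.renameVars <- function(expr, map) {
  rec <- function(e) {
    switch(e$op,
      var   = if (e$name %in% names(map)) bVar(unname(map[[e$name]])) else e,
      const = e,
      not   = bNot(rec(e$child)),
      and   = do.call(bAnd, lapply(e$children, rec)),
      or    = do.call(bOr, lapply(e$children, rec)))
  }
  rec(expr)
}
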