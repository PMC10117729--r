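# Level expressions: the small boolean grammar over discrete node levels used
# by logical rules.  Atoms compare one node's level against a constant:
#   Name       shorthand for Name >= 1 ("the node is active")
#   Name=k     equality
#   Name<k     strictly below threshold k
#   Name>=k    at or above threshold k
# Connectives: ! (NOT), & (AND), | (OR), with parentheses; & binds tighter
# than |.  Expressions are stored as a small AST (nested lists) and evaluate
# either on a single named state vector or column-wise on a state matrix.

#' Parse a logical-rule expression
#'
#' Parses a rule string written in the package's rule grammar into an
#' expression tree.  Atoms are level comparisons (`Name`, `Name=k`, `Name<k`,
#' `Name>=k`); connectives are `!`, `&`, `|` and parentheses, with `&`
#' binding tighter than `|`.
#'
#' @param text A single character string containing the rule.
#' @return An object of class `level_expr` (an expression tree).
#' @examples
#' parse_rule("!IscR-H & !RyhB & Fe_free=2 & !H2O2")
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  toks <- tokenize_rule(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input after position ", st$pos, " in rule: ", text)
  }
  structure(e, class = "level_expr")
}

tokenize_rule <- function(text) {
  pat <- "[A-Za-z][A-Za-z0-9_.-]*|[0-9]+|>=|[=<!&|()]"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  # anything not matched and not whitespace is an error
  residue <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", residue)) {
    stop("unrecognized characters in rule: ", text)
  }
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; invisible(NULL) }
expect_tok <- function(st, tok) {
  if (!identical(peek(st), tok)) stop("expected '", tok, "' at token ", st$pos)
  advance(st)
}

parse_or <- function(st) {
  args <- list(parse_and(st))
  while (identical(peek(st), "|")) {
    advance(st)
    args <- c(args, list(parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

parse_and <- function(st) {
  args <- list(parse_unary(st))
  while (identical(peek(st), "&")) {
    advance(st)
    args <- c(args, list(parse_unary(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

parse_unary <- function(st) {
  if (identical(peek(st), "!")) {
    advance(st)
    return(list(op = "not", arg = parse_unary(st)))
  }
  parse_primary(st)
}

parse_primary <- function(st) {
  tok <- peek(st)
  if (is.na(tok)) stop("unexpected end of rule")
  if (tok == "(") {
    advance(st)
    e <- parse_or(st)
    expect_tok(st, ")")
    return(e)
  }
  if (!grepl("^[A-Za-z]", tok)) stop("unexpected token '", tok, "'")
  advance(st)
  nxt <- peek(st)
  if (identical(nxt, "=") || identical(nxt, "<") || identical(nxt, ">=")) {
    advance(st)
    k <- peek(st)
    if (is.na(k) || !grepl("^[0-9]+$", k)) stop("expected level after '", nxt, "'")
    advance(st)
    cmp <- c("=" = "eq", "<" = "lt", ">=" = "ge")[[nxt]]
    return(list(op = "atom", var = tok, cmp = cmp, k = as.integer(k)))
  }
  # bare name: truthy, i.e. >= 1
  list(op = "atom", var = tok, cmp = "ge", k = 1L)
}

#' Deparse an expression tree back to rule text
#'
#' Produces the canonical textual form of a parsed rule; `parse_rule()` and
#' `deparse_rule()` round-trip (`deparse_rule(parse_rule(x))` is stable).
#'
#' @param expr A `level_expr` tree (or an internal node of one).
#' @return A character string.
#' @export
deparse_rule <- function(expr) {
  dep <- function(e, parent) {
    switch(e$op,
      atom = {
        if (e$cmp == "ge" && e$k == 1L) e$var
        else if (e$cmp == "ge") paste0(e$var, ">=", e$k)
        else if (e$cmp == "eq") paste0(e$var, "=", e$k)
        else paste0(e$var, "<", e$k)
      },
      not = {
        inner <- dep(e$arg, "not")
        if (e$arg$op %in% c("and", "or")) paste0("!(", inner, ")")
        else paste0("!", inner)
      },
      and = {
        parts <- vapply(e$args, function(a) {
          s <- dep(a, "and")
          if (a$op == "or") paste0("(", s, ")") else s
        }, character(1))
        paste(parts, collapse = " & ")
      },
      or = {
        s <- paste(vapply(e$args, dep, character(1), parent = "or"),
                   collapse = " | ")
        if (parent == "or") s else s
      },
      stop("unknown expression op: ", e$op)
    )
  }
  dep(expr, "top")
}

#' @export
print.level_expr <- function(x, ...) {
  cat(deparse_rule(x), "\n")
  invisible(x)
}

# Evaluate an expression tree.  `values` is either a named integer vector
# (one state) or an integer matrix with one column per node (all states of a
# subspace); the result is a logical scalar or vector accordingly.
eval_expr <- function(expr, values) {
  if (is.matrix(values)) {
    getter <- function(v) values[, v]
  } else {
    getter <- function(v) values[[v]]
  }
  ev <- function(e) {
    switch(e$op,
      atom = {
        x <- getter(e$var)
        switch(e$cmp, ge = x >= e$k, eq = x == e$k, lt = x < e$k)
      },
      not = !ev(e$arg),
      and = Reduce(`&`, lapply(e$args, ev)),
      or  = Reduce(`|`, lapply(e$args, ev))
    )
  }
  ev(expr)
}

# Collect (var, level) comparison pairs appearing in an expression.
# A bare-name atom contributes threshold 1; Name<k and Name>=k contribute k;
# Name=k contributes max(k, 1) so that equality-with-zero (written !Name)
# still registers the level-1 threshold.
expr_atoms <- function(expr) {
  acc <- list()
  walk <- function(e) {
    if (e$op == "atom") {
      lev <- if (e$cmp == "eq" && e$k == 0L) 1L else e$k
      acc[[length(acc) + 1L]] <<- list(var = e$var, level = lev)
    } else if (e$op == "not") walk(e$arg)
    else lapply(e$args, walk)
    invisible(NULL)
  }
  walk(expr)
  acc
}
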