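# Kinetic-law expressions are plain R language objects: numeric literals,
# names (symbols) and calls.  Only the arithmetic operators +, -, *, /, ^
# are structurally analyzed; any other call (piecewise, delay, exp, ...)
# is carried opaquely and renders the law unanalyzable.

ARITH_OPS <- c("+", "-", "*", "/", "^")

# MathML builtins we recognise on input but never analyze structurally.
BUILTIN_FUNS <- c(
  "exp", "ln", "log", "log10", "sqrt", "root", "abs", "floor", "ceiling",
  "factorial", "piecewise", "delay", "sin", "cos", "tan", "sec", "csc",
  "cot", "sinh", "cosh", "tanh", "arcsin", "arccos", "arctan", "arcsinh",
  "arccosh", "arctanh", "arcsec", "arccsc", "arccot", "arcsech", "arccsch",
  "arccoth", "eq", "neq", "lt", "leq", "gt", "geq", "and", "or", "xor",
  "not", "min", "max", "rem", "quotient", "implies", "rateOf"
)

# Reserved symbols produced by the reader for non-identifier MathML atoms.
TIME_SYMBOL <- ".sbml_time"
RESERVED_SYMBOLS <- c(".sbml_time", ".sbml_avogadro", ".true", ".false")

is_num <- function(e) is.numeric(e) && length(e) == 1L

call_op <- function(e) {
  h <- e[[1L]]
  if (is.name(h)) as.character(h) else ""
}

#' Parse an infix rate-law string
#'
#' Parses a rate expression written with the operators `+ - * / ^`,
#' `pow(x, y)` and parentheses into the canonical expression form used
#' throughout the package (`pow` rewritten to `^`, parentheses stripped,
#' purely numeric subtrees folded).
#'
#' @param text a single character string, e.g. `"Cell*MI*V1*pow(K1 + MI, -1)"`.
#' @return an R language object (numeric, name or call).
#' @examples
#' parse_rate("uVol*k3*MKKK_P*MKK/(KK3 + MKK)")
#' @export
parse_rate <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  e <- tryCatch(str2lang(text), error = function(err) {
    stop("cannot parse rate expression '", text, "': ", conditionMessage(err),
         call. = FALSE)
  })
  canon_expr(e)
}

#' Canonicalize an expression
#'
#' Rewrites `pow(x, y)` as `x^y`, removes parentheses and unary `+`, and
#' folds purely numeric arithmetic subtrees to literals (`2*3` becomes `6`;
#' `1 + -1*M` is kept because it contains a symbol).  Idempotent.
#'
#' @param e an R language object.
#' @return the canonical form of `e`.
#' @export
canon_expr <- function(e) {
  if (is_num(e) || is.name(e)) return(e)
  if (!is.call(e)) stop("not an expression: ", class(e)[1L])
  op <- call_op(e)
  if (op == "(") return(canon_expr(e[[2L]]))
  if (op == "+" && length(e) == 2L) return(canon_expr(e[[2L]]))
  if (op == "pow" && length(e) == 3L) {
    return(canon_expr(call("^", e[[2L]], e[[3L]])))
  }
  args <- lapply(as.list(e)[-1L], canon_expr)
  if (op == "^" && length(args) == 2L && is_num(args[[2L]]) &&
      !is_num(args[[1L]])) {
    if (args[[2L]] == 1) return(args[[1L]])
    if (args[[2L]] == 0) return(1)
  }
  e2 <- as.call(c(e[[1L]], args))
  if (op %in% ARITH_OPS && all(vapply(args, is_num, logical(1L)))) {
    v <- tryCatch(eval(e2, baseenv()), error = function(err) NULL)
    if (!is.null(v) && is.numeric(v) && length(v) == 1L && is.finite(v)) {
      return(v)
    }
  }
  e2
}

#' Is an expression analyzable?
#'
#' A kinetic law is structurally analyzable when, after function-definition
#' expansion, it consists only of numbers, identifiers and the arithmetic
#' operators.  Laws containing `piecewise`, `delay`, the `time` csymbol,
#' boolean atoms or any other function application cannot be pattern-matched;
#' their structural properties are all false and they fall through to the
#' unclassified (NA) type unless they contain no species at all.
#'
#' @param e an expression.
#' @return `TRUE` or `FALSE`.
#' @export
is_analyzable <- function(e) {
  if (is_num(e)) return(TRUE)
  if (is.name(e)) return(!(as.character(e) %in% RESERVED_SYMBOLS))
  if (!is.call(e)) return(FALSE)
  op <- call_op(e)
  if (!(op %in% ARITH_OPS)) return(FALSE)
  all(vapply(as.list(e)[-1L], is_analyzable, logical(1L)))
}

# ---- constructors that keep trees small -------------------------------------

mk_neg <- function(e) {
  if (is_num(e)) return(-e)
  if (is.call(e) && call_op(e) == "-" && length(e) == 2L) return(e[[2L]])
  call("-", e)
}

mk_add <- function(a, b) {
  if (is_num(a) && a == 0) return(b)
  if (is_num(b) && b == 0) return(a)
  if (is_num(a) && is_num(b)) return(a + b)
  call("+", a, b)
}

mk_sub <- function(a, b) {
  if (is_num(b) && b == 0) return(a)
  if (is_num(a) && is_num(b)) return(a - b)
  call("-", a, b)
}

mk_mul <- function(a, b) {
  if (is_num(a)) {
    if (a == 1) return(b)
    if (is_num(b)) return(a * b)
  }
  if (is_num(b) && b == 1) return(a)
  call("*", a, b)
}

mk_div <- function(a, b) {
  if (is_num(b) && b == 1) return(a)
  if (is_num(a) && is_num(b) && b != 0) return(a / b)
  call("/", a, b)
}

mk_pow <- function(b, p) {
  if (is_num(p)) {
    if (p == 1) return(b)
    if (p == 0) return(1)
    if (is_num(b)) return(b^p)
  }
  if (is_num(b) && b == 1) return(1)
  call("^", b, p)
}

mk_mul_list <- function(xs) {
  if (length(xs) == 0L) return(1)
  Reduce(mk_mul, xs)
}

mk_add_list <- function(xs) {
  if (length(xs) == 0L) return(0)
  Reduce(mk_add, xs)
}

# ---- rational form ----------------------------------------------------------

#' Rewrite an expression as a single fraction
#'
#' Combines every division and every power with an (explicitly) negative
#' exponent into one numerator/denominator pair.  `pow(K1 + MI, -1)` is a
#' division in disguise; symbolic exponents are never assumed negative and
#' contribute to the denominator only when their base is itself a fraction
#' or the exponent is an explicit negation.  The quotient
#' `numerator/denominator` equals the input at every assignment where both
#' are defined.
#'
#' @param e an expression (canonical form; `canon_expr` is applied).
#' @return a list with elements `num` and `den` (expressions).
#' @examples
#' rational_form(parse_rate("Cell*MI*V1*pow(K1 + MI, -1)"))
#' @export
rational_form <- function(e) {
  e <- canon_expr(e)
  rf <- rf_rec(e)
  list(num = canon_expr(rf$num), den = canon_expr(rf$den))
}

rf_rec <- function(e) {
  if (is_num(e) || is.name(e)) return(list(num = e, den = 1))
  op <- call_op(e)
  if (op == "-" && length(e) == 2L) {
    r <- rf_rec(e[[2L]])
    return(list(num = mk_neg(r$num), den = r$den))
  }
  if (!(op %in% ARITH_OPS)) return(list(num = e, den = 1))  # opaque call
  a <- rf_rec(e[[2L]])
  b <- rf_rec(e[[3L]])
  switch(op,
    "+" = list(num = mk_add(mk_mul(a$num, b$den), mk_mul(b$num, a$den)),
               den = mk_mul(a$den, b$den)),
    "-" = list(num = mk_sub(mk_mul(a$num, b$den), mk_mul(b$num, a$den)),
               den = mk_mul(a$den, b$den)),
    "*" = list(num = mk_mul(a$num, b$num), den = mk_mul(a$den, b$den)),
    "/" = list(num = mk_mul(a$num, b$den), den = mk_mul(a$den, b$num)),
    "^" = rf_pow(a, e[[3L]])
  )
}

rf_pow <- function(base, expo) {
  if (is_num(expo)) {
    if (expo < 0) {
      return(list(num = mk_pow(base$den, -expo), den = mk_pow(base$num, -expo)))
    }
    return(list(num = mk_pow(base$num, expo), den = mk_pow(base$den, expo)))
  }
  if (is.call(expo) && call_op(expo) == "-" && length(expo) == 2L) {
    # explicitly negated symbolic exponent: x^(-a) == 1/x^a
    p <- expo[[2L]]
    return(list(num = mk_pow(base$den, p), den = mk_pow(base$num, p)))
  }
  list(num = mk_pow(base$num, expo), den = mk_pow(base$den, expo))
}

# ---- sum-of-terms expansion -------------------------------------------------

# Distribute products over sums/differences; returns a list of term
# expressions (signs carried inside the terms, e.g. as -(x) or a negative
# numeric coefficient).  Powers and opaque calls are atomic.
expand_terms <- function(e) {
  if (is_num(e) || is.name(e)) return(list(e))
  if (!is.call(e)) return(list(e))
  op <- call_op(e)
  if (op == "+" && length(e) == 3L) {
    return(c(expand_terms(e[[2L]]), expand_terms(e[[3L]])))
  }
  if (op == "-" && length(e) == 3L) {
    return(c(expand_terms(e[[2L]]), lapply(expand_terms(e[[3L]]), mk_neg)))
  }
  if (op == "-" && length(e) == 2L) {
    return(lapply(expand_terms(e[[2L]]), mk_neg))
  }
  if (op == "+" && length(e) == 2L) return(expand_terms(e[[2L]]))
  if (op == "*") {
    out <- list()
    for (a in expand_terms(e[[2L]])) {
      for (b in expand_terms(e[[3L]])) out <- c(out, list(mk_mul(a, b)))
    }
    return(out)
  }
  if (op == "/") {
    return(lapply(expand_terms(e[[2L]]), function(t) mk_div(t, e[[3L]])))
  }
  list(e)
}

# ---- factor decomposition ---------------------------------------------------

# Flatten a term into a numeric coefficient (sign included) and a list of
# factors, each a list(base =, exp =).  Division contributes factors with
# negated exponents; opaque subtrees (sums, function calls) become single
# compound factors.
flatten_factors <- function(e) {
  coef <- 1
  factors <- list()
  neg_exp <- function(p) if (is_num(p)) -p else mk_neg(p)
  walk <- function(e, inv) {
    if (is_num(e)) {
      coef <<- if (inv) coef / e else coef * e
      return(invisible())
    }
    if (is.name(e)) {
      factors[[length(factors) + 1L]] <<- list(base = e, exp = if (inv) -1 else 1)
      return(invisible())
    }
    op <- if (is.call(e)) call_op(e) else ""
    if (op == "*" && length(e) == 3L) {
      walk(e[[2L]], inv); walk(e[[3L]], inv)
    } else if (op == "/" && length(e) == 3L) {
      walk(e[[2L]], inv); walk(e[[3L]], !inv)
    } else if (op == "-" && length(e) == 2L) {
      coef <<- -coef
      walk(e[[2L]], inv)
    } else if (op == "+" && length(e) == 2L) {
      walk(e[[2L]], inv)
    } else if (op == "^" && length(e) == 3L && (is.name(e[[2L]]) || is_num(e[[2L]]))) {
      b <- e[[2L]]; p <- e[[3L]]
      if (is_num(b) && is_num(p)) {
        coef <<- if (inv) coef / b^p else coef * b^p
      } else {
        factors[[length(factors) + 1L]] <<-
          list(base = b, exp = if (inv) neg_exp(p) else p)
      }
    } else {
      factors[[length(factors) + 1L]] <<-
        list(base = e, exp = if (inv) -1 else 1)
    }
    invisible()
  }
  walk(e, FALSE)
  list(coef = coef, factors = factors)
}

# Rebuild an expression from flatten_factors output (absolute value if
# drop_sign), preserving factor order.
rebuild_term <- function(ff, drop_sign = FALSE) {
  coef <- if (drop_sign) abs(ff$coef) else ff$coef
  parts <- lapply(ff$factors, function(f) mk_pow(f$base, f$exp))
  if (coef != 1 || length(parts) == 0L) parts <- c(list(coef), parts)
  mk_mul_list(parts)
}

# ---- numeric evaluation helpers ---------------------------------------------

#' Evaluate a rate expression numerically
#'
#' @param e an expression.
#' @param values a named list or numeric vector of symbol assignments.
#' @return a numeric scalar.
#' @export
eval_rate <- function(e, values) {
  env <- list2env(as.list(values), parent = baseenv())
  assign("pow", function(x, y) x^y, envir = env)
  eval(e, envir = env)
}

# Relative-tolerance numeric equality of two expressions over random positive
# assignments of their symbols; used by tests and round-trip checks.
exprs_numeric_equal <- function(e1, e2, vars = union(all.vars(e1), all.vars(e2)),
                                n = 20L, tol = 1e-9) {
  for (i in seq_len(n)) {
    vals <- stats::runif(length(vars), 0.1, 3)
    names(vals) <- vars
    v1 <- eval_rate(e1, vals)
    v2 <- eval_rate(e2, vals)
    if (!is.finite(v1) || !is.finite(v2)) next
    if (abs(v1 - v2) > tol * max(1, abs(v1), abs(v2))) return(FALSE)
  }
  TRUE
}

# Substitute symbols in an expression: map is a named list of replacement
# expressions (or a named character vector of new symbol names).
substitute_symbols <- function(e, map) {
  map <- lapply(as.list(map), function(v) if (is.character(v)) as.name(v) else v)
  rec <- function(e) {
    if (is_num(e)) return(e)
    if (is.name(e)) {
      nm <- as.character(e)
      if (nm %in% names(map)) return(map[[nm]])
      return(e)
    }
    if (is.call(e)) {
      args <- lapply(as.list(e)[-1L], rec)
      return(as.call(c(e[[1L]], args)))
    }
    e
  }
  rec(e)
}
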