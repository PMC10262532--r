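# Inlining of SBML function definitions into kinetic laws.

#' Expand function definitions in a kinetic law
#'
#' Replaces every application of a defined function by the definition body
#' with formal arguments substituted by the actual argument subtrees,
#' recursively (definitions may call other definitions).  Arithmetic
#' operators and recognised MathML builtins (`exp`, `piecewise`, ...) are
#' left alone; the latter simply render the law unanalyzable downstream.
#'
#' @param e an expression.
#' @param defs named list of definitions, each `list(args = <character>,
#'   body = <expression>)`.
#' @return the expanded expression (canonical form), guaranteed free of
#'   applications of any function in `defs`.
#' @section Errors:
#' A call to an unknown function (neither arithmetic, builtin, nor defined),
#' an arity mismatch, or a cyclic definition chain raises an error with class
#' `kinclass_expand_error`.
#' @examples
#' defs <- list(f = list(args = c("x"), body = parse_rate("a*x + b")))
#' expand_functions(parse_rate("f(t)"), defs)
#' @export
expand_functions <- function(e, defs = list()) {
  expand_err <- function(...) {
    stop(errorCondition(paste0(...),
         class = c("kinclass_expand_error", "error", "condition")))
  }
  rec <- function(e, stack) {
    if (is_num(e) || is.name(e)) return(e)
    if (!is.call(e)) return(e)
    op <- call_op(e)
    args <- lapply(as.list(e)[-1L], rec, stack = stack)
    if (op %in% ARITH_OPS || op == "(" || op == "pow") {
      return(as.call(c(e[[1L]], args)))
    }
    if (op %in% names(defs)) {
      if (op %in% stack) {
        expand_err("cyclic function definitions involving '", op, "'")
      }
      def <- defs[[op]]
      if (length(args) != length(def$args)) {
        expand_err("function '", op, "' called with ", length(args),
                   " argument(s), defined with ", length(def$args))
      }
      body <- substitute_symbols(def$body, stats::setNames(args, def$args))
      return(rec(body, stack = c(stack, op)))
    }
    if (op %in% BUILTIN_FUNS) {
      return(as.call(c(e[[1L]], args)))
    }
    expand_err("unknown function '", op, "' in kinetic law")
  }
  canon_expr(rec(canon_expr(e), stack = character()))
}
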