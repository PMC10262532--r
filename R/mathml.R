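# MathML content markup <-> expression conversion.  SBML levels 2-3 encode
# kinetic-law math this way; level 1 uses infix formula strings instead
# (handled by parse_rate).

MATHML_OPS <- c(plus = "+", minus = "-", times = "*", divide = "/",
                power = "^")

local_name <- function(node) sub("^.*:", "", xml2::xml_name(node))

# node: an element below <math> (namespaces already stripped by the reader).
mathml_to_expr <- function(node) {
  nm <- local_name(node)
  switch(nm,
    ci = as.name(trimws(xml2::xml_text(node))),
    cn = mathml_cn(node),
    csymbol = mathml_csymbol(node),
    apply = mathml_apply(node),
    piecewise = mathml_piecewise(node),
    pi = pi,
    exponentiale = exp(1),
    infinity = Inf,
    notanumber = NaN,
    "true" = as.name(".true"),
    "false" = as.name(".false"),
    stop("unsupported MathML element <", nm, ">")
  )
}

mathml_cn <- function(node) {
  type <- xml2::xml_attr(node, "type")
  if (is.na(type) || type %in% c("integer", "real")) {
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  parts <- as.numeric(trimws(xml2::xml_find_all(node, "text()") |> xml2::xml_text()))
  parts <- parts[!is.na(parts)]
  if (type == "e-notation") return(parts[1L] * 10^parts[2L])
  if (type == "rational") return(parts[1L] / parts[2L])
  as.numeric(trimws(xml2::xml_text(node)))
}

mathml_csymbol <- function(node) {
  url <- xml2::xml_attr(node, "definitionURL")
  if (!is.na(url) && grepl("time", url, fixed = TRUE)) return(as.name(TIME_SYMBOL))
  if (!is.na(url) && grepl("avogadro", url, fixed = TRUE)) {
    return(as.name(".sbml_avogadro"))
  }
  if (!is.na(url) && grepl("delay", url, fixed = TRUE)) return(as.name("delay"))
  as.name(trimws(xml2::xml_text(node)))
}

mathml_apply <- function(node) {
  kids <- xml2::xml_children(node)
  if (!length(kids)) stop("empty MathML <apply>")
  head <- kids[[1L]]
  hname <- local_name(head)
  args <- lapply(kids[-1L], mathml_to_expr)
  if (hname == "ci" || hname == "csymbol") {
    fn <- mathml_to_expr(head)
    return(as.call(c(fn, args)))
  }
  if (hname %in% names(MATHML_OPS)) {
    op <- MATHML_OPS[[hname]]
    if (op == "+" && length(args) == 0L) return(0)
    if (op == "*" && length(args) == 0L) return(1)
    if (length(args) == 1L) {
      if (op == "-") return(call("-", args[[1L]]))
      return(args[[1L]])
    }
    return(Reduce(function(a, b) call(op, a, b), args))
  }
  # root with optional <degree>
  if (hname == "root") {
    deg <- 2
    if (length(args) == 2L) { deg <- args[[1L]]; args <- args[-1L] }
    return(call("^", args[[1L]], mk_div(1, deg)))
  }
  as.call(c(as.name(hname), args))
}

mathml_piecewise <- function(node) {
  out <- list()
  for (child in xml2::xml_children(node)) {
    cn <- local_name(child)
    parts <- lapply(xml2::xml_children(child), mathml_to_expr)
    if (cn == "piece") {
      out <- c(out, parts[1:2])
    } else if (cn == "otherwise") {
      out <- c(out, parts[1L])
    }
  }
  as.call(c(as.name("piecewise"), out))
}

# ---- writing ----------------------------------------------------------------

num_to_cn <- function(v) {
  if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
    sprintf("<cn type=\"integer\"> %s </cn>", format(v, scientific = FALSE))
  } else {
    sprintf("<cn> %s </cn>", format(v, digits = 17))
  }
}

REV_MATHML_OPS <- c("+" = "plus", "-" = "minus", "*" = "times",
                    "/" = "divide", "^" = "power")

# expression -> MathML content markup string (no <math> wrapper).
expr_to_mathml <- function(e) {
  if (is_num(e)) return(num_to_cn(e))
  if (is.name(e)) {
    nm <- as.character(e)
    if (nm == TIME_SYMBOL) {
      return(paste0("<csymbol encoding=\"text\" definitionURL=",
                    "\"http://www.sbml.org/sbml/symbols/time\"> t </csymbol>"))
    }
    if (nm == ".sbml_avogadro") {
      return(paste0("<csymbol encoding=\"text\" definitionURL=",
                    "\"http://www.sbml.org/sbml/symbols/avogadro\"> NA </csymbol>"))
    }
    if (nm == ".true") return("<true/>")
    if (nm == ".false") return("<false/>")
    return(sprintf("<ci> %s </ci>", nm))
  }
  if (!is.call(e)) stop("cannot serialize expression of class ", class(e)[1L])
  op <- call_op(e)
  args <- as.list(e)[-1L]
  if (op == "(") return(expr_to_mathml(args[[1L]]))
  if (op == "pow") op <- "^"
  if (op %in% names(REV_MATHML_OPS)) {
    inner <- vapply(args, expr_to_mathml, character(1L))
    return(sprintf("<apply> <%s/> %s </apply>", REV_MATHML_OPS[[op]],
                   paste(inner, collapse = " ")))
  }
  if (op == "piecewise") {
    n <- length(args)
    pieces <- character()
    i <- 1L
    while (i + 1L <= n) {
      pieces <- c(pieces, sprintf("<piece> %s %s </piece>",
                                  expr_to_mathml(args[[i]]),
                                  expr_to_mathml(args[[i + 1L]])))
      i <- i + 2L
    }
    if (i <= n) {
      pieces <- c(pieces, sprintf("<otherwise> %s </otherwise>",
                                  expr_to_mathml(args[[i]])))
    }
    return(sprintf("<piecewise> %s </piecewise>", paste(pieces, collapse = " ")))
  }
  # generic function application / builtin operator element
  inner <- vapply(args, expr_to_mathml, character(1L))
  if (op %in% BUILTIN_FUNS) {
    return(sprintf("<apply> <%s/> %s </apply>", op, paste(inner, collapse = " ")))
  }
  sprintf("<apply> <ci> %s </ci> %s </apply>", op, paste(inner, collapse = " "))
}

math_element <- function(e) {
  sprintf("<math xmlns=\"http://www.w3.org/1998/Math/MathML\"> %s </math>",
          expr_to_mathml(e))
}

lambda_element <- function(args, body) {
  bvars <- paste(sprintf("<bvar> <ci> %s </ci> </bvar>", args), collapse = " ")
  sprintf(paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\"> ",
                 "<lambda> %s %s </lambda> </math>"),
          bvars, expr_to_mathml(body))
}
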