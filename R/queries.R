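# Structural queries on kinetic-law expressions.  `roles` is a named
# character vector mapping each identifier to one of: species, parameter,
# compartment, local-parameter, function-name, time-like, other.

ROLE_LEVELS <- c("species", "parameter", "compartment", "local-parameter",
                 "function-name", "time-like", "other")

species_ids <- function(roles) names(roles)[roles == "species"]

check_symbols_resolved <- function(e, roles) {
  unknown <- setdiff(all.vars(e), names(roles))
  if (length(unknown)) {
    stop(errorCondition(
      paste0("unresolved symbol(s) in kinetic law: ",
             paste(unknown, collapse = ", ")),
      class = c("kinclass_symbol_error", "error", "condition")))
  }
  invisible(TRUE)
}

#' Species occurring in a kinetic law
#'
#' Returns the set of distinct identifiers with role `species` occurring
#' anywhere in the expression (numerator, denominator, exponents).
#' Compartments and (local) parameters never count as species.
#'
#' @param e an expanded expression.
#' @param roles named character vector of symbol roles.
#' @return character vector of species identifiers (possibly empty).
#' @export
species_in <- function(e, roles) {
  check_symbols_resolved(e, roles)
  intersect(all.vars(e), species_ids(roles))
}

contains_species <- function(e, roles) {
  length(intersect(all.vars(e), species_ids(roles))) > 0L
}

#' Does the denominator contain a species?
#'
#' True iff the law, brought to a single fraction by [rational_form()],
#' has at least one species symbol in its denominator.  This is the gate
#' for all fraction-shaped kinetics (Michaelis-Menten, Hill, FR).
#'
#' @inheritParams species_in
#' @return `TRUE` or `FALSE`.
#' @export
species_in_denominator <- function(e, roles) {
  if (!is_analyzable(e)) return(FALSE)
  check_symbols_resolved(e, roles)
  rf <- rational_form(e)
  contains_species(rf$den, roles)
}

# Per-factor census of a product.  Returns list(ok =, species_exp =) where
# ok is FALSE when any species occurs in a non-simple factor (inside a sum,
# a compound power base, an exponent, or with a non-positive/non-literal
# exponent unless allow_symbolic_exp) and species_exp is a named list
# id -> list of exponent expressions (one per occurrence).
product_species_factors <- function(e, roles, allow_symbolic_exp = FALSE) {
  sp <- species_ids(roles)
  ff <- flatten_factors(e)
  species_exp <- list()
  for (f in ff$factors) {
    vars <- union(all.vars(f$base), if (is_num(f$exp)) character() else all.vars(f$exp))
    if (!length(intersect(vars, sp))) next  # species-free factor: any shape
    if (!is.name(f$base) || !(as.character(f$base) %in% sp)) {
      return(list(ok = FALSE, species_exp = NULL))
    }
    if (!is_num(f$exp) && length(intersect(all.vars(f$exp), sp))) {
      return(list(ok = FALSE, species_exp = NULL))  # species in exponent
    }
    if (is_num(f$exp)) {
      if (f$exp <= 0) return(list(ok = FALSE, species_exp = NULL))
    } else if (!allow_symbolic_exp) {
      return(list(ok = FALSE, species_exp = NULL))
    }
    id <- as.character(f$base)
    species_exp[[id]] <- c(species_exp[[id]], list(f$exp))
  }
  list(ok = TRUE, species_exp = species_exp)
}

#' Is a kinetic law a single product of terms?
#'
#' True iff the law has no species in its denominator and its numerator is a
#' product whose species-containing factors are each a bare species symbol or
#' a species raised to a positive literal exponent.  Species-free additive
#' subexpressions inside a factor (e.g. `(k1 + k2)*S`) do not disqualify.
#'
#' @inheritParams species_in
#' @return `TRUE` or `FALSE`.
#' @export
is_single_product <- function(e, roles) {
  if (!is_analyzable(e)) return(FALSE)
  check_symbols_resolved(e, roles)
  rf <- rational_form(e)
  if (contains_species(rf$den, roles)) return(FALSE)
  product_species_factors(rf$num, roles)$ok
}

#' Decompose a kinetic law into a two-term difference
#'
#' Distributes products over sums; if exactly two terms remain, one positive
#' and one negative, and each term is individually a single product, returns
#' the pair (common species-free prefactors such as a compartment are
#' distributed into both terms).  Returns `NULL` otherwise, and always when
#' the denominator contains a species.
#'
#' @inheritParams species_in
#' @return `NULL`, or a list with elements `pos` and `neg` (expressions,
#'   signs removed).
#' @export
two_term_difference <- function(e, roles) {
  if (!is_analyzable(e)) return(NULL)
  check_symbols_resolved(e, roles)
  rf <- rational_form(e)
  if (contains_species(rf$den, roles)) return(NULL)
  terms <- expand_terms(rf$num)
  if (length(terms) != 2L) return(NULL)
  ffs <- lapply(terms, flatten_factors)
  signs <- vapply(ffs, function(ff) sign(ff$coef), numeric(1L))
  if (!setequal(signs, c(1, -1))) return(NULL)
  for (ff in ffs) {
    if (!product_species_factors(rebuild_term(ff, drop_sign = TRUE), roles)$ok) {
      return(NULL)
    }
  }
  pos <- rebuild_term(ffs[[which(signs > 0)]], drop_sign = TRUE)
  neg <- rebuild_term(ffs[[which(signs < 0)]], drop_sign = TRUE)
  if (!is_num(rf$den) || rf$den != 1) {
    pos <- mk_div(pos, rf$den)
    neg <- mk_div(neg, rf$den)
  }
  list(pos = pos, neg = neg)
}

# Exponent of species id within one denominator term; NULL when absent,
# NA when the occurrence is not a simple power of the bare symbol.
term_species_exponents <- function(term, roles) {
  product_species_factors(term, roles, allow_symbolic_exp = TRUE)
}

#' Match Michaelis-Menten shapes
#'
#' Tests the law against the two Michaelis-Menten patterns.  `"MM"`: the
#' numerator is a single product whose only species factor is one reactant
#' `S` with exponent 1, and the denominator is a sum of two or more terms
#' containing no species other than `S`, with `S` carrying exponent 1 in at
#' least one term.  `"MMCAT"`: as MM but the numerator's species factors are
#' exactly `{S, E}` (each exponent 1) with `S` a reactant and `E` any other
#' species absent from the denominator.  Returns `"none"` otherwise.
#'
#' @param e an expanded expression.
#' @param reactants character vector of the reaction's distinct reactants.
#' @param roles named character vector of symbol roles.
#' @return one of `"MM"`, `"MMCAT"`, `"none"`.
#' @export
match_michaelis_menten <- function(e, reactants, roles) {
  if (!is_analyzable(e)) return("none")
  check_symbols_resolved(e, roles)
  rf <- rational_form(e)
  den_sp <- intersect(all.vars(rf$den), species_ids(roles))
  if (!length(den_sp)) return("none")
  num <- product_species_factors(rf$num, roles)
  if (!num$ok) return("none")
  exps <- num$species_exp
  unit_exp <- function(xs) {
    length(xs) == 1L && is_num(xs[[1L]]) && xs[[1L]] == 1
  }
  if (!all(vapply(exps, unit_exp, logical(1L)))) return("none")
  num_sp <- names(exps)
  den_ok_for <- function(S) {
    if (!identical(sort(den_sp), sort(S))) return(FALSE)
    terms <- expand_terms(rf$den)
    if (length(terms) < 2L) return(FALSE)
    for (t in terms) {
      info <- term_species_exponents(t, roles)
      if (!info$ok) next
      xs <- info$species_exp[[S]]
      if (!is.null(xs) && unit_exp(xs)) return(TRUE)
    }
    FALSE
  }
  if (length(num_sp) == 1L) {
    S <- num_sp
    if (S %in% reactants && den_ok_for(S)) return("MM")
    return("none")
  }
  if (length(num_sp) == 2L) {
    for (S in num_sp) {
      E <- setdiff(num_sp, S)
      if (S %in% reactants && den_ok_for(S) && !(E %in% den_sp)) {
        return("MMCAT")
      }
    }
  }
  "none"
}

#' Match the Hill-equation shape
#'
#' True iff the law in rational form has a numerator whose only species
#' factor is a single species `S` raised to an exponent `p` (a symbol or a
#' literal different from 1) and a denominator that is a two-term sum of
#' `S^p` (syntactically identical exponent) and a species-free term, each
#' possibly scaled by species-free factors.  `S` need not be a reactant.
#'
#' @inheritParams species_in
#' @return `TRUE` or `FALSE`.
#' @export
match_hill <- function(e, roles) {
  if (!is_analyzable(e)) return(FALSE)
  check_symbols_resolved(e, roles)
  rf <- rational_form(e)
  num <- product_species_factors(rf$num, roles, allow_symbolic_exp = TRUE)
  if (!num$ok || length(num$species_exp) != 1L) return(FALSE)
  if (length(num$species_exp[[1L]]) != 1L) return(FALSE)
  S <- names(num$species_exp)
  p <- num$species_exp[[1L]][[1L]]
  if (is_num(p) && p == 1) return(FALSE)
  terms <- expand_terms(rf$den)
  if (length(terms) != 2L) return(FALSE)
  term_kind <- function(t) {
    if (!contains_species(t, roles)) return("free")
    info <- term_species_exponents(t, roles)
    if (!info$ok) return("bad")
    if (!identical(names(info$species_exp), S)) return("bad")
    xs <- info$species_exp[[S]]
    if (length(xs) == 1L && identical(xs[[1L]], p)) return("hill")
    "bad"
  }
  kinds <- vapply(terms, term_kind, character(1L))
  setequal(kinds, c("free", "hill"))
}
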