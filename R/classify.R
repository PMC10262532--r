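# Kinetics-type (K type) and reaction-type (R type) classification.
#
# A kinetic law is reduced to eight structural properties:
#   a  number of distinct species in the law
#   b  the law is a single product of terms
#   c  the law is the difference between two products of terms
#   d  term/species-to-reactant/product correspondence (meaning depends on
#      whether b or c holds)
#   e  Michaelis-Menten shape, single reactant in the numerator
#   f  Michaelis-Menten shape with an explicit enzyme in the numerator
#   g  Hill-equation shape
#   h  fraction with at least one species in the denominator
# and the decision table maps the properties to exactly one of ten types.

#' Canonical order of the ten kinetics types
#' @export
k_type_levels <- function() {
  c("ZERO", "UNDR", "UNMO", "BIDR", "BIMO", "MM", "MMCAT", "HILL", "FR", "NA")
}

#' Canonical order of the sixteen reaction types
#'
#' Labels are `"R=<r>,P=<p>"` with each count binned as 0, 1, 2 or >2,
#' ordered by (reactant bin, product bin).
#' @export
r_type_levels <- function() {
  bins <- c("0", "1", "2", ">2")
  as.vector(t(outer(bins, bins, function(r, p) sprintf("R=%s,P=%s", r, p))))
}

#' Canonical order of the 160 K-by-R cells (K within R)
#' @export
kr_type_levels <- function() {
  as.vector(vapply(r_type_levels(), function(r) paste(r, k_type_levels(), sep = "|"),
                   character(length(k_type_levels()))))
}

count_bin <- function(n) if (n > 2L) ">2" else as.character(n)

#' Compute the eight kinetics properties of a reaction's law
#'
#' @param reaction an [sbml_reaction()] with a non-`NULL` kinetic law.
#' @param roles named role vector (see [reaction_roles()]).
#' @param defs function-definition list for expansion (may be empty).
#' @return a list with fields `a` (integer) and `b`-`h` (logical).
#' @export
compute_k_properties <- function(reaction, roles, defs = list()) {
  if (is.null(reaction$math)) stop("reaction '", reaction$id, "' has no kinetic law")
  e <- expand_functions(reaction$math, defs)
  check_symbols_resolved(e, roles)
  sp <- species_in(e, roles)
  a <- length(sp)
  h <- species_in_denominator(e, roles)
  b <- is_single_product(e, roles)
  ttd <- if (!b) two_term_difference(e, roles) else NULL
  cc <- !is.null(ttd)
  d <- FALSE
  if (b) {
    d <- setequal(sp, reaction$reactants)
  } else if (cc) {
    d <- setequal(species_in(ttd$pos, roles), reaction$reactants) &&
      setequal(species_in(ttd$neg, roles), reaction$products)
  }
  mm <- match_michaelis_menten(e, reaction$reactants, roles)
  g <- match_hill(e, roles)
  list(a = a, b = b, c = cc, d = d,
       e = identical(mm, "MM"), f = identical(mm, "MMCAT"), g = g, h = h)
}

#' Assign the kinetics type from the eight properties
#'
#' The decision proceeds column by column, first match wins; with the
#' convention that single-product and two-term properties are false for
#' fraction-shaped laws, the types are mutually exclusive and the order is
#' immaterial, but it is fixed for determinism.
#'
#' @param props a property list as returned by [compute_k_properties()].
#' @return one of `"ZERO"`, `"UNDR"`, `"UNMO"`, `"BIDR"`, `"BIMO"`, `"MM"`,
#'   `"MMCAT"`, `"HILL"`, `"FR"`, `"NA"` (a string, never `NA`).
#' @export
classify_k_type <- function(props) {
  p <- props
  if (p$a == 0L) return("ZERO")
  if (p$b && p$d) return("UNDR")
  if (p$b && !p$d) return("UNMO")
  if (p$c && p$d) return("BIDR")
  if (p$c && !p$d) return("BIMO")
  if (p$a == 1L && p$e && p$h) return("MM")
  if (p$a == 2L && p$f && p$h) return("MMCAT")
  if (p$a == 1L && p$g && p$h) return("HILL")
  if (p$a > 0L && p$h && !p$e && !p$f && !p$g) return("FR")
  "NA"
}

#' Assign the reaction type
#'
#' The reaction type is the pair of distinct-reactant and distinct-product
#' counts, each binned as 0, 1, 2 or >2; it never depends on the kinetic
#' law.
#'
#' @param reaction an `sbml_reaction`.
#' @return a string of the form `"R=2,P=1"`.
#' @export
classify_r_type <- function(reaction) {
  sprintf("R=%s,P=%s",
          count_bin(length(reaction$reactants)),
          count_bin(length(reaction$products)))
}

render_reaction <- function(reaction) {
  side <- function(ids) {
    if (!length(ids)) "" else paste(sort(ids), collapse = " + ")
  }
  paste(side(reaction$reactants), "->", side(reaction$products))
}

render_law <- function(e) {
  if (is.null(e)) return(NA_character_)
  paste(deparse(e, width.cutoff = 500L), collapse = " ")
}

#' Classify one reaction
#'
#' Runs the full per-reaction pipeline: function-definition expansion,
#' property analysis, kinetics-type decision and reaction typing.  A law
#' that cannot be expanded or analyzed degrades to K type `"NA"` with a
#' warning rather than aborting a corpus run.
#'
#' @param reaction an `sbml_reaction` with a kinetic law.
#' @param roles named role vector in force for this reaction.
#' @param defs function-definition list of the enclosing model.
#' @param model_id model identifier used in renderings and diagnostics.
#' @return a one-row data frame with columns `model_id`, `reaction_id`,
#'   `reaction`, `kinetic_law`, `k_type`, `r_type` and the properties
#'   `a`-`h`.
#' @export
classify_reaction <- function(reaction, roles, defs = list(),
                              model_id = NA_character_) {
  props <- tryCatch(
    compute_k_properties(reaction, roles, defs),
    error = function(err) {
      warning("model '", model_id, "', reaction '", reaction$id,
              "': analysis failed (", conditionMessage(err),
              "); classified NA", call. = FALSE)
      list(a = NA_integer_, b = FALSE, c = FALSE, d = FALSE,
           e = FALSE, f = FALSE, g = FALSE, h = FALSE)
    })
  k <- if (is.na(props$a)) "NA" else classify_k_type(props)
  data.frame(model_id = model_id,
             reaction_id = reaction$id,
             reaction = render_reaction(reaction),
             kinetic_law = render_law(reaction$math),
             k_type = k,
             r_type = classify_r_type(reaction),
             a = props$a, b = props$b, c = props$c, d = props$d,
             e = props$e, f = props$f, g = props$g, h = props$h,
             stringsAsFactors = FALSE)
}
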