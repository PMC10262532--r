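# Structural queries and transformations on rate-law expressions.

test_that("canonicalization folds constants, strips pow/parens, is idempotent", {
  e <- parse_rate("2*3*A")
  expect_identical(e, quote(6 * A))
  expect_identical(parse_rate("pow(K1 + MI, -1)"),
                   call("^", quote(K1 + MI), -1))
  expect_identical(parse_rate("Cell*k1*pow(A, 1)"), quote(Cell * k1 * A))
  # additive structure with a symbol is never folded away
  expect_identical(parse_rate("1 + -1*M"),
                   call("+", 1, call("*", -1, quote(M))))
  for (tpl in template_library()) {
    e <- parse_rate(tpl$law)
    expect_identical(canon_expr(e), e, label = paste("idempotent:", tpl$law))
  }
})

test_that("rational form matches frozen structures on the worked shapes", {
  rf <- rational_form(parse_rate("Cell*MI*V1*pow(K1 + MI, -1)"))
  expect_identical(rf$num, quote(Cell * MI * V1))
  expect_identical(rf$den, quote(K1 + MI))

  rf <- rational_form(parse_rate("k1*A*B"))
  expect_identical(rf$num, quote(k1 * A * B))
  expect_identical(rf$den, 1)

  rf <- rational_form(parse_rate("(a1/b1)/(c1/d1)"))
  expect_identical(rf$num, quote(a1 * d1))
  expect_identical(rf$den, quote(b1 * c1))
})

test_that("every transformation preserves numeric value on the template library", {
  set.seed(101)
  for (tpl in template_library()) {
    if (!tpl$analyzable) next
    e <- parse_rate(tpl$law)
    rf <- rational_form(e)
    expect_value_preserved(e, rf)
    # sum-of-terms expansion of the numerator preserves value too
    terms <- kinclass:::expand_terms(rf$num)
    resummed <- kinclass:::mk_add_list(terms)
    expect_true(kinclass:::exprs_numeric_equal(rf$num, resummed),
                label = paste("expansion preserves", tpl$law))
  }
})

test_that("species census counts distinct species anywhere in the law", {
  roles <- make_roles(species = "CP", parameters = "k9",
                      compartments = "Cell")
  expect_identical(species_in(parse_rate("Cell*k1aa"),
                              make_roles(parameters = "k1aa",
                                         compartments = "Cell")),
                   character(0))
  expect_identical(species_in(parse_rate("Cell*CP*k9"), roles), "CP")
  roles2 <- make_roles(species = c("MKKK_P", "MKK"),
                       parameters = c("k3", "KK3"), compartments = "uVol")
  expect_setequal(
    species_in(parse_rate("uVol*k3*MKKK_P*MKK/(KK3 + MKK)"), roles2),
    c("MKKK_P", "MKK"))
  expect_error(species_in(parse_rate("k*Unknown"), roles),
               class = "kinclass_symbol_error")
})

test_that("single-product and denominator-species tests match the shape families", {
  cases <- list(
    list("Cell*CP*k9", "CP", single = TRUE, den_sp = FALSE),
    list("Comp1*(kf_0*B - kr_0*BL)", c("B", "BL"), single = FALSE, den_sp = FALSE),
    list("(k1 + k2)*A", "A", single = TRUE, den_sp = FALSE),
    list("k1*(A + B)", c("A", "B"), single = FALSE, den_sp = FALSE),
    list("uVol*k3*MKKK_P*MKK/(KK3 + MKK)", c("MKKK_P", "MKK"),
         single = FALSE, den_sp = TRUE),
    list("S/(k1 + k2)", "S", single = TRUE, den_sp = FALSE),
    list("k1*pow(A, 2)", "A", single = TRUE, den_sp = FALSE),
    list("pow(S, n)*k", "S", single = FALSE, den_sp = FALSE),
    list("A*pow(B, -1)", c("A", "B"), single = FALSE, den_sp = TRUE))
  for (cs in cases) {
    e <- parse_rate(cs[[1]])
    roles <- roles_for(e, cs[[2]])
    expect_identical(is_single_product(e, roles), cs$single,
                     label = paste("single:", cs[[1]]))
    expect_identical(species_in_denominator(e, roles), cs$den_sp,
                     label = paste("den:", cs[[1]]))
  }
})

test_that("two-term difference distributes prefactors and keeps orientation", {
  e <- parse_rate("Comp1*(kf_0*B - kr_0*BL)")
  roles <- roles_for(e, c("B", "BL"))
  d <- two_term_difference(e, roles)
  expect_setequal(species_in(d$pos, roles), "B")
  expect_setequal(species_in(d$neg, roles), "BL")

  e <- parse_rate("c1*g*s173*(s172 - s135)")
  roles <- roles_for(e, c("s172", "s135", "s173"))
  d <- two_term_difference(e, roles)
  expect_setequal(species_in(d$pos, roles), c("s173", "s172"))
  expect_setequal(species_in(d$neg, roles), c("s173", "s135"))

  # sign carried by a -1 coefficient, and term order in the source
  e <- parse_rate("-(kr*B) + kf*A")
  roles <- roles_for(e, c("A", "B"))
  d <- two_term_difference(e, roles)
  expect_setequal(species_in(d$pos, roles), "A")
  expect_setequal(species_in(d$neg, roles), "B")

  roles <- roles_for(parse_rate("k1*A"), "A")
  expect_null(two_term_difference(parse_rate("k1*A"), roles))
  e <- parse_rate("kf*A - kr*B + k3*C")
  expect_null(two_term_difference(e, roles_for(e, c("A", "B", "C"))))
  e <- parse_rate("kf*A + kr*B")
  expect_null(two_term_difference(e, roles_for(e, c("A", "B"))))
})

test_that("Michaelis-Menten matcher distinguishes MM, MMCAT and rejects others", {
  mm_case <- function(law, species, reactants) {
    e <- parse_rate(law)
    match_michaelis_menten(e, reactants, roles_for(e, species))
  }
  expect_identical(mm_case("Cell*MI*V1*pow(K1 + MI, -1)", "MI", "MI"), "MM")
  expect_identical(mm_case("V*S/(K1 + K2 + S)", "S", "S"), "MM")
  expect_identical(mm_case("1/(1/S + k)", "S", "S"), "MM")
  expect_identical(
    mm_case("uVol*k3*MKKK_P*MKK/(KK3 + MKK)", c("MKKK_P", "MKK"), "MKK"),
    "MMCAT")
  # numerator with additive species structure is no Michaelis-Menten form
  expect_identical(
    mm_case("Cell*(1 + -1*M)*V1*pow(K1 + -1*M + 1, -1)", "M", character()),
    "none")
  # the single numerator species must be a reactant
  expect_identical(mm_case("V*S/(K + S)", "S", character()), "none")
  # second species in the denominator disqualifies
  expect_identical(mm_case("V*S/(K + S + S2)", c("S", "S2"), "S"), "none")
  # squared numerator species disqualifies
  expect_identical(mm_case("V*S*S/(K + S)", "S", "S"), "none")
  # one-term denominator is not a Michaelis-Menten denominator
  expect_identical(mm_case("V*S/(K*S)", "S", "S"), "none")
})

test_that("Hill matcher requires one species with the same exponent in both places", {
  hill <- function(law, species) {
    e <- parse_rate(law)
    match_hill(e, roles_for(e, species))
  }
  expect_true(hill("Compartment*(n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a)))",
                   "cXn"))
  expect_true(hill("n1*pow(S, 2)/(pow(g1, 3) + pow(S, 2))", "S"))
  expect_true(hill("V*pow(S, hc)/(pow(K, hc) + pow(S, hc))", "S"))
  expect_false(hill("V*S/(K + S)", "S"))                       # exponent 1
  expect_false(hill("n1*pow(S, 2)/(pow(g1, 2) + pow(S, 3))", "S"))
  expect_false(hill("n1*pow(S, 2)/(pow(g1, 2) + pow(S, 2) + k)", "S"))
})

test_that("structural queries are invariant to renaming non-species symbols", {
  set.seed(77)
  for (tpl in template_library()) {
    if (!tpl$analyzable) next
    e <- parse_rate(tpl$law)
    roles <- roles_for(e, tpl$species)
    pars <- names(roles)[roles == "parameter"]
    if (!length(pars)) next
    ren <- stats::setNames(paste0("zz_", pars), pars)
    e2 <- kinclass:::substitute_symbols(e, as.list(ren))
    roles2 <- roles_for(e2, tpl$species)
    expect_identical(is_single_product(e, roles), is_single_product(e2, roles2),
                     label = paste("rename b:", tpl$law))
    expect_identical(species_in_denominator(e, roles),
                     species_in_denominator(e2, roles2),
                     label = paste("rename h:", tpl$law))
    expect_identical(match_hill(e, roles), match_hill(e2, roles2),
                     label = paste("rename g:", tpl$law))
    expect_identical(is.null(two_term_difference(e, roles)),
                     is.null(two_term_difference(e2, roles2)),
                     label = paste("rename c:", tpl$law))
  }
})

test_that("non-algebraic constructs are unanalyzable and all matchers decline", {
  e <- parse_rate("piecewise(k1, lt(.sbml_time, 5), k2*X)")
  roles <- roles_for(e, "X")
  expect_false(is_analyzable(e))
  expect_false(is_single_product(e, roles))
  expect_false(species_in_denominator(e, roles))
  expect_false(match_hill(e, roles))
  expect_identical(match_michaelis_menten(e, "X", roles), "none")
  expect_null(two_term_difference(e, roles))
  # the species census still sees X
  expect_identical(species_in(e, roles), "X")
})
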