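# Kinetics-property computation and the decision table.

test_that("property traces of the canonical examples match their published analysis", {
  ex <- kinetics_examples()
  # single product of terms whose species are exactly the reactants
  m <- ex$UNDR; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "b", "d")], list(a = 1L, b = TRUE, d = TRUE))
  expect_false(any(unlist(p[c("c", "e", "f", "g", "h")])))
  # moderator in the law, not a reactant
  m <- ex$UNMO; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "b", "d")], list(a = 1L, b = TRUE, d = FALSE))
  # two-term difference aligned with reactants and products
  m <- ex$BIDR; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "c", "d")], list(a = 2L, c = TRUE, d = TRUE))
  # fraction shapes switch on h and the matching e/f/g flag
  m <- ex$MM; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "e", "h")], list(a = 1L, e = TRUE, h = TRUE))
  expect_false(p$b)  # gated: a fraction is never a "single product"
  m <- ex$MMCAT; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "f", "h")], list(a = 2L, f = TRUE, h = TRUE))
  m <- ex$HILL; rx <- m$reactions[[1]]
  p <- compute_k_properties(rx, reaction_roles(m, rx))
  expect_identical(p[c("a", "g", "h")], list(a = 1L, g = TRUE, h = TRUE))
})

test_that("decision logic handles edge shapes", {
  # a bare number has zero species
  expect_identical(classify_law("5"), "ZERO")
  expect_identical(classify_law("k1 + k2"), "ZERO")
  # repeated species still equal the distinct reactant set
  expect_identical(classify_law("k1*A*A", reactants = "A"), "UNDR")
  # species-free additive factor does not break mass action
  expect_identical(classify_law("(k1 + k2)*A", reactants = "A"), "UNDR")
  # swapping the difference orientation demotes BIDR to BIMO
  expect_identical(
    classify_law("Comp1*(kf_0*B - kr_0*BL)", reactants = "B", products = "BL"),
    "BIDR")
  expect_identical(
    classify_law("Comp1*(kr_0*BL - kf_0*B)", reactants = "B", products = "BL"),
    "BIMO")
  # a Michaelis-Menten shape whose numerator species is not a reactant
  expect_identical(classify_law("V*S/(K + S)", species = "S"), "FR")
  # fraction with an extra denominator species
  expect_identical(
    classify_law("V*S/(K + S + S2)", species = "S2", reactants = "S"), "FR")
  # additive law that is neither product nor difference
  expect_identical(classify_law("k1 + k2*S", species = "S"), "NA")
  expect_identical(classify_law("pow(S, n)*k", species = "S"), "NA")
})

test_that("the decision table is total and single-valued over the property space", {
  lv <- k_type_levels()
  n_states <- 0L
  for (a in 0:3) {
    for (bits in 0:(2^7 - 1)) {
      fl <- as.logical(bitwAnd(bits, 2^(0:6)))
      props <- list(a = a, b = fl[1], c = fl[2], d = fl[3],
                    e = fl[4], f = fl[5], g = fl[6], h = fl[7])
      k <- classify_k_type(props)
      expect_true(is.character(k) && length(k) == 1L && k %in% lv)
      n_states <- n_states + 1L
    }
  }
  expect_identical(n_states, 512L)
})

test_that("kinetics type is invariant under scaling, factor order and expansion", {
  cases <- list(
    list("Cell*CP*k9", "CP", "CP", "C2"),
    list("Comp1*(kf_0*B - kr_0*BL)", c("B", "BL"), "B", "BL"),
    list("Cell*MI*V1*pow(K1 + MI, -1)", "MI", "MI", "M"),
    list("uVol*k3*MKKK_P*MKK/(KK3 + MKK)", c("MKKK_P", "MKK"), "MKK", "MKK_P"),
    list("n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a))", "cXn", character(), "cLm"))
  for (cs in cases) {
    base <- classify_law(cs[[1]], species = cs[[2]], reactants = cs[[3]],
                         products = cs[[4]])
    scaled <- classify_law(paste0("scale_par*(", cs[[1]], ")"),
                           species = cs[[2]], reactants = cs[[3]],
                           products = cs[[4]])
    expect_identical(scaled, base, label = paste("scaling", cs[[1]]))
    # wrap the law in a function definition: classification unchanged
    e <- parse_rate(cs[[1]])
    vars <- sort(all.vars(e))
    formals <- sprintf("x%d", seq_along(vars))
    defs <- list(fd = list(
      args = formals,
      body = kinclass:::substitute_symbols(e, stats::setNames(formals, vars))))
    rx <- sbml_reaction("r1", reactants = cs[[3]],
                        products = if (length(cs[[4]])) cs[[4]] else character(),
                        math = as.call(c(as.name("fd"), lapply(vars, as.name))))
    roles <- roles_for(e, unique(c(cs[[2]], cs[[3]], cs[[4]])))
    wrapped <- classify_k_type(compute_k_properties(rx, roles, defs))
    expect_identical(wrapped, base, label = paste("expansion", cs[[1]]))
  }
  # shuffled factor order never changes the type
  set.seed(31)
  for (tpl in template_library()) {
    if (!tpl$analyzable) next
    base <- classify_law(tpl$law, species = tpl$species,
                         reactants = tpl$species[1][length(tpl$species) > 0])
    e2 <- kinclass:::shuffle_factors(parse_rate(tpl$law))
    rx <- sbml_reaction("r1",
                        reactants = tpl$species[1][length(tpl$species) > 0],
                        math = e2)
    roles <- roles_for(e2, tpl$species)
    expect_identical(classify_k_type(compute_k_properties(rx, roles)), base,
                     label = paste("shuffle", tpl$law))
  }
})

test_that("reaction types bin distinct reactant and product counts at >2", {
  bin_of <- function(nr, np) {
    classify_r_type(sbml_reaction("r", reactants = sprintf("R%d", seq_len(nr)),
                                  products = sprintf("P%d", seq_len(np))))
  }
  expect_identical(bin_of(2, 1), "R=2,P=1")
  expect_identical(bin_of(0, 1), "R=0,P=1")
  expect_identical(bin_of(4, 1), "R=>2,P=1")
  expect_identical(bin_of(0, 0), "R=0,P=0")
  expect_identical(bin_of(3, 5), "R=>2,P=>2")
  # the kinetic law never enters the reaction type
  rx <- sbml_reaction("r", reactants = "A", products = "B",
                      math = parse_rate("piecewise(k, lt(.sbml_time, 1), 0)"))
  expect_identical(classify_r_type(rx), "R=1,P=1")
})

test_that("analysis failures degrade to NA with a diagnostic", {
  rx <- sbml_reaction("r1", reactants = "A",
                      math = parse_rate("mystery_fun(A, k)"))
  roles <- make_roles(species = "A", parameters = "k")
  expect_warning(res <- classify_reaction(rx, roles, model_id = "m"),
                 "classified NA")
  expect_identical(res$k_type, "NA")
})
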