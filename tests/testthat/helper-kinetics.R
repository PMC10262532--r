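# Shared fixtures: role builders, a library of rate-law templates spanning
# all shape families, and numeric-equivalence utilities.

make_roles <- function(species = character(), parameters = character(),
                       compartments = character()) {
  c(stats::setNames(rep("species", length(species)), species),
    stats::setNames(rep("parameter", length(parameters)), parameters),
    stats::setNames(rep("compartment", length(compartments)), compartments),
    stats::setNames("time-like", ".sbml_time"))
}

# Roles covering every symbol of an expression: listed ids are species,
# everything else defaults to parameter.
roles_for <- function(e, species = character()) {
  vars <- setdiff(all.vars(e), ".sbml_time")
  make_roles(species = intersect(vars, species),
             parameters = setdiff(vars, species))
}

toy_reaction <- function(law, reactants = character(), products = character(),
                         modifiers = character(), id = "r1") {
  sbml_reaction(id = id, reactants = reactants, products = products,
                modifiers = modifiers, math = parse_rate(law))
}

classify_law <- function(law, species = character(), reactants = character(),
                         products = character()) {
  rx <- toy_reaction(law, reactants, products)
  roles <- roles_for(rx$math, species = unique(c(species, reactants, products)))
  classify_k_type(compute_k_properties(rx, roles))
}

# Rate-law template library: law string + which symbols are species.
# Covers products, differences, Michaelis-Menten, Hill, other fractions,
# nested rationals and unanalyzable shapes.
template_library <- function() {
  t <- function(law, species = character(), analyzable = TRUE) {
    list(law = law, species = species, analyzable = analyzable)
  }
  list(
    t("k1"),
    t("Cell*k1aa"),
    t("k1*A", "A"),
    t("k1*A*B", c("A", "B")),
    t("Cell*CP*k9", "CP"),
    t("k1*A*A", "A"),
    t("k1*pow(A, 2)", "A"),
    t("(k1 + k2)*A", "A"),
    t("comp*k*S1*S2*S3", c("S1", "S2", "S3")),
    t("k_tl*X", "X"),
    t("2*3*A", "A"),
    t("k1*A/k2", "A"),
    t("A*B/(k1*k2)", c("A", "B")),
    t("Cell*k1*pow(A, 1)", "A"),
    t("kf*A - kr*B", c("A", "B")),
    t("Comp1*(kf_0*B - kr_0*BL)", c("B", "BL")),
    t("c1*g*s173*(s172 - s135)", c("s172", "s135", "s173")),
    t("M*(kf*A - kr*B)", c("A", "B", "M")),
    t("kf*A - kr*B + k3*C", c("A", "B", "C")),
    t("kf*A + kr*B", c("A", "B")),
    t("-(kr*B) + kf*A", c("A", "B")),
    t("(kf*A - kr*B)/k3", c("A", "B")),
    t("k1*(A + B)", c("A", "B")),
    t("V*S/(K + S)", "S"),
    t("Cell*MI*V1*pow(K1 + MI, -1)", "MI"),
    t("V*S/(K + S + S2)", c("S", "S2")),
    t("uVol*k3*MKKK_P*MKK/(KK3 + MKK)", c("MKK", "MKKK_P")),
    t("kcat*E2*S/(Km + S)", c("S", "E2")),
    t("V*S*S/(K + S)", "S"),
    t("V*S/(K1 + K2 + S)", "S"),
    t("V*S/(K*pow(S, 2))", "S"),
    t("V*S2/(K + S1)", c("S1", "S2")),
    t("n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a))", "cXn"),
    t("Compartment*(n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a)))", "cXn"),
    t("n1*pow(S, 2)/(pow(g1, 3) + pow(S, 2))", "S"),
    t("n1*pow(S, 2)/(pow(g1, 2) + pow(S, 3))", "S"),
    t("V*pow(S, hc)/(pow(K, hc) + pow(S, hc))", "S"),
    t("Cell*(1 + -1*M)*V1*pow(K1 + -1*M + 1, -1)", "M"),
    t("k*A/(K + B)", c("A", "B")),
    t("kp/(K + S)", "S"),
    t("(kf*A - kr*B)/(K + A)", c("A", "B")),
    t(paste0("WholeCell*((1 - pow(1 - prct, npt))*tccctimp",
             " + pow(1 - prct, npt)*tcdvpmt)*timp"), c("prct", "timp")),
    t("pow(S, n)*k", "S"),
    t("k1 + k2*S", "S"),
    t("(a1/b1)/(c1/d1)", c("a1", "c1")),
    t("1/(1/S + k)", "S"),
    t("A*pow(B, -1)", c("A", "B")),
    t("S*pow(K + S, -2)", "S"),
    t("at*tt + bt"),
    t("(S + 1)*2", "S"),
    t("k1*S1*pow(S2, 2)/(Km + S1)", c("S1", "S2")),
    t("V*S/(K + S) + k2*S", "S"),
    t("q1*q2*pow(K2 + S1*S2, -1)*S1", c("S1", "S2")),
    t("exp(-k*td)*A", "A", analyzable = FALSE),
    t("piecewise(k1, lt(.sbml_time, 5), k2*X)", "X", analyzable = FALSE)
  )
}

# num/den recombined must equal the original law at random positive points.
expect_value_preserved <- function(e, rf, vars = all.vars(e), tol = 1e-9) {
  recombined <- call("/", rf$num, rf$den)
  expect_true(kinclass:::exprs_numeric_equal(e, recombined, vars,
                                             n = 20L, tol = tol),
              label = paste("value preserved for", deparse(e)))
}
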