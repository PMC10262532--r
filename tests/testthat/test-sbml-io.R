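# SBML reading (levels 1-3), writing (L3V1), role resolution and
# function-definition expansion.

test_that("level 1 documents with infix formulas and duplicate reactants read correctly", {
  path <- system.file("extdata", "l1_toy.xml", package = "kinclass")
  m <- read_sbml(path)
  expect_identical(m$model_id, "l1_toy")
  expect_setequal(m$species, c("A", "B"))
  rx <- m$reactions[[1]]
  # species listed twice (and with stoichiometry 2) count once
  expect_identical(rx$reactants, "A")
  expect_identical(rx$products, "B")
  roles <- reaction_roles(m, rx)
  expect_identical(unname(roles["cell"]), "compartment")
  res <- classify_reaction(rx, roles, m$function_defs, m$model_id)
  expect_identical(res$k_type, "UNDR")
  expect_identical(res$r_type, "R=1,P=1")
})

test_that("level 2 MathML with a function definition reads, expands and classifies", {
  path <- system.file("extdata", "l2_fundef.xml", package = "kinclass")
  expect_warning(m <- read_sbml(path), "no kinetic law")
  expect_named(m$function_defs, "mmrate")
  rx <- m$reactions[[1]]
  roles <- reaction_roles(m, rx)
  expanded <- expand_functions(rx$math, m$function_defs)
  expect_true(is_analyzable(expanded))
  expect_identical(classify_reaction(rx, roles, m$function_defs)$k_type, "MM")
  # e-notation constant folded into the numeric coefficient
  expect_true(kinclass:::exprs_numeric_equal(
    expanded, parse_rate("1.5*Vmax*S/(Km + S)")))
  # the reaction without a kinetic law is retained, unclassifiable
  expect_null(m$reactions[[2]]$math)
})

test_that("piecewise laws with the time csymbol survive reading and fall to NA", {
  path <- system.file("extdata", "l3_piecewise.xml", package = "kinclass")
  m <- read_sbml(path)
  rx <- m$reactions[[1]]
  expect_false(is_analyzable(rx$math))
  res <- classify_reaction(rx, reaction_roles(m, rx), m$function_defs)
  expect_identical(res$k_type, "NA")
})

test_that("writing and re-reading a model preserves reactions, roles and law values", {
  set.seed(11)
  cfg <- corpus_config(n_models = 4, reactions_per_model = c(4, 6), seed = 5,
                       p_function_def = 0.5, p_compartment = 0.5,
                       p_pow_division = 0.5, shuffle = TRUE)
  out <- generate_corpus(cfg)
  for (m in out$models) {
    path <- tempfile(fileext = ".xml")
    write_sbml(m, path)
    m2 <- suppressWarnings(read_sbml(path))
    expect_identical(m2$model_id, m$model_id)
    expect_setequal(m2$species, m$species)
    expect_identical(symbol_roles(m2), symbol_roles(m))
    expect_length(m2$reactions, length(m$reactions))
    for (i in seq_along(m$reactions)) {
      a <- m$reactions[[i]]; b <- m2$reactions[[i]]
      expect_setequal(b$reactants, a$reactants)
      expect_setequal(b$products, a$products)
      ea <- expand_functions(a$math, m$function_defs)
      eb <- expand_functions(b$math, m2$function_defs)
      if (is_analyzable(ea)) {
        expect_true(kinclass:::exprs_numeric_equal(ea, eb, tol = 1e-9),
                    label = paste("law value", m$model_id, a$id))
      } else {
        expect_identical(eb, ea)
      }
    }
  }
})

test_that("local parameters shadow global species inside their reaction only", {
  base <- sbml_model("shadow", compartments = "c0",
                     species = c("k", "P2"), parameters = "v")
  rx_shadowed <- sbml_reaction("r1", reactants = "P2", products = character(),
                               math = parse_rate("v*k*P2"),
                               local_parameters = "k")
  rx_plain <- sbml_reaction("r2", reactants = "P2", products = character(),
                            math = parse_rate("v*k*P2"))
  m <- base; m$reactions <- list(rx_shadowed, rx_plain)
  roles1 <- reaction_roles(m, rx_shadowed)
  roles2 <- reaction_roles(m, rx_plain)
  expect_identical(unname(roles1["k"]), "local-parameter")
  expect_identical(unname(roles2["k"]), "species")
  expect_identical(species_in(rx_shadowed$math, roles1), "P2")
  expect_setequal(species_in(rx_plain$math, roles2), c("k", "P2"))
  # the species count difference flips the kinetics type
  expect_identical(classify_reaction(rx_shadowed, roles1)$k_type, "UNDR")
  expect_identical(classify_reaction(rx_plain, roles2)$k_type, "UNMO")
})

test_that("function expansion substitutes recursively and reports misuse", {
  defs <- list(
    f = list(args = "x", body = parse_rate("x + 1")),
    g = list(args = "y", body = parse_rate("f(y)*2")))
  expect_identical(expand_functions(parse_rate("g(S)"), defs),
                   call("*", quote(S + 1), 2))
  defs_ab <- list(f = list(args = "x", body = parse_rate("a*x + b")))
  expect_identical(expand_functions(parse_rate("f(t)"), defs_ab),
                   quote(a * t + b))
  # identity on expression without applications
  e <- parse_rate("k1*A*B")
  expect_identical(expand_functions(e, defs), e)
  expect_error(expand_functions(parse_rate("f(a, b)"), defs_ab),
               class = "kinclass_expand_error")
  expect_error(expand_functions(parse_rate("nosuch(a)"), defs_ab),
               class = "kinclass_expand_error")
  cyc <- list(f = list(args = "x", body = parse_rate("g(x)")),
              g = list(args = "x", body = parse_rate("f(x)")))
  expect_error(expand_functions(parse_rate("f(a)"), cyc),
               class = "kinclass_expand_error")
})

test_that("an empty model round-trips and unreadable input errors name the file", {
  m <- sbml_model("empty_model")
  path <- tempfile(fileext = ".xml")
  write_sbml(m, path)
  m2 <- read_sbml(path)
  expect_identical(m2$model_id, "empty_model")
  expect_length(m2$reactions, 0)
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model", bad)
  expect_error(read_sbml(bad), basename(bad), fixed = TRUE)
})
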