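# Ten tiny one-reaction models, one per kinetics type, with rate laws drawn
# from curated public repository models.  They double as documentation of
# the scheme and as the canonical regression fixture: classification must recover each type.

kinetics_example_specs <- function() {
  list(
    list(k_type = "ZERO", model_id = "ex_zero",
         reactants = "EmptySet", products = "Y", modifiers = character(),
         species = c("EmptySet", "Y"), parameters = "k1aa",
         compartments = "Cell", law = "Cell*k1aa"),
    list(k_type = "UNDR", model_id = "ex_undr",
         reactants = "CP", products = "C2", modifiers = character(),
         species = c("CP", "C2"), parameters = "k9",
         compartments = "Cell", law = "Cell*CP*k9"),
    list(k_type = "UNMO", model_id = "ex_unmo",
         reactants = character(), products = "PX", modifiers = "X",
         species = c("PX", "X"), parameters = "k_tl",
         compartments = character(), law = "k_tl*X"),
    list(k_type = "BIDR", model_id = "ex_bidr",
         reactants = "B", products = "BL", modifiers = character(),
         species = c("B", "BL"), parameters = c("kf_0", "kr_0"),
         compartments = "Comp1", law = "Comp1*(kf_0*B - kr_0*BL)"),
    list(k_type = "BIMO", model_id = "ex_bimo",
         reactants = "s172", products = "s135", modifiers = "s173",
         species = c("s172", "s135", "s173"), parameters = "g",
         compartments = "c1", law = "c1*g*s173*(s172 - s135)"),
    list(k_type = "MM", model_id = "ex_mm",
         reactants = "MI", products = "M", modifiers = character(),
         species = c("MI", "M"), parameters = c("V1", "K1"),
         compartments = "Cell", law = "Cell*MI*V1*pow(K1 + MI, -1)"),
    list(k_type = "MMCAT", model_id = "ex_mmcat",
         reactants = "MKK", products = "MKK_P", modifiers = "MKKK_P",
         species = c("MKK", "MKK_P", "MKKK_P"), parameters = c("k3", "KK3"),
         compartments = "uVol", law = "uVol*k3*MKKK_P*MKK/(KK3 + MKK)"),
    list(k_type = "HILL", model_id = "ex_hill",
         reactants = character(), products = "cLm", modifiers = "cXn",
         species = c("cLm", "cXn"), parameters = c("n1", "a", "g1"),
         compartments = "Compartment",
         law = "Compartment*(n1*pow(cXn, a)/(pow(g1, a) + pow(cXn, a)))"),
    list(k_type = "FR", model_id = "ex_fr",
         reactants = character(), products = "M", modifiers = character(),
         species = "M", parameters = c("V1", "K1"),
         compartments = "Cell",
         law = "Cell*(1 + -1*M)*V1*pow(K1 + -1*M + 1, -1)"),
    list(k_type = "NA", model_id = "ex_na",
         reactants = character(), products = "timm",
         modifiers = c("prct", "timp"),
         species = c("timm", "prct", "timp"),
         parameters = c("npt", "tccctimp", "tcdvpmt"),
         compartments = "WholeCell",
         law = paste0("WholeCell*((1 - pow(1 - prct, npt))*tccctimp",
                      " + pow(1 - prct, npt)*tcdvpmt)*timp"))
  )
}

#' The ten canonical kinetics-type example models
#'
#' Builds ten one-reaction models, each exemplifying one kinetics type with
#' a rate law taken from a curated repository model (species, parameter and
#' compartment roles as published).  Useful as a worked example and as a
#' self-check: `classify_corpus()` on these models must recover every type.
#'
#' @return named list of `sbml_model` objects, in canonical kinetics-type
#'   order (ZERO through NA).
#' @export
kinetics_examples <- function() {
  out <- lapply(kinetics_example_specs(), function(sp) {
    sbml_model(
      model_id = sp$model_id,
      compartments = sp$compartments,
      species = sp$species,
      parameters = sp$parameters,
      reactions = list(sbml_reaction(
        id = "re1", reactants = sp$reactants, products = sp$products,
        modifiers = sp$modifiers, math = parse_rate(sp$law))))
  })
  stats::setNames(out, vapply(kinetics_example_specs(), `[[`, "", "k_type"))
}

#' Write the canonical example models as SBML files
#'
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_kinetics_examples <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(kinetics_examples(), function(m) {
    write_sbml(m, file.path(dir, paste0(m$model_id, ".xml")))
  }, character(1L))
  invisible(paths)
}
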