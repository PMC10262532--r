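Package: kinclass
Title: Annotation-Independent Classification of Reaction Kinetics in SBML Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies the kinetic law of every reaction in a collection of
    SBML models (levels 1-3) into one of ten mutually exclusive kinetics types
    (zeroth order, uni- and bi-directional mass action with or without
    moderators, Michaelis-Menten with or without an explicit enzyme, Hill,
    other fractional forms, and unclassified) purely from the algebraic
    structure of the rate expression and the reaction's distinct reactants and
    products, without using SBO or MIRIAM annotations.  Reactions are further
    binned by reaction type (number of distinct reactants and products), and
    corpus-level distributions are reported both pooled over all reactions and
    averaged per model with standard errors.  Includes a seeded synthetic-corpus
    generator emitting labelled SBML fixtures for validation and for random
    reaction-network studies, plus command-line style report drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    xml2,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
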