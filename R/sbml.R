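# Reading SBML levels 1-3 and writing SBML Level 3 Version 1.  Only the
# elements the classification needs are modelled: compartments, species,
# global/local parameters, function definitions, and reactions with their
# kinetic laws.  Rate rules, assignment rules and events are ignored (a
# note is logged when present).

id_or_name <- function(node) {
  id <- xml2::xml_attr(node, "id")
  if (!is.na(id) && nzchar(id)) return(id)
  nm <- xml2::xml_attr(node, "name")
  if (!is.na(nm) && nzchar(nm)) return(nm)
  NA_character_
}

#' Construct an in-memory SBML model record
#'
#' @param model_id model identifier (unique within a corpus).
#' @param compartments,species,parameters character vectors of identifiers.
#' @param function_defs named list of `list(args =, body =)` definitions.
#' @param reactions list of reactions built with [sbml_reaction()].
#' @return an object of class `sbml_model`.
#' @export
sbml_model <- function(model_id, compartments = character(),
                       species = character(), parameters = character(),
                       function_defs = list(), reactions = list()) {
  structure(list(model_id = model_id,
                 compartments = compartments,
                 species = species,
                 parameters = parameters,
                 function_defs = function_defs,
                 reactions = reactions),
            class = "sbml_model")
}

#' Construct a reaction record
#'
#' Reactant/product/modifier lists are reduced to sets of distinct species
#' identifiers: a species listed twice (or with stoichiometry 2) contributes
#' one element, as only distinct participants matter for reaction typing.
#'
#' @param id reaction identifier.
#' @param reactants,products,modifiers character vectors of species ids.
#' @param reversible logical; read from the file but ignored by
#'   classification.
#' @param math kinetic-law expression, or `NULL` when the reaction has none.
#' @param local_parameters identifiers of parameters local to the kinetic
#'   law (these shadow global identifiers within the law).
#' @return an object of class `sbml_reaction`.
#' @export
sbml_reaction <- function(id, reactants = character(), products = character(),
                          modifiers = character(), reversible = FALSE,
                          math = NULL, local_parameters = character()) {
  structure(list(id = id,
                 reactants = unique(reactants),
                 products = unique(products),
                 modifiers = unique(modifiers),
                 reversible = isTRUE(reversible),
                 math = math,
                 local_parameters = unique(local_parameters)),
            class = "sbml_reaction")
}

#' @export
print.sbml_model <- function(x, ...) {
  cat("SBML model '", x$model_id, "': ", length(x$species), " species, ",
      length(x$reactions), " reactions, ", length(x$function_defs),
      " function definition(s)\n", sep = "")
  invisible(x)
}

#' Read an SBML file
#'
#' Parses an SBML document (level 1, 2 or 3) into a [sbml_model()] record.
#' Level 1 kinetic laws given as infix `formula` attributes and level 2/3
#' MathML content markup are both supported.  Reactions lacking a kinetic
#' law are retained with `math = NULL` and reported with a warning; they are
#' excluded from all classification statistics.
#'
#' @param path path to an SBML XML file.
#' @return an `sbml_model`.
#' @export
read_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path)
  doc <- tryCatch(xml2::read_xml(path), error = function(err) {
    stop("failed to read SBML file '", path, "': ", conditionMessage(err),
         call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  if (local_name(doc) != "sbml") {
    stop("not an SBML document (root <", local_name(doc), ">): ", path)
  }
  model <- xml2::xml_find_first(doc, "./model")
  if (inherits(model, "xml_missing")) {
    stop("SBML document has no <model>: ", path)
  }
  model_id <- id_or_name(model)
  if (is.na(model_id)) model_id <- tools::file_path_sans_ext(basename(path))

  grab_ids <- function(xpath) {
    nodes <- xml2::xml_find_all(model, xpath)
    ids <- vapply(nodes, id_or_name, character(1L))
    ids[!is.na(ids)]
  }
  compartments <- grab_ids("./listOfCompartments/compartment")
  species <- grab_ids("./listOfSpecies/species | ./listOfSpecies/specie")
  parameters <- grab_ids("./listOfParameters/parameter")

  function_defs <- list()
  for (fd in xml2::xml_find_all(model, "./listOfFunctionDefinitions/functionDefinition")) {
    fid <- id_or_name(fd)
    lam <- xml2::xml_find_first(fd, "./math/lambda")
    if (inherits(lam, "xml_missing")) next
    kids <- xml2::xml_children(lam)
    kinds <- vapply(kids, local_name, character(1L))
    args <- vapply(kids[kinds == "bvar"], function(b) {
      trimws(xml2::xml_text(xml2::xml_find_first(b, "./ci")))
    }, character(1L))
    body_nodes <- kids[kinds != "bvar"]
    if (!length(body_nodes)) next
    body <- canon_expr(mathml_to_expr(body_nodes[[length(body_nodes)]]))
    function_defs[[fid]] <- list(args = as.character(args), body = body)
  }

  for (ignored in c("./listOfRules/*", "./listOfEvents/*")) {
    if (length(xml2::xml_find_all(model, ignored))) {
      message("note [", model_id, "]: rules/events present are ignored")
      break
    }
  }

  reactions <- list()
  for (rx in xml2::xml_find_all(model, "./listOfReactions/reaction")) {
    rid <- id_or_name(rx)
    sp_refs <- function(xpath, attr_names = c("species", "specie")) {
      nodes <- xml2::xml_find_all(rx, xpath)
      out <- vapply(nodes, function(nd) {
        for (a in attr_names) {
          v <- xml2::xml_attr(nd, a)
          if (!is.na(v) && nzchar(v)) return(v)
        }
        NA_character_
      }, character(1L))
      unique(out[!is.na(out)])
    }
    reactants <- sp_refs("./listOfReactants/speciesReference | ./listOfReactants/specieReference")
    products <- sp_refs("./listOfProducts/speciesReference | ./listOfProducts/specieReference")
    modifiers <- sp_refs("./listOfModifiers/modifierSpeciesReference")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- is.na(rev_attr) || tolower(rev_attr) %in% c("true", "1")

    kl <- xml2::xml_find_first(rx, "./kineticLaw")
    math <- NULL
    local_params <- character()
    if (!inherits(kl, "xml_missing")) {
      local_nodes <- xml2::xml_find_all(
        kl, "./listOfParameters/parameter | ./listOfLocalParameters/localParameter")
      local_params <- vapply(local_nodes, id_or_name, character(1L))
      local_params <- local_params[!is.na(local_params)]
      formula <- xml2::xml_attr(kl, "formula")
      if (!is.na(formula) && nzchar(formula)) {
        math <- tryCatch(parse_rate(formula), error = function(err) {
          warning("model '", model_id, "', reaction '", rid,
                  "': unparsable kinetic-law formula (", conditionMessage(err),
                  ")", call. = FALSE)
          NULL
        })
      } else {
        mnode <- xml2::xml_find_first(kl, "./math/*")
        if (!inherits(mnode, "xml_missing")) {
          math <- tryCatch(canon_expr(mathml_to_expr(mnode)),
                           error = function(err) {
            warning("model '", model_id, "', reaction '", rid,
                    "': unparsable kinetic-law MathML (",
                    conditionMessage(err), ")", call. = FALSE)
            NULL
          })
        }
      }
    }
    if (is.null(math)) {
      warning("model '", model_id, "', reaction '", rid,
              "': no kinetic law; excluded from classification",
              call. = FALSE)
    }
    reactions[[length(reactions) + 1L]] <-
      sbml_reaction(id = rid, reactants = reactants, products = products,
                    modifiers = modifiers, reversible = reversible,
                    math = math, local_parameters = local_params)
  }

  sbml_model(model_id = model_id, compartments = compartments,
             species = species, parameters = parameters,
             function_defs = function_defs, reactions = reactions)
}

#' Resolve the role of every identifier in a model
#'
#' Maps each identifier to one of `species`, `parameter`, `compartment`,
#' `function-name`, `time-like` or `other`.  Variable compartment sizes
#' count as compartments (hence never as species); an identifier declared
#' in two namespaces is an error.  Use [reaction_roles()] to overlay a
#' reaction's local parameters.
#'
#' @param model an `sbml_model`.
#' @return named character vector: identifier -> role.
#' @export
symbol_roles <- function(model) {
  roles <- c(
    stats::setNames(rep("species", length(model$species)), model$species),
    stats::setNames(rep("parameter", length(model$parameters)), model$parameters),
    stats::setNames(rep("compartment", length(model$compartments)), model$compartments),
    stats::setNames(rep("function-name", length(model$function_defs)),
                    names(model$function_defs))
  )
  dup <- names(roles)[duplicated(names(roles))]
  if (length(dup)) {
    stop("identifier(s) declared in more than one namespace in model '",
         model$model_id, "': ", paste(unique(dup), collapse = ", "))
  }
  c(roles,
    stats::setNames("time-like", TIME_SYMBOL),
    stats::setNames(rep("other", 3L), c(".sbml_avogadro", ".true", ".false")))
}

#' Roles in force inside one reaction's kinetic law
#'
#' Local parameters shadow any global identifier of the same name within
#' their reaction's kinetic law.
#'
#' @param model an `sbml_model`.
#' @param reaction an `sbml_reaction` belonging to `model`.
#' @return named character vector: identifier -> role.
#' @export
reaction_roles <- function(model, reaction) {
  roles <- symbol_roles(model)
  if (length(reaction$local_parameters)) {
    roles[reaction$local_parameters] <- "local-parameter"
  }
  roles
}

# ---- writing ----------------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a model as SBML Level 3 Version 1
#'
#' Emits a valid SBML L3V1 document that round-trips through [read_sbml()]
#' to an equivalent record (same reaction sets and roles; kinetic laws equal
#' numerically).  Output bytes are deterministic for a given record.
#'
#' @param model an `sbml_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  comp_ref <- if (length(model$compartments)) model$compartments[[1L]] else "default"
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\">"),
    sprintf("  <model id=\"%s\">", xml_escape(model$model_id))
  )
  if (length(model$function_defs)) {
    lines <- c(lines, "    <listOfFunctionDefinitions>")
    for (fid in names(model$function_defs)) {
      def <- model$function_defs[[fid]]
      lines <- c(lines,
        sprintf("      <functionDefinition id=\"%s\">", xml_escape(fid)),
        paste0("        ", lambda_element(def$args, def$body)),
        "      </functionDefinition>")
    }
    lines <- c(lines, "    </listOfFunctionDefinitions>")
  }
  comps <- if (length(model$compartments)) model$compartments else comp_ref
  lines <- c(lines, "    <listOfCompartments>",
    sprintf(paste0("      <compartment id=\"%s\" spatialDimensions=\"3\" ",
                   "size=\"1\" constant=\"true\"/>"), xml_escape(comps)),
    "    </listOfCompartments>")
  if (length(model$species)) {
    lines <- c(lines, "    <listOfSpecies>",
      sprintf(paste0("      <species id=\"%s\" compartment=\"%s\" ",
                     "initialConcentration=\"1\" hasOnlySubstanceUnits=\"false\" ",
                     "boundaryCondition=\"false\" constant=\"false\"/>"),
              xml_escape(model$species), xml_escape(comp_ref)),
      "    </listOfSpecies>")
  }
  if (length(model$parameters)) {
    lines <- c(lines, "    <listOfParameters>",
      sprintf("      <parameter id=\"%s\" value=\"1\" constant=\"true\"/>",
              xml_escape(model$parameters)),
      "    </listOfParameters>")
  }
  if (length(model$reactions)) {
    lines <- c(lines, "    <listOfReactions>")
    for (rx in model$reactions) {
      lines <- c(lines,
        sprintf("      <reaction id=\"%s\" reversible=\"%s\" fast=\"false\">",
                xml_escape(rx$id), tolower(as.character(rx$reversible))))
      ref_block <- function(tag, ids, mod = FALSE) {
        if (!length(ids)) return(character())
        el <- if (mod) "modifierSpeciesReference" else "speciesReference"
        extra <- if (mod) "" else " stoichiometry=\"1\" constant=\"true\""
        c(sprintf("        <%s>", tag),
          sprintf("          <%s species=\"%s\"%s/>", el, xml_escape(ids), extra),
          sprintf("        </%s>", tag))
      }
      lines <- c(lines,
        ref_block("listOfReactants", rx$reactants),
        ref_block("listOfProducts", rx$products),
        ref_block("listOfModifiers", rx$modifiers, mod = TRUE))
      if (!is.null(rx$math)) {
        lines <- c(lines, "        <kineticLaw>",
          paste0("          ", math_element(rx$math)))
        if (length(rx$local_parameters)) {
          lines <- c(lines, "          <listOfLocalParameters>",
            sprintf("            <localParameter id=\"%s\" value=\"1\"/>",
                    xml_escape(rx$local_parameters)),
            "          </listOfLocalParameters>")
        }
        lines <- c(lines, "        </kineticLaw>")
      }
      lines <- c(lines, "      </reaction>")
    }
    lines <- c(lines, "    </listOfReactions>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
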