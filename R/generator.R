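# Seeded generator of SBML corpora with known ground-truth kinetics and
# reaction types.  Each kinetics type is emitted from its canonical shape
# family (mass-action products, two-term differences, Michaelis-Menten and
# Hill fractions, an irreducible nested-fraction/power shape for NA), with
# fresh identifiers per reaction and optional structure-preserving
# obfuscations that classification must see through: wrapping the law in a
# function definition, multiplying by a compartment, writing divisions as
# pow(x, -1), and shuffling factor order.

default_k_probs <- function() {
  c(ZERO = 0.05, UNDR = 0.40, UNMO = 0.10, BIDR = 0.08, BIMO = 0.05,
    MM = 0.08, MMCAT = 0.07, HILL = 0.05, FR = 0.08, "NA" = 0.04)
}

default_r_probs <- function() {
  p <- stats::setNames(rep(0, 16L), r_type_levels())
  p[c("R=1,P=1", "R=2,P=1", "R=1,P=2", "R=2,P=2", "R=1,P=0", "R=0,P=1",
      "R=2,P=0", "R=0,P=2", "R=>2,P=>2")] <-
    c(0.30, 0.20, 0.15, 0.10, 0.10, 0.10, 0.02, 0.02, 0.01)
  p
}

#' Configuration for the synthetic-corpus generator
#'
#' @param n_models number of models to generate.
#' @param reactions_per_model integer range `c(lo, hi)`; each model's
#'   reaction count is drawn uniformly from it.
#' @param k_type_probs named probabilities over the ten kinetics types
#'   (must sum to 1).  The default mimics a curated-repository profile:
#'   uni-directional mass action dominant, a few percent unclassifiable.
#' @param r_type_probs named probabilities over the sixteen reaction types.
#'   Reaction types infeasible for a drawn kinetics type (a mass-action or
#'   Michaelis-Menten law needs at least one reactant; a bi-directional law
#'   needs a product too) are excluded and the remainder renormalized.
#' @param seed integer seed; fully determines the output bytes.
#' @param p_function_def,p_compartment,p_pow_division probabilities of
#'   wrapping a law in a function definition, multiplying it by the model
#'   compartment, and rewriting divisions as `pow(x, -1)`.
#' @param shuffle logical; randomly permute the factor order of products
#'   (difference terms keep their orientation).
#' @return a `corpus_config` list, validated.
#' @export
corpus_config <- function(n_models = 10L, reactions_per_model = c(5L, 10L),
                          k_type_probs = default_k_probs(),
                          r_type_probs = default_r_probs(),
                          seed = 1L,
                          p_function_def = 0, p_compartment = 0,
                          p_pow_division = 0, shuffle = FALSE) {
  check_probs <- function(p, levels, what) {
    if (is.null(names(p)) || !all(names(p) %in% levels)) {
      stop("config error in ", what, ": names must be in {",
           paste(levels, collapse = ", "), "}")
    }
    full <- stats::setNames(rep(0, length(levels)), levels)
    full[names(p)] <- p
    if (any(full < 0) || abs(sum(full) - 1) > 1e-9) {
      stop("config error in ", what, ": probabilities must be >= 0 and sum to 1")
    }
    full
  }
  cfg <- list(
    n_models = as.integer(n_models),
    reactions_per_model = as.integer(reactions_per_model),
    k_type_probs = check_probs(k_type_probs, k_type_levels(), "k_type_probs"),
    r_type_probs = check_probs(r_type_probs, r_type_levels(), "r_type_probs"),
    seed = as.integer(seed),
    p_function_def = p_function_def,
    p_compartment = p_compartment,
    p_pow_division = p_pow_division,
    shuffle = isTRUE(shuffle))
  if (cfg$n_models < 0L) stop("config error in n_models: must be >= 0")
  if (length(cfg$reactions_per_model) == 1L) {
    cfg$reactions_per_model <- rep(cfg$reactions_per_model, 2L)
  }
  # every k type must have at least one feasible r bin with positive mass
  for (k in names(cfg$k_type_probs)[cfg$k_type_probs > 0]) {
    feas <- feasible_r_types(k)
    if (sum(cfg$r_type_probs[feas]) <= 0) {
      stop("config error: no reaction type with positive probability is ",
           "feasible for kinetics type ", k)
    }
  }
  structure(cfg, class = "corpus_config")
}

# R bins compatible with a kinetics type: mass-action style laws must have
# their species be the (nonempty) reactant set; MM shapes need a reactant;
# BIDR needs both sides nonempty.
feasible_r_types <- function(k_type) {
  lv <- r_type_levels()
  rbin <- sub("^R=([^,]+),.*$", "\\1", lv)
  pbin <- sub("^.*,P=(.+)$", "\\1", lv)
  keep <- switch(k_type,
    UNDR = , MM = , MMCAT = rbin != "0",
    BIDR = rbin != "0" & pbin != "0",
    rep(TRUE, length(lv)))
  lv[keep]
}

bin_count <- function(bin) switch(bin, "0" = 0L, "1" = 1L, "2" = 2L, ">2" = 3L)

# Identifier factory: fresh species/parameter names per model.
new_idgen <- function() {
  env <- new.env(parent = emptyenv())
  env$s <- 0L
  env$p <- 0L
  list(
    species = function(n = 1L) {
      ids <- sprintf("S%d", env$s + seq_len(n)); env$s <- env$s + n; ids
    },
    param = function(n = 1L) {
      ids <- sprintf("k%d", env$p + seq_len(n)); env$p <- env$p + n; ids
    })
}

prod_expr <- function(ids) mk_mul_list(lapply(ids, as.name))

#' Emit one reaction with known ground-truth types
#'
#' Builds a reaction of the requested reaction type whose kinetic law is
#' drawn from the canonical shape family of the requested kinetics type.
#' Consumes the current R random-number stream.
#'
#' @param k_type one of the ten kinetics types.
#' @param r_type one of the sixteen reaction types, e.g. `"R=2,P=1"`.
#' @param idgen identifier factory from `new_idgen()` (one per model).
#' @param rid reaction identifier.
#' @return list with `reaction` (an `sbml_reaction`), `species`,
#'   `parameters` (identifiers to declare in the model).
#' @section Errors:
#' An infeasible pair (for example a uni-directional mass-action law with
#' zero reactants) raises an error naming the violated constraint.
#' @export
emit_reaction <- function(k_type, r_type, idgen = new_idgen(), rid = "re1") {
  if (!(k_type %in% k_type_levels())) stop("unknown kinetics type: ", k_type)
  if (!(r_type %in% r_type_levels())) stop("unknown reaction type: ", r_type)
  if (!(r_type %in% feasible_r_types(k_type))) {
    stop("infeasible pair: kinetics type ", k_type, " requires ",
         if (k_type == "BIDR") "at least one reactant and one product"
         else "at least one reactant", ", got ", r_type)
  }
  rbin <- sub("^R=([^,]+),.*$", "\\1", r_type)
  pbin <- sub("^.*,P=(.+)$", "\\1", r_type)
  reactants <- idgen$species(bin_count(rbin))
  products <- idgen$species(bin_count(pbin))
  modifiers <- character()
  extra_params <- character()
  mod <- function() {
    id <- idgen$species(1L)
    modifiers <<- c(modifiers, id)
    id
  }
  par <- function(n = 1L) {
    ids <- idgen$param(n)
    extra_params <<- c(extra_params, ids)
    ids
  }
  law <- switch(k_type,
    ZERO = as.name(par()),
    UNDR = mk_mul(as.name(par()), prod_expr(reactants)),
    UNMO = {
      m <- mod()
      base <- mk_mul(as.name(par()), as.name(m))
      if (length(reactants) && stats::runif(1) < 0.5) {
        mk_mul(base, prod_expr(reactants))
      } else base
    },
    BIDR = {
      ks <- par(2L)
      mk_sub(mk_mul(as.name(ks[1L]), prod_expr(reactants)),
             mk_mul(as.name(ks[2L]), prod_expr(products)))
    },
    BIMO = {
      ks <- par(2L)
      if (length(reactants) && length(products) && stats::runif(1) < 0.5) {
        m <- mod()
        mk_mul(as.name(m),
               mk_sub(mk_mul(as.name(ks[1L]), prod_expr(reactants)),
                      mk_mul(as.name(ks[2L]), prod_expr(products))))
      } else {
        mk_sub(mk_mul(as.name(ks[1L]), as.name(mod())),
               mk_mul(as.name(ks[2L]), as.name(mod())))
      }
    },
    MM = {
      ks <- par(2L)  # Vmax, Km
      S <- as.name(reactants[1L])
      mk_div(mk_mul(as.name(ks[1L]), S), mk_add(as.name(ks[2L]), S))
    },
    MMCAT = {
      ks <- par(2L)
      S <- as.name(reactants[1L])
      E <- as.name(mod())
      mk_div(mk_mul(mk_mul(as.name(ks[1L]), E), S), mk_add(as.name(ks[2L]), S))
    },
    HILL = {
      ks <- par(2L)  # Vmax, K
      S <- as.name(if (length(reactants)) reactants[1L] else mod())
      hexp <- if (stats::runif(1) < 0.5) as.name(par()) else
        sample(2:4, 1L)
      mk_div(mk_mul(as.name(ks[1L]), mk_pow(S, hexp)),
             mk_add(mk_pow(as.name(ks[2L]), hexp), mk_pow(S, hexp)))
    },
    FR = {
      if (stats::runif(1) < 0.5) {
        # fraction with a second species in the denominator
        ks <- par(2L)
        S <- as.name(if (length(reactants)) reactants[1L] else mod())
        M2 <- as.name(mod())
        mk_div(mk_mul(as.name(ks[1L]), S),
               mk_add(mk_add(as.name(ks[2L]), S), M2))
      } else {
        # (1 - M)*V/(K - M + 1): fractional, neither MM nor Hill
        ks <- par(2L)
        M <- as.name(mod())
        mk_div(mk_mul(mk_sub(1, M), as.name(ks[1L])),
               mk_add(mk_sub(as.name(ks[2L]), M), 1))
      }
    },
    "NA" = {
      if (stats::runif(1) < 0.5) {
        # nested non-matching fraction/power structure
        ks <- par(3L)  # p1, p2, np
        M1 <- as.name(mod()); M2 <- as.name(mod())
        inner <- mk_pow(mk_sub(1, M1), as.name(ks[3L]))
        mk_mul(mk_add(mk_mul(mk_sub(1, inner), as.name(ks[1L])),
                      mk_mul(inner, as.name(ks[2L]))), M2)
      } else {
        # piecewise law: not analyzable
        ks <- par(2L)
        M1 <- as.name(mod())
        as.call(list(as.name("piecewise"),
                     mk_mul(as.name(ks[1L]), M1),
                     call("lt", as.name(TIME_SYMBOL), 5),
                     mk_mul(as.name(ks[2L]), M1)))
      }
    })
  list(reaction = sbml_reaction(id = rid, reactants = reactants,
                                products = products, modifiers = modifiers,
                                math = canon_expr(law)),
       species = c(reactants, products, modifiers),
       parameters = extra_params)
}

# ---- obfuscations -----------------------------------------------------------

rewrite_div_as_pow <- function(e) {
  if (is_num(e) || is.name(e)) return(e)
  if (!is.call(e)) return(e)
  args <- lapply(as.list(e)[-1L], rewrite_div_as_pow)
  if (call_op(e) == "/" && length(e) == 3L) {
    return(call("*", args[[1L]], call("^", args[[2L]], -1)))
  }
  as.call(c(e[[1L]], args))
}

shuffle_factors <- function(e) {
  if (is_num(e) || is.name(e)) return(e)
  if (!is.call(e)) return(e)
  op <- call_op(e)
  if (op == "*") {
    flat <- function(x) {
      if (is.call(x) && call_op(x) == "*" && length(x) == 3L) {
        c(flat(x[[2L]]), flat(x[[3L]]))
      } else list(x)
    }
    parts <- lapply(flat(e), shuffle_factors)
    return(mk_mul_list(parts[sample.int(length(parts))]))
  }
  args <- lapply(as.list(e)[-1L], shuffle_factors)
  if (op == "+" && length(e) == 3L && stats::runif(1) < 0.5) {
    return(call("+", args[[2L]], args[[1L]]))
  }
  as.call(c(e[[1L]], args))
}

#' Generate a labelled synthetic SBML corpus
#'
#' Writes `n_models` SBML Level 3 files into `dir` together with a
#' `labels.csv` ground-truth table (model id, reaction id, true kinetics
#' type, true reaction type).  Kinetics types are drawn from the configured
#' distribution; reaction types from the configured distribution restricted
#' to the bins feasible for the drawn kinetics type.  Output is
#' byte-identical across runs with the same configuration.
#'
#' @param config a [corpus_config()].
#' @param dir output directory (created if needed); when `NULL`, models are
#'   returned in memory and nothing is written.
#' @return invisibly, a list with `labels` (data frame) and `models`
#'   (list of `sbml_model`).
#' @export
generate_corpus <- function(config, dir = NULL) {
  stopifnot(inherits(config, "corpus_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  models <- vector("list", config$n_models)
  labels <- list()
  for (i in seq_len(config$n_models)) {
    mid <- sprintf("synthetic_%04d", i)
    idgen <- new_idgen()
    n_rx <- if (config$reactions_per_model[1L] == config$reactions_per_model[2L])
      config$reactions_per_model[1L] else
      sample(config$reactions_per_model[1L]:config$reactions_per_model[2L], 1L)
    species <- character()
    params <- character()
    fundefs <- list()
    reactions <- vector("list", n_rx)
    comp <- "comp"
    for (j in seq_len(n_rx)) {
      k <- sample(names(config$k_type_probs), 1L, prob = config$k_type_probs)
      feas <- feasible_r_types(k)
      rp <- config$r_type_probs[feas]
      r <- sample(names(rp), 1L, prob = rp / sum(rp))
      em <- emit_reaction(k, r, idgen, rid = sprintf("re%d", j))
      rx <- em$reaction
      law <- rx$math
      if (stats::runif(1) < config$p_compartment) {
        law <- mk_mul(as.name(comp), law)
      }
      if (config$shuffle) law <- shuffle_factors(law)
      if (stats::runif(1) < config$p_pow_division) law <- rewrite_div_as_pow(law)
      if (is_analyzable(law) && stats::runif(1) < config$p_function_def) {
        fid <- sprintf("fd_%d", j)
        vars <- sort(all.vars(law))
        formals <- sprintf("x%d", seq_along(vars))
        fundefs[[fid]] <- list(
          args = formals,
          body = substitute_symbols(law, stats::setNames(formals, vars)))
        law <- as.call(c(as.name(fid), lapply(vars, as.name)))
      }
      rx$math <- law
      reactions[[j]] <- rx
      species <- c(species, em$species)
      params <- c(params, em$parameters)
      labels[[length(labels) + 1L]] <-
        data.frame(model_id = mid, reaction_id = rx$id,
                   k_type = k, r_type = r, stringsAsFactors = FALSE)
    }
    models[[i]] <- sbml_model(model_id = mid, compartments = comp,
                              species = unique(species),
                              parameters = unique(params),
                              function_defs = fundefs,
                              reactions = reactions)
  }
  labels <- if (length(labels)) do.call(rbind, labels) else
    data.frame(model_id = character(), reaction_id = character(),
               k_type = character(), r_type = character())
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (m in models) {
      write_sbml(m, file.path(dir, paste0(m$model_id, ".xml")))
    }
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(list(labels = labels, models = models))
}
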