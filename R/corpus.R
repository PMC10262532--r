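# Corpus-level classification: read every SBML file, classify every
# reaction, and return a classed profile object that the statistics and
# reporting layers consume.

#' Classify every reaction in a corpus of SBML models
#'
#' The workhorse of the package.  Accepts a directory of SBML files, a
#' character vector of file paths, or a list of in-memory [sbml_model()]
#' records.  Each reaction with a kinetic law is assigned a kinetics type
#' (one of the ten mutually exclusive K types) and a reaction type (one of
#' the sixteen distinct-reactant/product bins).  Reactions without a
#' kinetic law are tallied separately and excluded from all distributions;
#' unreadable files are logged and skipped rather than aborting the run.
#'
#' @param x directory path, vector of SBML file paths, or list of
#'   `sbml_model` objects.
#' @param pattern filename pattern used when `x` is a directory.
#' @return an object of class `kinetics_profile` with components
#'   \describe{
#'     \item{results}{per-reaction data frame (model id, reaction id,
#'       renderings, `k_type`, `r_type`, properties a-h).}
#'     \item{models}{per-model data frame with reaction counts.}
#'     \item{manifest}{run accounting: models read/failed, reactions
#'       classified/skipped, package version, timestamp.}
#'   }
#' @seealso [distribution()], [k_by_r_table()], [run_classify()]
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' write_kinetics_examples(dir)
#' prof <- classify_corpus(dir)
#' print(prof)
#' @export
classify_corpus <- function(x, pattern = "\\.(xml|sbml)$") {
  failures <- character()
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    x <- sort(list.files(x, pattern = pattern, full.names = TRUE))
  }
  if (is.character(x)) {
    models <- list()
    for (path in x) {
      m <- tryCatch(read_sbml(path), error = function(err) {
        warning("skipping '", path, "': ", conditionMessage(err), call. = FALSE)
        NULL
      })
      if (is.null(m)) failures <- c(failures, path) else {
        models[[length(models) + 1L]] <- m
      }
    }
  } else if (is.list(x)) {
    models <- x
    stopifnot(all(vapply(models, inherits, logical(1L), "sbml_model")))
  } else {
    stop("x must be a directory, file paths, or a list of sbml_model objects")
  }

  rows <- list()
  model_rows <- list()
  n_no_law <- 0L
  for (m in models) {
    defs <- m$function_defs
    n_cls <- 0L
    n_missing <- 0L
    for (rx in m$reactions) {
      if (is.null(rx$math)) {
        n_missing <- n_missing + 1L
        next
      }
      roles <- reaction_roles(m, rx)
      rows[[length(rows) + 1L]] <-
        classify_reaction(rx, roles, defs, model_id = m$model_id)
      n_cls <- n_cls + 1L
    }
    n_no_law <- n_no_law + n_missing
    model_rows[[length(model_rows) + 1L]] <-
      data.frame(model_id = m$model_id,
                 n_reactions = length(m$reactions),
                 n_classified = n_cls,
                 n_no_law = n_missing,
                 stringsAsFactors = FALSE)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    classify_reaction(sbml_reaction("x", math = 1), character())[0L, ]
  model_df <- if (length(model_rows)) do.call(rbind, model_rows) else
    data.frame(model_id = character(), n_reactions = integer(),
               n_classified = integer(), n_no_law = integer())
  manifest <- list(
    models_read = length(models),
    models_failed = length(failures),
    failed_files = failures,
    reactions_classified = nrow(results),
    reactions_no_law = n_no_law,
    tool_version = as.character(utils::packageVersion("kinclass")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(results = results, models = model_df, manifest = manifest),
            class = "kinetics_profile")
}

#' @export
print.kinetics_profile <- function(x, ...) {
  cat("Kinetics classification profile\n")
  cat("  models:    ", x$manifest$models_read,
      if (x$manifest$models_failed)
        sprintf(" (%d failed to parse)", x$manifest$models_failed) else "",
      "\n", sep = "")
  cat("  reactions: ", x$manifest$reactions_classified, " classified, ",
      x$manifest$reactions_no_law, " without a kinetic law\n", sep = "")
  if (nrow(x$results)) {
    tab <- distribution(x, axis = "K")
    top <- query_top(tab, 3L)
    cat("  top K types: ", paste(top, collapse = ", "), "\n", sep = "")
    na_pct <- 100 * tab$pooled[tab$category == "NA"]
    cat(sprintf("  unclassified (NA): %.2f%%\n", na_pct))
  }
  invisible(x)
}

#' @export
summary.kinetics_profile <- function(object, ...) {
  out <- list(k = distribution(object, "K"),
              r = distribution(object, "R"),
              manifest = object$manifest)
  class(out) <- "summary.kinetics_profile"
  out
}

#' @export
print.summary.kinetics_profile <- function(x, ...) {
  cat("K-type distribution (pooled / per-model mean +- SE):\n")
  print(as.data.frame(x$k), digits = 4)
  cat("\nR-type distribution:\n")
  print(as.data.frame(x$r), digits = 4)
  invisible(x)
}

#' @export
plot.kinetics_profile <- function(x, axis = c("K", "R"), ...) {
  axis <- match.arg(axis)
  plot(distribution(x, axis), ...)
}

#' Per-model K-type fraction table
#'
#' One row per model: model id, number of classified reactions, and the
#' fraction of each of the ten kinetics types within that model.
#'
#' @param profile a `kinetics_profile`.
#' @return a data frame.
#' @export
per_model_table <- function(profile) {
  res <- profile$results
  ks <- k_type_levels()
  split_res <- split(res$k_type, res$model_id)
  rows <- lapply(names(split_res), function(mid) {
    v <- split_res[[mid]]
    fr <- as.vector(table(factor(v, levels = ks))) / length(v)
    df <- data.frame(model_id = mid, n_reactions = length(v),
                     stringsAsFactors = FALSE)
    df[ks] <- as.list(fr)
    df
  })
  if (!length(rows)) {
    df <- data.frame(model_id = character(), n_reactions = integer())
    df[ks] <- replicate(length(ks), numeric(), simplify = FALSE)
    return(df)
  }
  do.call(rbind, rows)
}
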