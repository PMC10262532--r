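# Report drivers behind the command-line interface: classify a corpus into
# CSV/JSON reports (and optional plots), generate a synthetic corpus from a
# JSON config, and compare two distribution files.

usage_error <- function(...) {
  stop(errorCondition(paste0(...),
       class = c("kinclass_usage_error", "error", "condition")))
}

total_failure <- function(...) {
  stop(errorCondition(paste0(...),
       class = c("kinclass_total_failure", "error", "condition")))
}

#' Classify a corpus directory and write all reports
#'
#' Reads every SBML file under `input`, classifies all reactions, and
#' writes to `output`: `per_reaction.csv` (model id, reaction id, reaction,
#' kinetic law, kinetics type, reaction type), `per_model.csv` (model id,
#' reaction count, the ten kinetics-type fractions),
#' `distribution_k.json`, `distribution_r.json` (and
#' `distribution_kxr.json` when `axis = "kxr"`), a `manifest.json` run
#' record, and optionally bar-chart plots.  Data outputs are
#' byte-deterministic for identical inputs; the manifest carries a
#' timestamp.  Individual unreadable files are logged and skipped; the run
#' fails only when no file can be read.
#'
#' @param input directory containing SBML files.
#' @param output output directory (created if needed).
#' @param axis `"k"`, `"r"` or `"kxr"`: which distribution JSONs to write
#'   (the K and R axes are always written).
#' @param plots logical; also render PNG bar charts.
#' @return the run manifest, invisibly.
#' @export
run_classify <- function(input, output, axis = c("k", "r", "kxr"),
                         plots = FALSE) {
  axis <- match.arg(axis)
  if (!is.character(input) || !dir.exists(input)) {
    usage_error("input directory does not exist: ", input)
  }
  files <- sort(list.files(input, pattern = "\\.(xml|sbml)$", full.names = TRUE))
  if (!length(files)) usage_error("no SBML files found under ", input)
  prof <- classify_corpus(files)
  if (prof$manifest$models_read == 0L) {
    total_failure("every input file failed to parse")
  }
  if (!dir.exists(output)) dir.create(output, recursive = TRUE)
  res <- prof$results[, c("model_id", "reaction_id", "reaction",
                          "kinetic_law", "k_type", "r_type")]
  utils::write.csv(res, file.path(output, "per_reaction.csv"),
                   row.names = FALSE)
  utils::write.csv(per_model_table(prof), file.path(output, "per_model.csv"),
                   row.names = FALSE)
  if (nrow(prof$results)) {
    write_distribution_json(distribution(prof, "K"),
                            file.path(output, "distribution_k.json"))
    write_distribution_json(distribution(prof, "R"),
                            file.path(output, "distribution_r.json"))
    if (axis == "kxr") {
      write_distribution_json(distribution(prof, "KxR"),
                              file.path(output, "distribution_kxr.json"))
    }
    if (plots) render_plots(prof, output)
  }
  manifest <- c(prof$manifest, list(input = normalizePath(input),
                                    files_seen = length(files)))
  jsonlite::write_json(manifest, file.path(output, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Render distribution plots for a classified corpus
#'
#' Writes `k_distribution.png` and `r_distribution.png` (pooled vs
#' per-model-mean bars with standard-error whiskers) and `k_by_r.png`
#' (a 4x4 panel of conditional kinetics-type distributions, one per
#' reaction type).  Plotting failures degrade to warnings.
#'
#' @param profile a `kinetics_profile`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
render_plots <- function(profile, dir) {
  if (!nrow(profile$results)) {
    warning("no classified reactions; no plots rendered")
    return(invisible(character()))
  }
  paths <- character()
  safe_png <- function(name, width, height, fun) {
    path <- file.path(dir, name)
    ok <- tryCatch({
      grDevices::png(path, width = width, height = height)
      on.exit(grDevices::dev.off(), add = TRUE)
      fun()
      TRUE
    }, error = function(err) {
      warning("plot '", name, "' failed: ", conditionMessage(err),
              call. = FALSE)
      FALSE
    })
    if (ok) paths <<- c(paths, path)
  }
  safe_png("k_distribution.png", 900, 500, function() {
    plot(distribution(profile, "K"))
  })
  safe_png("r_distribution.png", 900, 500, function() {
    plot(distribution(profile, "R"))
  })
  safe_png("k_by_r.png", 1600, 1200, function() {
    tabs <- k_by_r_table(profile)
    old <- graphics::par(mfrow = c(4L, 4L), mar = c(5, 3, 2, 1))
    on.exit(graphics::par(old), add = TRUE)
    for (r in r_type_levels()) {
      tab <- tabs$conditional[[r]]
      share <- tabs$shares$pooled_share[tabs$shares$r_type == r]
      if (is.null(tab)) {
        graphics::plot.new()
        graphics::title(main = sprintf("%s (empty)", r))
      } else {
        h <- rbind(tab$pooled, tab$per_model_mean)
        colnames(h) <- tab$category
        graphics::barplot(h, beside = TRUE, las = 2,
                          col = c("steelblue", "darkorange"),
                          main = sprintf("%s (%.1f%%)", r, 100 * share))
      }
    }
  })
  invisible(paths)
}

#' Generate a synthetic corpus from a JSON configuration file
#'
#' The configuration mirrors [corpus_config()]: fields `n_models`,
#' `reactions_per_model`, `k_type_probs`, `r_type_probs`, `seed`,
#' `p_function_def`, `p_compartment`, `p_pow_division`, `shuffle`.
#' Missing fields take the defaults.
#'
#' @param config_file path to a JSON config.
#' @param out_dir output directory for the SBML files and `labels.csv`.
#' @return invisibly, the ground-truth label table.
#' @export
run_generate <- function(config_file, out_dir) {
  if (!file.exists(config_file)) {
    usage_error("config file not found: ", config_file)
  }
  raw <- tryCatch(jsonlite::read_json(config_file, simplifyVector = TRUE),
                  error = function(err) {
    usage_error("cannot parse config '", config_file, "': ",
                conditionMessage(err))
  })
  args <- raw[intersect(names(raw), names(formals(corpus_config)))]
  for (f in c("k_type_probs", "r_type_probs")) {
    if (!is.null(args[[f]])) args[[f]] <- unlist(args[[f]])
  }
  cfg <- do.call(corpus_config, args)
  out <- generate_corpus(cfg, out_dir)
  invisible(out$labels)
}

#' Compare two distribution JSON files
#'
#' @param a_json,b_json paths to files written by
#'   [write_distribution_json()]; both must be on the same axis.
#' @param quiet suppress printing.
#' @return a `kinetics_comparison`, invisibly.
#' @export
run_compare <- function(a_json, b_json, quiet = FALSE) {
  a <- read_distribution_json(a_json)
  b <- read_distribution_json(b_json)
  cmp <- compare_corpora(a, b)
  if (!quiet) print(cmp)
  invisible(cmp)
}
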