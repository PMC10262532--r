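# Distribution statistics: pooled over all reactions, and per-model means
# with standard errors across models.

axis_levels <- function(axis) {
  switch(axis,
    K = k_type_levels(),
    R = r_type_levels(),
    KxR = kr_type_levels(),
    stop("axis must be one of 'K', 'R', 'KxR'"))
}

axis_values <- function(results, axis) {
  switch(axis,
    K = results$k_type,
    R = results$r_type,
    KxR = paste(results$r_type, results$k_type, sep = "|"))
}

new_distribution <- function(df, axis, n_models, n_reactions,
                             single_model = FALSE) {
  structure(df, axis = axis, n_models = n_models, n_reactions = n_reactions,
            single_model = single_model,
            class = c("kinetics_distribution", "data.frame"))
}

#' Category distribution of a classified corpus
#'
#' Computes, for every category of the chosen axis (all ten K types, all
#' sixteen R types, or all 160 K-by-R cells, zeros included), two
#' estimates: the pooled fraction (reactions in the category divided by all
#' classified reactions, every model weighted by its size) and the
#' per-model mean (the average over models of within-model fractions) with
#' its standard error across models (sample standard deviation over models
#' divided by the square root of the number of models).  Models with zero
#' classified reactions are excluded from the per-model average.
#'
#' @param x a `kinetics_profile` (or its per-reaction results data frame).
#' @param axis `"K"`, `"R"` or `"KxR"`.
#' @return a `kinetics_distribution` data frame with columns `category`,
#'   `pooled`, `per_model_mean`, `per_model_se`; attributes `axis`,
#'   `n_models`, `n_reactions` and `single_model` (standard errors are
#'   reported as 0 with this flag when only one model is present).
#' @export
distribution <- function(x, axis = c("K", "R", "KxR")) {
  axis <- match.arg(axis)
  results <- if (inherits(x, "kinetics_profile")) x$results else x
  if (!nrow(results)) stop("no classified reactions: distribution undefined")
  lv <- axis_levels(axis)
  vals <- factor(axis_values(results, axis), levels = lv)
  pooled <- as.vector(table(vals)) / length(vals)
  frac_by_model <- t(vapply(split(vals, results$model_id), function(v) {
    as.vector(table(v)) / length(v)
  }, numeric(length(lv))))
  m <- nrow(frac_by_model)
  means <- colMeans(frac_by_model)
  se <- if (m > 1L) apply(frac_by_model, 2L, stats::sd) / sqrt(m) else
    rep(0, length(lv))
  new_distribution(
    data.frame(category = lv, pooled = pooled, per_model_mean = means,
               per_model_se = se, row.names = NULL, stringsAsFactors = FALSE),
    axis = axis, n_models = m, n_reactions = length(vals),
    single_model = m == 1L)
}

#' @export
print.kinetics_distribution <- function(x, ...) {
  cat(sprintf("%s-type distribution: %d reactions in %d model(s)\n",
              attr(x, "axis"), attr(x, "n_reactions"), attr(x, "n_models")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.kinetics_distribution <- function(x, main = NULL, ...) {
  h <- rbind(pooled = x$pooled, per_model = x$per_model_mean)
  colnames(h) <- x$category
  mid <- graphics::barplot(h, beside = TRUE, las = 2,
                           col = c("steelblue", "darkorange"),
                           ylab = "fraction of reactions",
                           main = main %||% paste0(attr(x, "axis"),
                                                   "-type distribution"),
                           legend.text = c("all reactions pooled",
                                           "per-model mean"),
                           args.legend = list(bty = "n"), ...)
  up <- x$per_model_mean + x$per_model_se
  keep <- x$per_model_se > 0
  if (any(keep)) {
    graphics::arrows(mid[2L, keep], x$per_model_mean[keep], mid[2L, keep],
                     up[keep], angle = 90, length = 0.03)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Conditional K-type distributions per reaction type
#'
#' For each of the sixteen reaction types: the conditional kinetics-type
#' distribution among the reactions of that type (pooled and per-model
#' variants), together with the reaction type's share of all reactions and
#' its mean share per model.
#'
#' @param x a `kinetics_profile`.
#' @return a list with `shares` (data frame over the 16 R types with
#'   `pooled_share` and `per_model_share`) and `conditional` (named list of
#'   `kinetics_distribution` tables on the K axis; `NULL` for empty cells).
#' @export
k_by_r_table <- function(x) {
  results <- if (inherits(x, "kinetics_profile")) x$results else x
  if (!nrow(results)) stop("no classified reactions")
  rshare <- distribution(results, "R")
  conditional <- stats::setNames(vector("list", length(r_type_levels())),
                                 r_type_levels())
  for (r in r_type_levels()) {
    sub <- results[results$r_type == r, , drop = FALSE]
    if (nrow(sub)) conditional[[r]] <- distribution(sub, "K")
  }
  list(shares = data.frame(r_type = rshare$category,
                           pooled_share = rshare$pooled,
                           per_model_share = rshare$per_model_mean,
                           per_model_se = rshare$per_model_se,
                           stringsAsFactors = FALSE),
       conditional = conditional)
}

#' Compare two distributions of the same axis
#'
#' @param a,b `kinetics_distribution` tables on the same axis.
#' @return a `kinetics_comparison` data frame with side-by-side fractions
#'   and per-category absolute differences; the top category of each corpus
#'   is carried in attributes `top_a` and `top_b`.
#' @export
compare_corpora <- function(a, b) {
  if (!identical(attr(a, "axis"), attr(b, "axis")) ||
      !identical(a$category, b$category)) {
    stop("cannot compare distributions on different axes/categories")
  }
  out <- data.frame(category = a$category,
                    pooled_a = a$pooled, pooled_b = b$pooled,
                    abs_difference = abs(a$pooled - b$pooled),
                    stringsAsFactors = FALSE)
  structure(out, axis = attr(a, "axis"),
            top_a = query_top(a, 1L), top_b = query_top(b, 1L),
            class = c("kinetics_comparison", "data.frame"))
}

#' @export
print.kinetics_comparison <- function(x, ...) {
  cat(sprintf("Comparison on the %s axis\n", attr(x, "axis")))
  cat("  top category, corpus A: ", attr(x, "top_a"), "\n", sep = "")
  cat("  top category, corpus B: ", attr(x, "top_b"), "\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Top categories of a distribution
#'
#' Categories sorted by pooled fraction, descending; ties broken by the
#' canonical category order.
#'
#' @param table a `kinetics_distribution`.
#' @param n how many categories to return (capped at the category count).
#' @return character vector of category labels.
#' @export
query_top <- function(table, n = 1L) {
  ord <- order(-table$pooled, seq_len(nrow(table)))
  table$category[ord][seq_len(min(n, nrow(table)))]
}

#' Write a distribution table as JSON
#'
#' @param table a `kinetics_distribution`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_distribution_json <- function(table, path) {
  payload <- list(axis = attr(table, "axis"),
                  n_models = attr(table, "n_models"),
                  n_reactions = attr(table, "n_reactions"),
                  categories = data.frame(category = table$category,
                                          pooled = table$pooled,
                                          mean = table$per_model_mean,
                                          se = table$per_model_se))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a distribution table written by [write_distribution_json()]
#'
#' @param path JSON file path.
#' @return a `kinetics_distribution`.
#' @export
read_distribution_json <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(err) {
    stop("cannot parse distribution JSON '", path, "': ",
         conditionMessage(err), call. = FALSE)
  })
  if (is.null(obj$axis) || is.null(obj$categories)) {
    stop("'", path, "' is not a distribution JSON (missing axis/categories)")
  }
  df <- data.frame(category = obj$categories$category,
                   pooled = obj$categories$pooled,
                   per_model_mean = obj$categories$mean,
                   per_model_se = obj$categories$se,
                   stringsAsFactors = FALSE)
  new_distribution(df, axis = obj$axis, n_models = obj$n_models,
                   n_reactions = obj$n_reactions)
}
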