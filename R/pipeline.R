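# End-to-end orchestration: read (or simulate) -> filter -> assemble ->
# fit -> categorize -> compare -> report. One run configuration drives
# everything; report.json is the single provenance artifact with the full
# config, per-stage counts and conservation checks.

#' Read and validate a run configuration
#'
#' YAML (or JSON) file with blocks: either \code{input} (paths
#' \code{milkings}, \code{repro}) or \code{simulate} (either a fixture
#' \code{name} or \code{\link{sim_config}} fields); optional
#' \code{filters} (\code{min_dim}, \code{min_dim_rule}), \code{fit}
#' (\code{\link{milkbot_control}} fields), \code{categories}
#' (\code{scheme}: \code{"fixed"} or \code{"quantiles"}; optional
#' \code{probs}), \code{model} (\code{traits}, \code{df_method},
#' \code{adjust}), and \code{seed}.
#'
#' @param path configuration file.
#' @return validated list of class \code{"run_config"}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a configuration list (as parsed from the file).
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$simulate))
    stop("config error: one of 'input' or 'simulate' is required", call. = FALSE)
  if (!is.null(cfg$input) && !is.null(cfg$simulate))
    stop("config error: 'input' and 'simulate' are mutually exclusive",
         call. = FALSE)
  if (!is.null(cfg$input)) {
    if (is.null(cfg$input$milkings) || is.null(cfg$input$repro))
      stop("config error: input block needs 'milkings' and 'repro' paths",
           call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  sch <- cfg$categories$scheme %||% "quantiles"
  if (!sch %in% c("quantiles", "fixed"))
    stop("config error: categories$scheme must be 'quantiles' or 'fixed'",
         call. = FALSE)
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes every stage and writes the standard artifact set into
#' \code{out_dir}: \code{lactations.csv}, \code{fitted_params.csv},
#' \code{categories.csv}, \code{comparison.csv}, \code{contrasts.csv} and
#' \code{report.json}. Row counts are conserved and asserted at every
#' stage (input = retained + dropped).
#'
#' @param config a \code{\link{read_run_config}} result or a plain list
#'   with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed overrides the config seed when non-NULL.
#' @param quiet suppress progress messages.
#' @return Invisibly, the run report (also written as
#'   \code{report.json}).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  report <- list(config = unclass(config), stages = list())

  # -- acquire -------------------------------------------------------------
  if (!is.null(config$simulate)) {
    say("stage: simulate")
    sim <- config$simulate
    cohort <- if (!is.null(sim$name)) {
      fx <- make_fixture(sim$name)
      if (!inherits(fx, "sim_cohort"))
        stop("fixture '", sim$name, "' is not a full cohort", call. = FALSE)
      fx
    } else {
      sim$seed <- config$seed
      do.call(sim_config, sim) |> simulate_cohort()
    }
    milkings_raw <- cohort$milkings
    repro <- cohort$repro
  } else {
    say("stage: read")
    milkings_raw <- read_milkings(config$input$milkings)
    repro <- read_repro(config$input$repro)
  }
  report$stages$input <- list(n_milkings = nrow(milkings_raw),
                              n_repro = nrow(repro))

  # -- filter --------------------------------------------------------------
  say("stage: filter")
  filt <- filter_milkings(milkings_raw)
  stopifnot(nrow(filt$retained) + sum(filt$dropped_counts) == nrow(milkings_raw))
  report$stages$filter <- list(
    n_in = nrow(milkings_raw), n_retained = nrow(filt$retained),
    dropped = as.list(filt$dropped_counts),
    conserved = TRUE)

  # -- assemble ------------------------------------------------------------
  say("stage: assemble")
  min_dim <- config$filters$min_dim %||% 10L
  rule <- config$filters$min_dim_rule %||% "max_dim"
  asm <- assemble_lactations(filt$retained, repro,
                             min_dim = min_dim, min_dim_rule = rule)
  stopifnot(nrow(asm$lactations) +
              sum(asm$dropped_counts[c("gl_out_of_range", "below_min_dim",
                                       "no_milkings")]) == nrow(repro))
  report$stages$assemble <- list(
    n_repro = nrow(repro), n_lactations = nrow(asm$lactations),
    dropped = as.list(asm$dropped_counts), conserved = TRUE)
  write_records(asm$lactations[, setdiff(names(asm$lactations),
                                         c("n_milkings", "max_dim"))],
                file.path(out_dir, "lactations.csv"))

  # -- fit -----------------------------------------------------------------
  say("stage: fit (", nrow(asm$lactations), " lactations)")
  fit_args <- config$fit %||% list()
  fit_args$seed <- fit_args$seed %||% config$seed
  control <- do.call(milkbot_control, fit_args)
  fitted <- fit_cohort(asm$lactations, asm$milkings, control = control)
  report$stages$fit <- list(
    n_lactations = nrow(asm$lactations), n_fitted = nrow(fitted),
    n_converged = sum(fitted$converged))
  write_records(fitted, file.path(out_dir, "fitted_params.csv"))

  # -- categorize ----------------------------------------------------------
  say("stage: categorize")
  scheme <- if ((config$categories$scheme %||% "quantiles") == "fixed")
    gl_scheme_fixed() else NULL
  cat_res <- categorize_cohort(asm$lactations, scheme = scheme,
                               probs = unlist(config$categories$probs) %||%
                                 c(0.01, 0.05, 0.25, 0.75))
  stopifnot(sum(cat_res$counts) == nrow(asm$lactations))
  report$stages$categorize <- list(
    counts = as.list(cat_res$counts),
    scheme = list(source = cat_res$scheme$source,
                  cutpoints = cat_res$scheme$cutpoints,
                  probs = cat_res$scheme$probs),
    conserved = TRUE)
  cats <- cat_res$lactations[c("animal_id", "gl_days", "category")]
  write_records(cats, file.path(out_dir, "categories.csv"))

  # -- compare -------------------------------------------------------------
  say("stage: compare")
  trait_table <- merge(fitted, cat_res$lactations[
    c("animal_id", "category", "calving_month", "calving_year", "afc")],
    by = "animal_id")
  traits <- unlist(config$model$traits) %||%
    c("m305", "a", "b", "d", "t_peak", "peak_yield")
  cmp <- compare_categories(
    trait_table, traits = traits,
    df_method = config$model$df_method %||% "asymptotic",
    adjust = config$model$adjust %||% "none")
  report$stages$compare <- list(
    n_modelled = nrow(trait_table), traits = traits,
    varcomp = lapply(cmp$models, function(m) as.list(m$varcomp)))
  write_records(cmp$comparison, file.path(out_dir, "comparison.csv"))
  write_records(cmp$contrasts, file.path(out_dir, "contrasts.csv"))

  report$table <- render_comparison_table(cmp)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in ", out_dir)
  invisible(report)
}

trait_display_names <- c(
  m305 = "305-day milk yield (kg)", a = "Scale", b = "Ramp", d = "Decay",
  t_peak = "Time to peak (d)", peak_yield = "Peak yield (kg)"
)

#' Render the trait-by-category summary table
#'
#' Plain-text table: one row per trait plus a lactation-count row, one
#' column per category; cells are \code{mean +- SE^letters}. Categories
#' with no animals render as \code{---} with a warning.
#'
#' @param comparison a \code{\link{compare_categories}} result.
#' @return character vector of table lines.
#' @export
render_comparison_table <- function(comparison) {
  comp <- comparison$comparison
  cats <- GL_LABELS[GL_LABELS %in% unique(comp$category)]
  if (!all(GL_LABELS %in% cats))
    warning("empty categor(ies): ",
            paste(setdiff(GL_LABELS, cats), collapse = ", "))
  all_cats <- GL_LABELS
  traits <- unique(comp$trait)
  fmt_cell <- function(row) {
    if (nrow(row) == 0) return("---")
    digits <- if (abs(row$ls_mean) < 0.1) 5 else if (abs(row$ls_mean) < 100) 1 else 0
    sprintf("%s ± %s^%s^",
            formatC(row$ls_mean, format = "f", digits = digits, big.mark = ","),
            formatC(row$se, format = "f",
                    digits = if (digits == 0) 0 else digits + 1),
            row$letters)
  }
  body <- lapply(traits, function(tr) {
    cells <- vapply(all_cats, function(cg)
      fmt_cell(comp[comp$trait == tr & comp$category == cg, , drop = FALSE]), "")
    c(trait_display_names[[tr]] %||% tr, cells)
  })
  counts <- vapply(all_cats, function(cg) {
    r <- comp[comp$trait == traits[1] & comp$category == cg, , drop = FALSE]
    if (nrow(r)) format(r$n, big.mark = ",") else "---"
  }, "")
  body <- c(body, list(c("Lactations", counts)))
  mat <- do.call(rbind, body)
  header <- c("Trait", all_cats)
  widths <- pmax(nchar(header), apply(mat, 2, function(x) max(nchar(x))))
  pad <- function(x) paste(mapply(formatC, x, width = widths,
                                  MoreArgs = list(flag = "-")), collapse = "  ")
  c(pad(header), paste(rep("-", sum(widths) + 2 * length(widths)),
                       collapse = ""), apply(mat, 1, pad))
}
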