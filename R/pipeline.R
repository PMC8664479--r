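#' Configuration for a full pipeline run
#'
#' Collects every option of the end-to-end analysis in one validated list.
#' Configurations can also be read from a YAML file with [load_config()];
#' fields not set in the file keep these defaults.
#'
#' @param mode `"synthetic"` (simulate a dry-down experiment) or `"csv"`
#'   (read a trait table from `csv`).
#' @param csv Path to a trait-table CSV (required for `mode = "csv"`).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness of a synthetic run.
#' @param design List of [dry_down_design()] argument overrides.
#' @param grid List with `min`, `max`, `n` for [moisture_grid()].
#' @param traits,species Optional restrictions for model selection.
#' @param spline_df Spline degrees of freedom.
#' @param as_printed_moisture,abs_mean_standardize,split_harvest Flags passed
#'   through to the corresponding stages.
#' @param mean_center `"level"` or `"grand"`, see [g_matrix()].
#' @return List of class `fvt_config`.
#' @export
fvt_config <- function(mode = c("synthetic", "csv"), csv = NULL,
                       out_dir = "fvt_out", seed = 1, design = list(),
                       grid = list(min = 30, max = 100, n = 20),
                       traits = NULL, species = NULL, spline_df = 2,
                       as_printed_moisture = FALSE,
                       abs_mean_standardize = FALSE, split_harvest = TRUE,
                       mean_center = "level") {
  mode <- match.arg(mode)
  if (mode == "csv" && is.null(csv)) stop("`csv` path required in csv mode")
  grid_def <- utils::modifyList(list(min = 30, max = 100, n = 20), grid)
  structure(list(mode = mode, csv = csv, out_dir = out_dir,
                 seed = as.integer(seed), design = design, grid = grid_def,
                 traits = traits, species = species, spline_df = spline_df,
                 as_printed_moisture = isTRUE(as_printed_moisture),
                 abs_mean_standardize = isTRUE(abs_mean_standardize),
                 split_harvest = isTRUE(split_harvest),
                 mean_center = match.arg(mean_center, c("level", "grand"))),
            class = "fvt_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [fvt_config()] arguments.
#' @return List of class `fvt_config`.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  bad <- setdiff(names(vals), names(formals(fvt_config)))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(fvt_config, vals)
}

#' Run the full function-valued-trait analysis
#'
#' Executes the complete pipeline: obtain a trait table (synthetic simulation
#' or CSV), select a reaction-norm model per trait and species by stepwise
#' AIC, predict genotype means on the moisture grid, and derive genetic
#' correlation curves, multivariate plasticity (with species contrasts and
#' trait-space PCA) and G-matrix constraint curves. All stage outputs are
#' written as plain CSV (plus JSON model records and a selection trace), and
#' a manifest lists every file with its MD5 checksum; a log records the seed
#' and the frozen spline knots, making runs fully reproducible.
#'
#' @param config An [fvt_config()] or the path to a YAML config file.
#' @return The manifest (list), invisibly. Files written to
#'   `config$out_dir`: `trait_table.csv` (+ `trait_table_truth.json`,
#'   synthetic mode), `model_terms.csv`, `models.json`,
#'   `selection_trace.csv`, `genotype_means.csv`, `correlations.csv`,
#'   `plasticity.csv`, `plasticity_tests.csv`, `pca_scores.csv`,
#'   `pca_loadings.csv`, `constraints.csv`, `run_log.txt`, `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "fvt_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("mode: %s", config$mode))

  if (config$mode == "synthetic") {
    design <- do.call(dry_down_design, config$design)
    sim <- simulate_dry_down(design, seed = config$seed,
                             split_harvest = config$split_harvest,
                             as_printed_moisture = config$as_printed_moisture)
    table <- sim$table
    write_trait_table(table, out("trait_table.csv"), norms = sim$norms)
  } else {
    table <- read_trait_table(config$csv)
  }

  models <- select_trait_models(table, traits = config$traits,
                                species = config$species,
                                df = config$spline_df)
  if (!length(models)) stop("no trait model could be fitted")
  utils::write.csv(term_matrix(models), out("model_terms.csv"),
                   row.names = FALSE)
  jsonlite::write_json(lapply(models, function(m) {
    list(species = m$species, trait = m$trait, terms = m$terms,
         basis = unclass(m$basis), coefficients = as.list(m$coefficients),
         aliased = names(m$coefficients)[m$aliased], rank = m$rank,
         n = m$n, rss = m$rss, aic = m$aic)
  }), out("models.json"), auto_unbox = TRUE, digits = NA)
  traces <- do.call(rbind, lapply(names(models), function(k) {
    cbind(model = k, models[[k]]$trace)
  }))
  utils::write.csv(traces, out("selection_trace.csv"), row.names = FALSE)
  log_lines <- c(log_lines, vapply(names(models), function(k) {
    b <- models[[k]]$basis
    sprintf("knots %s: boundary=[%.4f, %.4f] interior=%s", k,
            b$boundary_knots[1], b$boundary_knots[2],
            paste(sprintf("%.4f", b$interior_knots), collapse = ","))
  }, character(1)))

  grid <- moisture_grid(config$grid$n, config$grid$min, config$grid$max)
  gm <- predict_genotype_means(models, grid)
  utils::write.csv(gm, out("genotype_means.csv"), row.names = FALSE)

  cc <- correlation_curves(gm, models = models)
  utils::write.csv(cc, out("correlations.csv"), row.names = FALSE)

  spaces <- lapply(sort(unique(gm$species)), function(sp) {
    suppressWarnings(scale_traits(gm, species = sp, on_constant = "drop"))
  })
  series <- delta_T(spaces)
  utils::write.csv(series, out("plasticity.csv"), row.names = FALSE)
  if (length(unique(series$species)) == 2) {
    utils::write.csv(species_contrast(series), out("plasticity_tests.csv"),
                     row.names = FALSE)
  } else {
    log_lines <- c(log_lines,
                   "plasticity_tests: skipped (need exactly two species)")
  }
  pcas <- lapply(spaces, trait_space_pca)
  scores <- do.call(rbind, lapply(pcas, function(p) {
    data.frame(species = p$species, genotype = p$genotype, level = p$level,
               p$scores, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  loadings <- do.call(rbind, lapply(pcas, function(p) {
    data.frame(species = p$species, trait = rownames(p$loadings), p$loadings,
               stringsAsFactors = FALSE, check.names = FALSE)
  }))
  utils::write.csv(scores, out("pca_scores.csv"), row.names = FALSE)
  utils::write.csv(loadings, out("pca_loadings.csv"), row.names = FALSE)

  cons <- suppressWarnings(
    constraint_curves(gm, models = models,
                      abs_mean = config$abs_mean_standardize,
                      center = config$mean_center))
  utils::write.csv(cons, out("constraints.csv"), row.names = FALSE)

  writeLines(log_lines, out("run_log.txt"))
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    files = lapply(files, function(f) {
      list(name = f, md5 = unname(tools::md5sum(out(f))))
    }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
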