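#' Configure the end-to-end analysis pipeline
#'
#' Bundles every setting of the full workflow: response-surface fits with
#' ANOVA, the neural surrogate, the three optimization routes (GA over
#' the quadratic models, GA over the surrogate, desirability over the
#' quadratic models) and the validation-metric report. A configuration
#' can also be read from a JSON file with [read_pipeline_config()].
#'
#' @param design_csv Path to the design/response CSV
#'   (see [load_design_csv()]).
#' @param out_dir Output directory; created if absent.
#' @param responses Response columns to model.
#' @param seed Integer seed recorded in every output artifact and used
#'   for the surrogate, the GAs and the desirability starts.
#' @param ann Named list of overrides for [train_surrogate()]
#'   (`hidden_units`, `max_epochs`, `patience`, `split`, `algorithm`).
#' @param ga Named list of overrides for [ga_config()]
#'   (`population_size`, `generations`, ...).
#' @param desirability_goals Optional goals for [desirability_optimize()];
#'   default derives low/high from the observed response ranges.
#' @param log_level `"info"` for progress messages, `"quiet"` for none.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(design_csv, out_dir,
                            responses = c("DPPH", "ABTS", "TPC", "TFC"),
                            seed = 1, ann = list(), ga = list(),
                            desirability_goals = NULL,
                            log_level = c("info", "quiet")) {
  if (!file.exists(design_csv))
    stop("config error: design file not found: ", design_csv)
  structure(
    list(design_csv = design_csv, out_dir = out_dir, responses = responses,
         seed = as.integer(seed), ann = ann, ga = ga,
         desirability_goals = desirability_goals,
         log_level = match.arg(log_level)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

stage <- function(name, quiet, expr) {
  if (!quiet) message("[maeopt] stage: ", name)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the complete extraction-optimization pipeline
#'
#' Loads the design, fits the four quadratic response surfaces (writing
#' each as JSON plus a combined ANOVA table), computes the
#' experimental-vs-fitted validation metrics, trains the neural
#' surrogate, and runs the three optimization routes. All outputs land in
#' `config$out_dir`; `provenance.json` records the seed, package and R
#' versions and a timestamp (the only timestamped artifact, so repeated
#' runs with one seed are byte-identical elsewhere).
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the fitted models, ANOVA reports,
#'   metrics table, surrogate net and the three `optimum_report`s.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(system.file("extdata", "ccd_design_sf.csv",
#'                                    package = "maeopt"),
#'                        out_dir = tempfile(), seed = 1,
#'                        ga = list(generations = 40))
#' res <- run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  quiet <- config$log_level == "quiet"
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  design <- stage("load-design", quiet,
                  load_design_csv(config$design_csv,
                                  responses = config$responses))

  models <- stage("fit-rsm", quiet, {
    ms <- lapply(stats::setNames(config$responses, config$responses),
                 function(r) fit_quadratic(design, r))
    for (r in names(ms))
      write_model_json(ms[[r]], file.path(config$out_dir,
                                          paste0("model_", tolower(r), ".json")))
    ms
  })

  anova_reports <- stage("anova", quiet, {
    reps <- lapply(models, anova_report, design = design)
    tab <- do.call(rbind, lapply(reps, function(a)
      data.frame(response = a$response, r2 = a$r2, adj_r2 = a$adj_r2,
                 cv_percent = a$cv_percent,
                 adeq_precision = a$adeq_precision, model_f = a$model_f,
                 lack_of_fit_p = a$lack_of_fit_p,
                 stringsAsFactors = FALSE)))
    utils::write.csv(format_signif(tab),
                     file.path(config$out_dir, "anova.csv"),
                     row.names = FALSE, quote = FALSE)
    reps
  })

  metrics_tab <- stage("metrics", quiet, {
    fitted_cols <- design
    for (r in config$responses)
      fitted_cols$data[[paste0(r, "_fit")]] <-
        predict(models[[r]], coded_matrix(design))
    tab <- validation_report(fitted_cols, responses = config$responses,
                             predictors = c("rsm", "ann", "fit"))
    utils::write.csv(format_signif(tab),
                     file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE, quote = FALSE)
    tab
  })

  net <- stage("train-ann", quiet, {
    args <- c(list(design = design, responses = config$responses,
                   seed = config$seed), config$ann)
    n <- do.call(train_surrogate, args)
    write_net_json(n, file.path(config$out_dir, "net.json"))
    n
  })

  bounds <- factor_bounds(design$factors)
  opts <- stage("optimize", quiet, {
    ga_args <- config$ga
    mk_cfg <- function() do.call(ga_config, c(list(bounds = bounds,
                                                   seed = config$seed),
                                              ga_args))
    rsm_ga <- ga_maximize(scalarize(models, design = design), mk_cfg())
    rsm_ga$predicted_responses <-
      lapply(models, function(m) predict_actual(m, rsm_ga$best_point))
    rsm_ga$method <- "rsm_ga"
    ann_ga <- ga_maximize(scalarize(net, design = design), mk_cfg())
    ann_ga$predicted_responses <-
      as.list(predict_surrogate(net, ann_ga$best_point))
    ann_ga$method <- "ann_ga"
    rsm_df <- desirability_optimize(models, goals = config$desirability_goals,
                                    bounds = bounds, design = design,
                                    seed = config$seed)
    res <- list(rsm_ga = rsm_ga, ann_ga = ann_ga, rsm_df = rsm_df)
    for (nm in names(res))
      jsonlite::write_json(
        optimum_as_list(res[[nm]], seed = config$seed),
        file.path(config$out_dir, paste0("optimum_", nm, ".json")),
        auto_unbox = TRUE, digits = NA)
    res
  })

  stage("provenance", quiet, {
    jsonlite::write_json(
      list(seed = config$seed, package = "maeopt",
           package_version = as.character(utils::packageVersion("maeopt")),
           r_version = R.version.string,
           design_csv = config$design_csv,
           responses = config$responses,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      file.path(config$out_dir, "provenance.json"),
      auto_unbox = TRUE, digits = NA)
  })

  invisible(list(design = design, models = models,
                 anova = anova_reports, metrics = metrics_tab, net = net,
                 optima = opts, config = config))
}

optimum_as_list <- function(x, seed) {
  list(method = x$method, seed = seed,
       best_point = x$best_point,
       objective_value = x$objective_value,
       predicted_responses = x$predicted_responses,
       desirability = x$desirability,
       convergence_trace = x$convergence_trace)
}

# 6 significant digits for human-readable reports; JSON artifacts keep
# full precision.
format_signif <- function(df) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}
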