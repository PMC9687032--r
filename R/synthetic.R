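#' Default per-response noise standard deviations
#'
#' The homoscedastic Gaussian noise magnitudes used by the synthetic
#' generator: the median of the printed triplicate standard deviations of
#' each response in the bundled 27-run dataset (DPPH 2.20, ABTS 1.77,
#' TPC 0.76, TFC 0.58).
#'
#' @return Named numeric vector of standard deviations.
#' @export
default_noise_sd <- function() {
  d <- sf_design()$data
  vapply(c(DPPH = "DPPH_sd", ABTS = "ABTS_sd", TPC = "TPC_sd",
           TFC = "TFC_sd"),
         function(cl) stats::median(d[[cl]]), numeric(1))
}

#' Specify a synthetic design/response dataset
#'
#' A synthetic dataset is a design (by default the 27-run central
#' composite layout), a set of quadratic truth surfaces (by default the
#' four published coefficient sets) and i.i.d. Gaussian response noise.
#' Generation is seeded and reproducible (R's Mersenne-Twister RNG).
#'
#' @param truth_models Named list of 1-4 `quadratic_model`s.
#' @param design A `design_table` giving the runs to simulate at.
#' @param noise_sd Per-response noise SD, recycled; default
#'   [default_noise_sd()] for the matching responses.
#' @param seed Integer seed.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(truth_models = sf_models(),
                           design = build_ccd(n_centre = 3),
                           noise_sd = NULL, seed = 1) {
  if (inherits(truth_models, "quadratic_model"))
    truth_models <- stats::setNames(list(truth_models), truth_models$response)
  if (is.null(names(truth_models)))
    names(truth_models) <- vapply(truth_models, `[[`, character(1), "response")
  if (is.null(noise_sd)) {
    dflt <- default_noise_sd()
    noise_sd <- vapply(names(truth_models), function(r)
      if (r %in% names(dflt)) dflt[[r]] else 1.0, numeric(1))
  }
  noise_sd <- rep_len(noise_sd, length(truth_models))
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0")
  structure(
    list(truth_models = truth_models, design = design,
         noise_sd = stats::setNames(noise_sd, names(truth_models)),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic design/response table
#'
#' Evaluates each truth surface at the design's coded points and adds
#' independent Gaussian noise: `response = truth(coded) + N(0, sd)`.
#' With `noise_sd = 0` the responses equal the truth-surface predictions
#' exactly; equal seeds give identical tables.
#'
#' @param spec A `synthetic_spec`.
#' @return A `design_table` with the truth responses filled in.
#' @examples
#' spec <- synthetic_spec(sf_models("DPPH"), noise_sd = 0)
#' generate_synthetic(spec)
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  design <- spec$design
  coded <- coded_matrix(design)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(spec$seed)
  data <- design$data
  for (r in names(spec$truth_models)) {
    mu <- predict(spec$truth_models[[r]], coded)
    data[[r]] <- mu + stats::rnorm(nrow(coded), 0, spec$noise_sd[[r]])
  }
  new_design_table(data, design$factors,
                   responses = union(design$responses,
                                     names(spec$truth_models)))
}

#' Coefficient-recovery and argmax-recovery study
#'
#' Repeatedly simulates from the truth surfaces, refits the full
#' second-order model to each replicate and summarizes how well the 15
#' coefficients and the location of the response maximum are recovered.
#' Replicate `i` uses seed `spec$seed + i - 1`. The argmax comparison
#' locates the maximum of the refitted and the truth surface on a dense
#' coded grid over \[-2, 2\]^4 (`argmax_method = "ga"` instead runs the
#' genetic algorithm on the refitted surface).
#'
#' @param spec A `synthetic_spec`.
#' @param n_replicates Number of simulated datasets (>= 2).
#' @param argmax Whether to include the argmax comparison.
#' @param grid_n Grid levels per dimension for the argmax search.
#' @param argmax_method `"grid"` (default) or `"ga"` for the fitted-surface
#'   search.
#' @return A `recovery_study` object: list with `coefficients` (data
#'   frame of per-term true value, mean bias and RMSE across replicates),
#'   `argmax` (per-replicate distance between fitted and truth argmax in
#'   coded units, and the truth-objective gap), and the call settings.
#' @examples
#' spec <- synthetic_spec(sf_models("DPPH"), noise_sd = 1, seed = 7)
#' recovery_study(spec, n_replicates = 5, argmax = FALSE)
#' @export
recovery_study <- function(spec, n_replicates, argmax = TRUE, grid_n = 11,
                           argmax_method = c("grid", "ga")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  argmax_method <- match.arg(argmax_method)
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  r_names <- names(spec$truth_models)
  coded_box <- rbind(low = rep(-2, 4), high = rep(2, 4))

  truth_argmax <- if (argmax) {
    lapply(spec$truth_models, function(m)
      grid_maximize(function(P) predict(m, P), coded_box, n = grid_n,
                    vectorized = TRUE))
  }

  errs <- lapply(r_names, function(r) matrix(NA_real_, n_replicates, 15))
  names(errs) <- r_names
  argmax_rows <- list()

  for (i in seq_len(n_replicates)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i - 1L
    sim <- generate_synthetic(spec_i)
    for (r in r_names) {
      truth <- stats::coef(spec$truth_models[[r]])
      fit <- fit_quadratic(sim, r)
      errs[[r]][i, ] <- stats::coef(fit) - truth
      if (argmax) {
        fit_max <- grid_or_ga_argmax(fit, coded_box, grid_n, argmax_method,
                                     seed = spec$seed + i - 1L)
        tm <- truth_argmax[[r]]
        argmax_rows[[length(argmax_rows) + 1L]] <- data.frame(
          replicate = i, response = r,
          distance = sqrt(sum((fit_max$best_point - tm$best_point)^2)),
          objective_gap = tm$objective_value -
            predict(spec$truth_models[[r]], fit_max$best_point),
          stringsAsFactors = FALSE)
      }
    }
  }

  coef_tab <- do.call(rbind, lapply(r_names, function(r) {
    data.frame(response = r, term = TERM_NAMES,
               true = unname(stats::coef(spec$truth_models[[r]])),
               mean_bias = colMeans(errs[[r]]),
               rmse = sqrt(colMeans(errs[[r]]^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(coef_tab) <- NULL

  structure(
    list(coefficients = coef_tab,
         argmax = if (length(argmax_rows)) do.call(rbind, argmax_rows),
         n_replicates = n_replicates, noise_sd = spec$noise_sd,
         seed = spec$seed, argmax_method = if (argmax) argmax_method),
    class = "recovery_study"
  )
}

grid_or_ga_argmax <- function(model, bounds, grid_n, method, seed) {
  if (method == "grid")
    return(grid_maximize(function(P) predict(model, P), bounds, n = grid_n,
                         vectorized = TRUE))
  cfg <- ga_config(bounds, generations = 100, seed = seed)
  rep_ <- ga_maximize(function(x) predict(model, x), cfg)
  list(best_point = rep_$best_point, objective_value = rep_$objective_value)
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("<recovery_study> %d replicates, noise sd %s\n",
              x$n_replicates,
              paste(sprintf("%s=%.3g", names(x$noise_sd), x$noise_sd),
                    collapse = ", ")))
  worst <- x$coefficients[order(-abs(x$coefficients$mean_bias)), ][1, ]
  cat(sprintf("  largest |mean bias|: %s %s = %.4f\n",
              worst$response, worst$term, worst$mean_bias))
  if (!is.null(x$argmax))
    cat(sprintf("  median argmax distance (coded units): %.4f\n",
                stats::median(x$argmax$distance)))
  invisible(x)
}
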