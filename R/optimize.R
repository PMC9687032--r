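#' Genetic-algorithm configuration
#'
#' Settings for the bound-constrained real-coded genetic algorithm:
#' rank-based fitness scaling, stochastic-uniform selection, blend
#' crossover (BLX-alpha with alpha = 0.5) and Gaussian mutation whose
#' standard deviation shrinks linearly from `mutation_sd_start` to
#' `mutation_sd_end` (both as fractions of each factor's range), with
#' elitism. Offspring are clipped to the bounds.
#'
#' @param bounds 2 x k matrix (rows `low`, `high`) in the units the
#'   objective expects; see [factor_bounds()].
#' @param population_size Individuals per generation (default 90).
#' @param generations Number of generations.
#' @param crossover_fraction Fraction of non-elite offspring produced by
#'   crossover; the remainder are mutants.
#' @param mutation_fraction Fraction produced by mutation; defaults to
#'   `1 - crossover_fraction`.
#' @param elite_count Individuals copied unchanged each generation.
#' @param mutation_sd_start,mutation_sd_end Initial and final mutation
#'   standard deviation as a fraction of each factor range.
#' @param seed Integer seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(bounds, population_size = 90, generations = 100,
                      crossover_fraction = 0.8, mutation_fraction = NULL,
                      elite_count = 2, mutation_sd_start = 0.5,
                      mutation_sd_end = 0.1, seed = 1) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds[2, ] <= bounds[1, ]))
    stop("bounds must be a finite 2 x k matrix with low < high")
  if (is.null(mutation_fraction)) mutation_fraction <- 1 - crossover_fraction
  if (crossover_fraction <= 0 || crossover_fraction >= 1)
    stop("crossover_fraction must be in (0, 1)")
  if (mutation_fraction <= 0 || mutation_fraction >= 1)
    stop("mutation_fraction must be in (0, 1)")
  if (elite_count >= population_size)
    stop("elite_count must be smaller than population_size")
  structure(
    list(bounds = bounds, population_size = as.integer(population_size),
         generations = as.integer(generations),
         crossover_fraction = crossover_fraction,
         mutation_fraction = mutation_fraction,
         elite_count = as.integer(elite_count),
         mutation_sd_start = mutation_sd_start,
         mutation_sd_end = mutation_sd_end, seed = as.integer(seed)),
    class = "ga_config"
  )
}

clip_bounds <- function(m, bounds) {
  for (j in seq_len(ncol(m)))
    m[, j] <- pmin(pmax(m[, j], bounds[1, j]), bounds[2, j])
  m
}

# Stochastic-uniform (SUS) sampling of `n` parent indices given
# expectation weights.
sus_select <- function(expect, n) {
  cum <- cumsum(expect) / sum(expect) * n
  pointers <- stats::runif(1) + 0:(n - 1)
  findInterval(pointers, c(0, cum), rightmost.closed = TRUE)
}

#' Maximize an objective with the genetic algorithm
#'
#' Runs the seeded real-coded GA of [ga_config()] and returns the best
#' individual ever evaluated. The best-so-far trace is monotone
#' non-decreasing by construction (elitism plus best-ever tracking).
#'
#' @param objective Function mapping a length-k point (in the bound's
#'   units) to a finite scalar; non-finite values are treated as
#'   -Inf after initialization, but an initial population that is
#'   non-finite for more than half its members aborts with a diagnostic.
#' @param config A `ga_config`.
#' @return An `optimum_report`: list with `best_point`,
#'   `objective_value`, `convergence_trace` (best objective per
#'   generation), `method = "ga"` and the `config` used.
#' @examples
#' cfg <- ga_config(rbind(low = c(-1, -1), high = c(1, 1)),
#'                  generations = 60, seed = 1)
#' ga_maximize(function(x) -sum((x - 0.3)^2), cfg)$best_point
#' @export
ga_maximize <- function(objective, config) {
  stopifnot(inherits(config, "ga_config"))
  b <- config$bounds; k <- ncol(b)
  pop_n <- config$population_size
  n_elite <- config$elite_count

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(config$seed)

  eval_pop <- function(P) {
    v <- apply(P, 1, function(x) {
      val <- tryCatch(objective(x), error = function(e) NaN)
      if (!is.finite(val)) -Inf else val
    })
    as.numeric(v)
  }

  pop <- sapply(seq_len(k), function(j) stats::runif(pop_n, b[1, j], b[2, j]))
  val <- eval_pop(pop)
  if (mean(!is.finite(val)) > 0.5)
    stop("objective is non-finite for more than half of the initial ",
         "population; check the objective and bounds")

  best_val <- max(val)
  best_point <- pop[which.max(val), ]
  trace <- numeric(config$generations)
  range_ <- b[2, ] - b[1, ]

  for (g in seq_len(config$generations)) {
    ord <- order(val, decreasing = TRUE)
    # rank scaling: expectation ~ 1/sqrt(rank)
    expect <- 1 / sqrt(seq_len(pop_n))
    n_child <- pop_n - n_elite
    n_cross <- round(config$crossover_fraction * n_child)
    n_mut <- n_child - n_cross
    parents_idx <- ord[sus_select(expect, 2 * n_cross + n_mut)]
    parents_idx <- parents_idx[sample.int(length(parents_idx))]

    children <- matrix(NA_real_, n_child, k)
    if (n_cross > 0) {
      p1 <- pop[parents_idx[seq_len(n_cross)], , drop = FALSE]
      p2 <- pop[parents_idx[n_cross + seq_len(n_cross)], , drop = FALSE]
      u <- matrix(stats::runif(n_cross * k, -0.5, 1.5), n_cross, k)
      children[seq_len(n_cross), ] <- p1 + u * (p2 - p1)
    }
    if (n_mut > 0) {
      pm <- pop[parents_idx[2 * n_cross + seq_len(n_mut)], , drop = FALSE]
      frac <- (g - 1) / max(1, config$generations - 1)
      sd_g <- config$mutation_sd_start +
        (config$mutation_sd_end - config$mutation_sd_start) * frac
      noise <- matrix(stats::rnorm(n_mut * k), n_mut, k) *
        rep(sd_g * range_, each = n_mut)
      children[n_cross + seq_len(n_mut), ] <- pm + noise
    }
    children <- clip_bounds(children, b)
    child_val <- eval_pop(children)

    pop <- rbind(pop[ord[seq_len(n_elite)], , drop = FALSE], children)
    val <- c(val[ord[seq_len(n_elite)]], child_val)

    if (max(val) > best_val) {
      best_val <- max(val)
      best_point <- pop[which.max(val), ]
    }
    trace[g] <- best_val
  }

  structure(
    list(best_point = as.numeric(best_point), objective_value = best_val,
         predicted_responses = NULL, desirability = NULL,
         convergence_trace = trace, method = "ga", config = config),
    class = "optimum_report"
  )
}

#' @export
print.optimum_report <- function(x, ...) {
  cat(sprintf("<optimum_report> method %s: objective %.4f\n",
              x$method, x$objective_value))
  cat("  best point:", paste(signif(x$best_point, 6), collapse = ", "), "\n")
  if (!is.null(x$predicted_responses)) {
    cat("  predicted responses:\n")
    for (r in names(x$predicted_responses))
      cat(sprintf("    %s: %.4f\n", r, x$predicted_responses[[r]]))
  }
  if (!is.null(x$desirability))
    cat(sprintf("  overall desirability: %.4f\n", x$desirability))
  invisible(x)
}

as_predictor <- function(p, response = NULL) {
  if (is.function(p)) return(p)
  if (inherits(p, "quadratic_model"))
    return(function(x) predict_actual(p, x))
  if (inherits(p, "surrogate_net")) {
    if (is.null(response)) stop("a surrogate_net predictor needs a response name")
    return(function(x) unname(predict_surrogate(p, x)[response]))
  }
  stop("cannot interpret predictor of class ", paste(class(p), collapse = "/"))
}

#' Collapse several response predictors into one scalar objective
#'
#' The four responses are combined as a weighted sum of min-max
#' normalized predictions,
#' \eqn{f(x) = \sum_r w_r (\hat y_r(x) - \min_r) / (\max_r - \min_r)},
#' where the per-response ranges default to the observed response ranges
#' of a design table. This scalarization is a documented package choice:
#' the upstream procedure never states how four responses became one
#' fitness value.
#'
#' @param predictors Named list of predictors: functions of an
#'   actual-unit point, `quadratic_model` objects, or a single
#'   `surrogate_net` (whose response names are used).
#' @param weights Non-negative weights, not all zero (default equal).
#' @param ranges 2 x r matrix of per-response (min, max), or `design` to
#'   derive them from.
#' @param design Optional `design_table` supplying `ranges`.
#' @return A function mapping an actual-unit point to the scalarized
#'   objective.
#' @examples
#' obj <- scalarize(sf_models(), design = sf_design())
#' obj(c(50, 3, 130, 450))
#' @export
scalarize <- function(predictors, weights = NULL, ranges = NULL,
                      design = NULL) {
  if (inherits(predictors, "surrogate_net")) {
    net <- predictors
    predictors <- lapply(stats::setNames(net$responses, net$responses),
                         function(r) as_predictor(net, r))
  } else {
    predictors <- lapply(predictors, as_predictor)
  }
  r_names <- names(predictors)
  if (is.null(r_names)) stop("predictors must be named by response")
  if (is.null(weights)) weights <- rep(1, length(predictors))
  if (length(weights) != length(predictors))
    stop("one weight per predictor required")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  if (is.null(ranges)) {
    if (is.null(design)) stop("supply ranges or a design to derive them from")
    ranges <- sapply(r_names, function(r) range(response_values(design, r)))
  }
  ranges <- as.matrix(ranges)
  if (any(ranges[2, ] - ranges[1, ] <= 0))
    stop("degenerate response range")
  function(x) {
    s <- 0
    for (i in seq_along(predictors)) {
      y <- predictors[[i]](x)
      s <- s + weights[i] * (y - ranges[1, i]) / (ranges[2, i] - ranges[1, i])
    }
    s
  }
}

#' Dense grid search over a bounded box
#'
#' Brute-force maximization on a full factorial grid of `n` levels per
#' dimension; the reference oracle against which the GA is checked.
#'
#' @param objective Function of a point, or with `vectorized = TRUE` a
#'   function accepting a matrix of points (one row each).
#' @param bounds 2 x k bounds matrix.
#' @param n Levels per dimension (default 21).
#' @param vectorized Whether `objective` accepts a matrix.
#' @return List with `best_point` and `objective_value`.
#' @export
grid_maximize <- function(objective, bounds, n = 21, vectorized = FALSE) {
  b <- as.matrix(bounds); k <- ncol(b)
  axes <- lapply(seq_len(k), function(j) seq(b[1, j], b[2, j], length.out = n))
  grid <- as.matrix(expand.grid(axes))
  dimnames(grid) <- NULL
  val <- if (vectorized) as.numeric(objective(grid))
         else apply(grid, 1, objective)
  i <- which.max(val)
  list(best_point = grid[i, ], objective_value = val[i])
}

#' Derringer-Suich desirability for a maximized response
#'
#' Linear one-sided desirability: 0 at or below `low`, 1 at or above
#' `high`, linear in between.
#'
#' @param y Predicted response value(s).
#' @param low,high Lower and upper anchors, `low < high`.
#' @return Desirability in \[0, 1\].
#' @export
desirability_max <- function(y, low, high) {
  if (!(low < high)) stop("desirability: need low < high")
  pmin(pmax((y - low) / (high - low), 0), 1)
}

#' Multi-response optimization by the desirability function
#'
#' Maximizes the overall Derringer-Suich desirability, the geometric mean
#' of the per-response one-sided desirabilities, over the bounded factor
#' box using seeded multi-start local search (`n_starts` random starts
#' refined with L-BFGS-B).
#'
#' @param predictors Named list of predictors (see [scalarize()]).
#' @param goals Named list, one per response, each `list(low = , high = )`;
#'   defaults to the observed response ranges of `design`.
#' @param bounds 2 x 4 factor bounds (default [factor_bounds()] of
#'   [default_factors()]).
#' @param design Optional `design_table` supplying default goals.
#' @param n_starts Number of random starts (>= 1; default 32).
#' @param seed Integer seed.
#' @return An `optimum_report` with `desirability` set and per-response
#'   `predicted_responses`.
#' @examples
#' \donttest{
#' desirability_optimize(sf_models(), design = sf_design(), seed = 1)
#' }
#' @export
desirability_optimize <- function(predictors, goals = NULL,
                                  bounds = factor_bounds(default_factors()),
                                  design = NULL, n_starts = 32, seed = 1) {
  if (inherits(predictors, "surrogate_net")) {
    net <- predictors
    predictors <- lapply(stats::setNames(net$responses, net$responses),
                         function(r) as_predictor(net, r))
  } else {
    predictors <- lapply(predictors, as_predictor)
  }
  r_names <- names(predictors)
  if (is.null(goals)) {
    if (is.null(design)) stop("supply goals or a design to derive them from")
    goals <- lapply(stats::setNames(r_names, r_names), function(r) {
      rng <- range(response_values(design, r))
      list(low = rng[1], high = rng[2])
    })
  }
  if (!length(goals)) stop("empty goals")
  for (r in r_names) {
    g <- goals[[r]]
    if (is.null(g) || !(g$low < g$high))
      stop("goal for ", r, " must have low < high")
  }
  b <- as.matrix(bounds); k <- ncol(b)

  overall_d <- function(x) {
    d <- vapply(r_names, function(r)
      desirability_max(predictors[[r]](x), goals[[r]]$low, goals[[r]]$high),
      numeric(1))
    if (any(d == 0)) 0 else exp(mean(log(d)))
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)

  best_x <- NULL; best_d <- -Inf
  for (s in seq_len(n_starts)) {
    x0 <- stats::runif(k, b[1, ], b[2, ])
    opt <- tryCatch(
      stats::optim(x0, overall_d, method = "L-BFGS-B",
                   lower = b[1, ], upper = b[2, ],
                   control = list(fnscale = -1)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$value > best_d) { best_d <- opt$value; best_x <- opt$par }
  }
  if (is.null(best_x)) stop("desirability optimization failed from all starts")
  best_x <- pmin(pmax(best_x, b[1, ]), b[2, ])
  preds <- lapply(predictors, function(p) p(best_x))

  structure(
    list(best_point = as.numeric(best_x), objective_value = best_d,
         predicted_responses = preds, desirability = best_d,
         convergence_trace = NULL, method = "desirability",
         config = list(goals = goals, bounds = b, n_starts = n_starts,
                       seed = seed)),
    class = "optimum_report"
  )
}

#' Optimize extraction conditions through a fitted surrogate
#'
#' Convenience front-end reproducing the three optimization routes:
#' `"rsm_ga"` (GA over the quadratic models), `"ann_ga"` (GA over the
#' neural surrogate) and `"rsm_df"` (desirability over the quadratic
#' models). The scalarized GA objective uses equal-weight min-max
#' normalization against the design's observed response ranges.
#'
#' @param models Named list of `quadratic_model`s (for `rsm_*`) or a
#'   `surrogate_net` (for `ann_ga`).
#' @param design `design_table` providing response ranges / goals.
#' @param method One of `"rsm_ga"`, `"ann_ga"`, `"rsm_df"`.
#' @param bounds Factor bounds (default from the design's factors).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [ga_config()] or
#'   [desirability_optimize()].
#' @return An `optimum_report` with `predicted_responses` filled.
#' @export
optimize_extraction <- function(models, design,
                                method = c("rsm_ga", "ann_ga", "rsm_df"),
                                bounds = factor_bounds(design$factors),
                                seed = 1, ...) {
  method <- match.arg(method)
  if (method == "rsm_df")
    return(desirability_optimize(models, design = design, bounds = bounds,
                                 seed = seed, ...))
  obj <- scalarize(models, design = design)
  rep_ <- ga_maximize(obj, ga_config(bounds, seed = seed, ...))
  rep_$method <- method
  preds <- if (inherits(models, "surrogate_net")) {
    as.list(predict_surrogate(models, rep_$best_point))
  } else {
    lapply(models, function(m) predict_actual(m, rep_$best_point))
  }
  rep_$predicted_responses <- preds
  rep_
}

#' The confirmation-run extraction conditions
#'
#' The modified near-optimal settings used for the final confirmation
#' extraction (50 % ethanol, 3 min, 140 degC, 600 W), shipped as a
#' preset evaluation point for the fitted surfaces.
#'
#' @return Named numeric vector of actual-unit settings.
#' @examples
#' vapply(sf_models(), predict_actual, numeric(1),
#'        actual = confirmation_point())
#' @export
confirmation_point <- function() {
  c(ethanol = 50, time = 3, temperature = 140, power = 600)
}
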