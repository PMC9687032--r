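ITX_PAIRS <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))

TERM_NAMES <- c("(Intercept)", paste0("x", 1:4), paste0("x", 1:4, "^2"),
                apply(ITX_PAIRS, 1, function(p) paste0("x", p[1], ":x", p[2])))

#' Second-order model matrix in coded units
#'
#' Columns, in fixed order: intercept, the four linear terms, the four
#' pure quadratic terms, and the six two-way interactions ordered
#' (1,2), (1,3), (1,4), (2,3), (2,4), (3,4) -- 15 columns in all.
#'
#' @param coded Matrix of coded factor settings (runs x 4) or a length-4
#'   vector for a single point.
#' @return Numeric matrix with 15 columns.
#' @export
quadratic_model_matrix <- function(coded) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1)
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == 4L)
  if (!all(is.finite(coded))) stop("non-finite coded settings")
  itx <- sapply(seq_len(nrow(ITX_PAIRS)), function(i)
    coded[, ITX_PAIRS[i, 1]] * coded[, ITX_PAIRS[i, 2]])
  if (is.null(dim(itx))) itx <- matrix(itx, nrow = 1)
  m <- cbind(1, coded, coded^2, itx)
  colnames(m) <- TERM_NAMES
  m
}

new_quadratic_model <- function(response, beta0, linear, quad, inter,
                                factors = default_factors(), units = NULL) {
  stopifnot(length(linear) == 4L, length(quad) == 4L, length(inter) == 6L)
  structure(
    list(response = response, beta0 = unname(beta0),
         linear = unname(linear), quad = unname(quad), inter = unname(inter),
         factors = factors, units = units),
    class = "quadratic_model"
  )
}

#' Construct a second-order polynomial response-surface model
#'
#' Builds a `quadratic_model` from explicit coefficients in coded units:
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
#'       \sum_{i<j} \beta_{ij} x_i x_j}
#'
#' @param response Response name.
#' @param beta0 Intercept.
#' @param linear Four linear coefficients.
#' @param quad Four pure-quadratic coefficients.
#' @param inter Six interaction coefficients, ordered (1,2), (1,3),
#'   (1,4), (2,3), (2,4), (3,4).
#' @param factors Factor specifications defining the coding.
#' @param units Response unit label (optional).
#' @return A `quadratic_model`.
#' @export
quadratic_model <- function(response, beta0, linear, quad, inter,
                            factors = default_factors(), units = NULL) {
  new_quadratic_model(response, beta0, linear, quad, inter, factors, units)
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("<quadratic_model> %s%s: 15 coefficients in coded units\n",
              x$response, if (is.null(x$units)) "" else paste0(" [", x$units, "]")))
  print(round(stats::coef(x), 4))
  invisible(x)
}

#' @export
coef.quadratic_model <- function(object, ...) {
  stats::setNames(c(object$beta0, object$linear, object$quad, object$inter),
                  TERM_NAMES)
}

#' Fit the full second-order polynomial by ordinary least squares
#'
#' Fits the 15-term quadratic surface to one response of a design table,
#' in coded units. The fit is plain OLS; no term selection is performed.
#'
#' @param design A `design_table` whose response columns include `response`.
#' @param response Name of the response column to fit.
#' @return A `quadratic_model` with attributes recording the fit
#'   (fitted values, residuals, standard errors) used by [anova_report()].
#' @examples
#' fit <- fit_quadratic(sf_design(), "DPPH")
#' predict(fit, c(0, 0, 0, 0))
#' @export
fit_quadratic <- function(design, response) {
  y <- response_values(design, response)
  if (!all(is.finite(y))) stop("response '", response, "' has non-finite values")
  X <- quadratic_model_matrix(coded_matrix(design))
  n <- nrow(X); p <- ncol(X)
  if (n < p)
    stop("rank-deficient fit: ", n, " runs cannot identify ", p,
         " coefficients")
  qrX <- qr(X)
  if (qrX$rank < p) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("rank-deficient design: collinear term(s) ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  sigma2 <- sum(res^2) / (n - p)
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  mod <- new_quadratic_model(response, beta[1], beta[2:5], beta[6:9],
                             beta[10:15], factors = design$factors)
  attr(mod, "fit") <- list(fitted = fitted, residuals = res, se = se,
                           sigma2 = sigma2, n = n, p = p, y = y)
  mod
}

#' Evaluate a quadratic response-surface model
#'
#' @param object A `quadratic_model`.
#' @param coded Coded point (length-4 vector) or matrix of coded points.
#' @param ... Unused.
#' @return Predicted response value(s).
#' @export
predict.quadratic_model <- function(object, coded, ...) {
  drop(quadratic_model_matrix(coded) %*% stats::coef(object))
}

#' Evaluate a quadratic model at actual-unit settings
#'
#' Convenience wrapper that codes `actual` with the model's own factor
#' specifications before evaluating.
#'
#' @param model A `quadratic_model`.
#' @param actual Actual-unit point or matrix.
#' @return Predicted response value(s).
#' @export
predict_actual <- function(model, actual) {
  predict(model, code_point(actual, model$factors))
}

#' ANOVA and diagnostics for a fitted response surface
#'
#' Produces the standard design-of-experiments report for an OLS quadratic
#' fit: R-squared (centred total sum of squares), adjusted R-squared,
#' coefficient of variation (percent), adequate precision (the
#' signal-to-noise ratio `(max fitted - min fitted) / sqrt(p * MSE / n)`),
#' the model F statistic, per-coefficient t tests, and the lack-of-fit
#' F test obtained by splitting residual error into pure error (within
#' replicate groups) and lack-of-fit components.
#'
#' @param model A `quadratic_model` returned by [fit_quadratic()] (it must
#'   carry the fit attributes; published coefficient fixtures cannot be
#'   ANOVA-ed without refitting).
#' @param design The `design_table` the model was fitted to (for replicate
#'   groups).
#' @return An object of class `anova_report`: list with elements `r2`,
#'   `adj_r2`, `cv_percent`, `adeq_precision`, `model_f`, `model_p`,
#'   `lack_of_fit_f`, `lack_of_fit_p` (NA when the design has no
#'   replicates), `coefficient_table` and `residuals`.
#' @examples
#' rep <- anova_report(fit_quadratic(sf_design(), "DPPH"), sf_design())
#' rep$r2
#' @export
anova_report <- function(model, design) {
  fit <- attr(model, "fit")
  if (is.null(fit))
    stop("anova_report needs a model fitted by fit_quadratic(), ",
         "not a published-coefficient fixture")
  y <- fit$y; n <- fit$n; p <- fit$p
  res <- fit$residuals
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  dfe <- n - p
  r2 <- 1 - sse / sst
  adj_r2 <- 1 - (sse / dfe) / (sst / (n - 1))
  mse <- sse / dfe
  cv <- 100 * sqrt(mse) / mean(y)
  adeq <- (max(fit$fitted) - min(fit$fitted)) / sqrt(p * mse / n)
  ssr <- sst - sse
  model_f <- (ssr / (p - 1)) / mse
  model_p <- stats::pf(model_f, p - 1, dfe, lower.tail = FALSE)

  est <- stats::coef(model)
  tval <- est / fit$se
  pval <- 2 * stats::pt(abs(tval), dfe, lower.tail = FALSE)
  coef_tab <- data.frame(term = TERM_NAMES, estimate = unname(est),
                         std_error = fit$se, t_value = unname(tval),
                         p_value = unname(pval),
                         signif = signif_stars(pval),
                         stringsAsFactors = FALSE)

  lof_f <- lof_p <- NA_real_
  groups <- design$replicate_groups
  if (length(groups)) {
    ids <- design$data$run_id
    ss_pe <- 0; df_pe <- 0
    for (g in groups) {
      yg <- y[match(g, ids)]
      ss_pe <- ss_pe + sum((yg - mean(yg))^2)
      df_pe <- df_pe + length(yg) - 1L
    }
    df_lof <- dfe - df_pe
    if (df_pe > 0 && df_lof > 0 && ss_pe > 0) {
      ss_lof <- sse - ss_pe
      lof_f <- (ss_lof / df_lof) / (ss_pe / df_pe)
      lof_p <- stats::pf(lof_f, df_lof, df_pe, lower.tail = FALSE)
    }
  }

  structure(
    list(response = model$response, r2 = r2, adj_r2 = adj_r2,
         cv_percent = cv, adeq_precision = adeq,
         model_f = model_f, model_p = model_p,
         lack_of_fit_f = lof_f, lack_of_fit_p = lof_p,
         coefficient_table = coef_tab, residuals = res),
    class = "anova_report"
  )
}

signif_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.anova_report <- function(x, ...) {
  cat(sprintf("<anova_report> %s\n", x$response))
  cat(sprintf("  R2 %.4f | adj R2 %.4f | CV %.2f%% | adeq precision %.2f\n",
              x$r2, x$adj_r2, x$cv_percent, x$adeq_precision))
  cat(sprintf("  model F %.2f (p %.3g) | lack-of-fit p %s\n",
              x$model_f, x$model_p,
              if (is.na(x$lack_of_fit_p)) "undefined (no replicates)"
              else sprintf("%.4f", x$lack_of_fit_p)))
  invisible(x)
}

#' Read and write quadratic models as JSON
#'
#' The JSON layout is `{response, units, coding: {factor_names, centres,
#' steps}, beta0, beta_linear, beta_quad, beta_inter}` with interactions
#' ordered (1,2), (1,3), (1,4), (2,3), (2,4), (3,4). Bounds for the
#' coding's factor specifications are taken from [default_factors()] when
#' the names match, else set to centre +/- 2 steps.
#'
#' @param path JSON file path.
#' @return `read_model_json()` returns a `quadratic_model`;
#'   `write_model_json()` returns `path` invisibly.
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  centres <- as.numeric(x$coding$centres)
  steps <- as.numeric(x$coding$steps)
  nms <- if (!is.null(x$coding$factor_names)) as.character(x$coding$factor_names)
         else paste0("x", seq_along(centres))
  defaults <- default_factors()
  dflt_names <- factor_names(defaults)
  factors <- lapply(seq_along(centres), function(i) {
    j <- match(nms[i], dflt_names)
    if (!is.na(j) && defaults[[j]]$centre == centres[i] &&
        defaults[[j]]$step == steps[i]) return(defaults[[j]])
    factor_spec(nms[i], "", centres[i], steps[i],
                centres[i] - 2 * steps[i], centres[i] + 2 * steps[i])
  })
  new_quadratic_model(x$response, x$beta0, as.numeric(x$beta_linear),
                      as.numeric(x$beta_quad), as.numeric(x$beta_inter),
                      factors = factors, units = x$units)
}

#' @rdname read_model_json
#' @param model A `quadratic_model`.
#' @export
write_model_json <- function(model, path) {
  x <- list(
    response = model$response, units = model$units,
    coding = list(factor_names = factor_names(model$factors),
                  centres = factor_centres(model$factors),
                  steps = factor_steps(model$factors)),
    beta0 = model$beta0, beta_linear = model$linear,
    beta_quad = model$quad, beta_inter = model$inter
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The published response-surface coefficient sets
#'
#' Loads the four published fitted quadratic surfaces (DPPH, ABTS, TPC,
#' TFC) bundled with the package, exactly as printed. Note two printed
#' inconsistencies that are preserved, not corrected: the TPC intercept
#' (35.48 in the equation vs 35.80 in the printed coefficient table) and
#' the sign of its ethanol-by-time interaction.
#'
#' @param response Optional single response name; default returns all four.
#' @return A `quadratic_model`, or a named list of the four models.
#' @examples
#' predict(sf_models("DPPH"), c(0, 0, 0, 0))  # 26.34
#' @export
sf_models <- function(response = NULL) {
  files <- c(DPPH = "model_dpph.json", ABTS = "model_abts.json",
             TPC = "model_tpc.json", TFC = "model_tfc.json")
  if (!is.null(response)) {
    response <- match.arg(response, names(files))
    return(read_model_json(system.file("extdata", files[[response]],
                                       package = "maeopt", mustWork = TRUE)))
  }
  lapply(stats::setNames(names(files), names(files)), sf_models)
}
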