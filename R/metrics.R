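check_paired <- function(experimental, predicted) {
  if (length(experimental) != length(predicted))
    stop("experimental and predicted series differ in length (",
         length(experimental), " vs ", length(predicted), ")")
  if (length(experimental) < 1L) stop("empty paired series")
  if (!all(is.finite(experimental)) || !all(is.finite(predicted)))
    stop("non-finite values in paired series")
  invisible(TRUE)
}

#' Model-validation metrics for paired experimental/predicted series
#'
#' The five metrics conventionally used to compare a fitted surrogate
#' against experimental data, each defined on paired vectors of
#' experimental values \eqn{y} and predictions \eqn{\hat y}:
#'
#' * `mse()`: mean squared error \eqn{\frac1n \sum (\hat y_i - y_i)^2};
#' * `rmse()`: its square root;
#' * `r2_percent()`: \eqn{100 (1 - \sum(\hat y_i - y_i)^2 / \sum(y_i - \bar y)^2)},
#'   with the experimental series as reference;
#' * `aad_percent()`: absolute average deviation,
#'   \eqn{\frac{100}{n} \sum |y_i - \hat y_i| / y_i} (per-row experimental
#'   denominator, so the experimental values must be nonzero);
#' * `sep_percent()`: standard error of prediction,
#'   \eqn{100 \cdot \mathrm{RMSE} / \bar y} (nonzero experimental mean
#'   required).
#'
#' @param experimental Numeric vector of observed values.
#' @param predicted Numeric vector of model predictions, same length.
#' @return A single numeric value.
#' @examples
#' d <- sf_design()$data
#' rmse(d$DPPH, d$DPPH_ann)  # ~1.15
#' @export
mse <- function(experimental, predicted) {
  check_paired(experimental, predicted)
  mean((predicted - experimental)^2)
}

#' @rdname mse
#' @export
rmse <- function(experimental, predicted) sqrt(mse(experimental, predicted))

#' @rdname mse
#' @export
r2_percent <- function(experimental, predicted) {
  check_paired(experimental, predicted)
  sst <- sum((experimental - mean(experimental))^2)
  if (sst == 0) stop("r2_percent: experimental series is constant")
  100 * (1 - sum((predicted - experimental)^2) / sst)
}

#' @rdname mse
#' @export
aad_percent <- function(experimental, predicted) {
  check_paired(experimental, predicted)
  if (any(experimental == 0))
    stop("aad_percent: experimental values must be nonzero")
  100 * mean(abs(experimental - predicted) / experimental)
}

#' @rdname mse
#' @export
sep_percent <- function(experimental, predicted) {
  check_paired(experimental, predicted)
  ym <- mean(experimental)
  if (ym == 0) stop("sep_percent: experimental mean is zero")
  100 * rmse(experimental, predicted) / ym
}

#' Tabulate validation metrics for several predictors
#'
#' Builds the standard model-comparison table: one row per metric (RMSE,
#' R2 %, AAD %, SEP %), one column per response and predictor. The design
#' must carry predicted columns named `<response>_<suffix>` (as the
#' bundled dataset does with `_rsm` and `_ann`).
#'
#' @param design A `design_table`.
#' @param responses Response names to include.
#' @param predictors Column suffixes identifying the prediction columns.
#' @return A data frame with columns `response`, `predictor`, `rmse`,
#'   `r2_percent`, `aad_percent`, `sep_percent`, `mse`.
#' @examples
#' validation_report(sf_design())
#' @export
validation_report <- function(design, responses = design$responses,
                              predictors = c("rsm", "ann")) {
  rows <- list()
  for (r in responses) {
    y <- response_values(design, r)
    for (p in predictors) {
      col <- paste0(r, "_", p)
      if (!col %in% names(design$data)) next
      yp <- design$data[[col]]
      rows[[length(rows) + 1L]] <- data.frame(
        response = r, predictor = p,
        rmse = rmse(y, yp), r2_percent = r2_percent(y, yp),
        aad_percent = aad_percent(y, yp), sep_percent = sep_percent(y, yp),
        mse = mse(y, yp), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no prediction columns found for the requested predictors")
  do.call(rbind, rows)
}
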