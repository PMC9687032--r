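#' Define an extraction factor
#'
#' A factor is described by its centre and step in actual units, which
#' together define the affine map to dimensionless coded units,
#' `coded = (actual - centre) / step`, plus the bounds of the region the
#' design explores.
#'
#' @param name Factor name (column name in design tables).
#' @param unit Actual unit, for reporting only.
#' @param centre Centre-point setting in actual units.
#' @param step Actual units per coded unit; must be positive.
#' @param low,high Bounds of the design region in actual units.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("ethanol", "%", centre = 50, step = 20, low = 10, high = 90)
#' @export
factor_spec <- function(name, unit, centre, step, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(centre) || !is.finite(step) || !is.finite(low) || !is.finite(high))
    stop("factor_spec: all numeric arguments must be finite")
  if (step <= 0) stop("factor_spec: step must be > 0")
  if (!(low < centre && centre < high))
    stop("factor_spec: need low < centre < high, got ", low, " / ", centre, " / ", high)
  structure(
    list(name = name, unit = unit, centre = centre, step = step,
         low = low, high = high),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s [%s]: centre %g, step %g, bounds [%g, %g]\n",
              x$name, x$unit, x$centre, x$step, x$low, x$high))
  invisible(x)
}

#' Default four-factor microwave-assisted extraction design
#'
#' Ethanol concentration (%), extraction time (min), temperature (degC)
#' and microwave power (W), with centres (50, 3, 130, 450) and steps
#' (20, 1, 20, 150) inferred from the replicated centre runs and level
#' spacing of the 27-run design. Bounds are the observed factor ranges.
#'
#' @return A list of four `factor_spec` objects.
#' @export
default_factors <- function() {
  list(
    factor_spec("ethanol",     "%",    centre = 50,  step = 20,  low = 10,  high = 90),
    factor_spec("time",        "min",  centre = 3,   step = 1,   low = 1,   high = 5),
    factor_spec("temperature", "degC", centre = 130, step = 20,  low = 90,  high = 150),
    factor_spec("power",       "W",    centre = 450, step = 150, low = 150, high = 750)
  )
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")
factor_centres <- function(factors) vapply(factors, `[[`, numeric(1), "centre")
factor_steps <- function(factors) vapply(factors, `[[`, numeric(1), "step")

#' Factor bounds as a matrix
#'
#' @param factors A list of `factor_spec` objects.
#' @return A 2-row matrix with rows `low` and `high`, one column per factor.
#' @export
factor_bounds <- function(factors) {
  rbind(low = vapply(factors, `[[`, numeric(1), "low"),
        high = vapply(factors, `[[`, numeric(1), "high"))
}

#' Convert between actual and coded factor settings
#'
#' `code_point()` applies the per-factor affine map
#' `(actual - centre) / step`; `decode_point()` inverts it. Both accept a
#' vector (one point) or a matrix with one column per factor.
#'
#' @param actual,coded Numeric vector of length equal to the number of
#'   factors, or a matrix with that many columns.
#' @param factors List of `factor_spec` objects.
#'
#' @return Numeric vector or matrix of the same shape.
#' @examples
#' code_point(c(50, 3, 130, 450), default_factors())  # coded origin
#' @export
code_point <- function(actual, factors) {
  affine_map(actual, factors, decode = FALSE)
}

#' @rdname code_point
#' @export
decode_point <- function(coded, factors) {
  affine_map(coded, factors, decode = TRUE)
}

affine_map <- function(x, factors, decode) {
  k <- length(factors)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(m) != k)
    stop("expected ", k, " factor columns, got ", ncol(m))
  if (!all(is.finite(m))) stop("non-finite factor settings")
  ctr <- factor_centres(factors); st <- factor_steps(factors)
  out <- if (decode) sweep(sweep(m, 2, st, "*"), 2, ctr, "+")
         else        sweep(sweep(m, 2, ctr, "-"), 2, st, "/")
  colnames(out) <- factor_names(factors)
  if (vec) drop(out) else out
}

new_design_table <- function(data, factors, responses) {
  k <- length(factors)
  fn <- factor_names(factors)
  stopifnot(all(c("run_id", fn) %in% names(data)))
  if (anyDuplicated(data$run_id))
    stop("duplicate run_id values: ",
         paste(unique(data$run_id[duplicated(data$run_id)]), collapse = ", "))
  num_cols <- c(fn, responses)
  for (cl in num_cols)
    if (!is.numeric(data[[cl]]))
      stop("non-numeric values in column '", cl, "'")
  actual <- as.matrix(data[, fn])
  coded <- code_point(actual, factors)
  # replicate groups: runs with exactly equal actual settings
  key <- apply(actual, 1, paste, collapse = "\r")
  groups <- split(data$run_id, key)
  groups <- unname(groups[vapply(groups, length, integer(1)) > 1L])
  structure(
    list(data = data, factors = factors, responses = responses,
         coded = coded, replicate_groups = groups),
    class = "design_table"
  )
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("<design_table> %d runs, %d factors (%s)\n",
              nrow(x$data), length(x$factors),
              paste(factor_names(x$factors), collapse = ", ")))
  cat(sprintf("  responses: %s\n",
              if (length(x$responses)) paste(x$responses, collapse = ", ") else "(none)"))
  if (length(x$replicate_groups))
    cat(sprintf("  replicate groups: %s\n",
                paste(vapply(x$replicate_groups,
                             function(g) paste0("{", paste(g, collapse = ","), "}"),
                             character(1)), collapse = " ")))
  invisible(x)
}

#' Number of runs in a design
#' @param design A `design_table`.
#' @return Integer run count.
#' @export
n_runs <- function(design) nrow(design$data)

#' Extract the coded design matrix
#' @param design A `design_table`.
#' @return Numeric matrix, one column per factor, in coded units.
#' @export
coded_matrix <- function(design) design$coded

#' Extract a response column
#' @param design A `design_table`.
#' @param response Response column name.
#' @return Numeric vector.
#' @export
response_values <- function(design, response) {
  if (!response %in% names(design$data))
    stop("design has no response column '", response, "'")
  design$data[[response]]
}

#' Build a four-factor central composite design
#'
#' Generates the rotatable-style central composite design used for the
#' extraction study: a full 2^4 factorial at coded +/-1, eight axial
#' points at coded +/-2 and `n_centre` replicated centre points, i.e.
#' `24 + n_centre` runs. Responses are left empty.
#'
#' @param factors List of `factor_spec` objects (default [default_factors()]).
#' @param n_centre Number of centre-point replicates (>= 1; 3 gives the
#'   27-run design).
#'
#' @return A `design_table` with no response columns.
#' @examples
#' n_runs(build_ccd(n_centre = 3))  # 27
#' @export
build_ccd <- function(factors = default_factors(), n_centre = 3) {
  k <- length(factors)
  if (k != 4L) stop("build_ccd: exactly 4 factors expected")
  if (n_centre < 1) stop("build_ccd: n_centre must be >= 1")
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) axial[2 * i - 1:0, i] <- c(-2, 2)
  centre <- matrix(0, n_centre, k)
  coded <- rbind(fact, axial, centre)
  actual <- decode_point(coded, factors)
  data <- data.frame(run_id = seq_len(nrow(actual)), actual,
                     check.names = FALSE)
  new_design_table(data, factors, responses = character(0))
}

#' Read or write a design/response table as CSV
#'
#' The CSV dialect is comma-separated, '.' decimal, UTF-8, with a header
#' row holding `run_id`, one column per factor in actual units and one
#' column per response. Extra columns (replicate standard deviations,
#' externally predicted values, ...) are carried through untouched.
#' Replicate groups are detected by exact equality of actual settings.
#'
#' @param path File path.
#' @param factors List of `factor_spec` objects naming the factor columns.
#' @param responses Candidate response column names; only those present in
#'   the file are registered as responses.
#'
#' @return `load_design_csv()` returns a `design_table`;
#'   `write_design_csv()` returns `path` invisibly.
#' @export
load_design_csv <- function(path, factors = default_factors(),
                            responses = c("DPPH", "ABTS", "TPC", "TFC")) {
  if (!file.exists(path)) stop("design file not found: ", path)
  data <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop("cannot parse design CSV '", path, "': ",
                             conditionMessage(e)))
  if (nrow(data) == 0L) stop("design CSV '", path, "' has no runs")
  fn <- factor_names(factors)
  missing_cols <- setdiff(c("run_id", fn), names(data))
  if (length(missing_cols))
    stop("design CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  present <- intersect(responses, names(data))
  new_design_table(data, factors, responses = present)
}

#' @rdname load_design_csv
#' @param design A `design_table`.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(design$data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The bundled 27-run extraction dataset
#'
#' The complete central-composite experiment on brown-seaweed
#' microwave-assisted extraction: 27 runs over ethanol concentration,
#' time, temperature and power, with the four measured responses (DPPH
#' and ABTS radical scavenging, total phenolic and total flavonoid
#' content), their replicate standard deviations (`*_sd` columns) and the
#' response-surface / neural-network predictions printed alongside the
#' experimental values (`*_rsm`, `*_ann` columns).
#'
#' Note that the temperature column does not follow the textbook
#' +/-1/+/-2 level pattern: its five levels 90/110/130/140/150 degC code
#' to (-2, -1, 0, +0.5, +1) under the affine map. The printed runs are
#' preserved as-is.
#'
#' @return A `design_table` with 27 runs and one replicate group of size 3.
#' @examples
#' d <- sf_design()
#' n_runs(d)
#' @export
sf_design <- function() {
  load_design_csv(system.file("extdata", "ccd_design_sf.csv",
                              package = "maeopt", mustWork = TRUE))
}

#' Serialize factor specifications to JSON
#'
#' @param factors List of `factor_spec` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_factors_json <- function(factors, path) {
  x <- lapply(factors, function(f)
    list(name = f$name, unit = f$unit, centre = f$centre, step = f$step,
         low = f$low, high = f$high))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_factors_json
#' @export
read_factors_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(x, function(f)
    factor_spec(f$name, f$unit, f$centre, f$step, f$low, f$high))
}
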