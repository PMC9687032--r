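test_that("OLS recovers a known coefficient vector exactly on noiseless data", {
  d <- build_ccd(n_centre = 3)
  set.seed(11)
  beta <- round(rnorm(15, 0, 2), 3)
  y <- apply(coded_matrix(d), 1, function(x) eval_quad(beta, x))
  dd <- make_design(as.matrix(d$data[, maeopt:::factor_names(d$factors)]),
                    responses = list(Y = y))
  fit <- fit_quadratic(dd, "Y")
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-9)

  a <- anova_report(fit, dd)
  expect_equal(a$r2, 1, tolerance = 1e-9)
  expect_equal(a$cv_percent, 0, tolerance = 1e-6)
})

test_that("refitting the printed dataset reproduces the published fit quality", {
  d <- sf_design()
  fit <- fit_quadratic(d, "DPPH")
  a <- anova_report(fit, d)
  expect_equal(a$r2, 0.9543, tolerance = 0.005)
  # the refit intercept equals the printed centre-run prediction (26.79),
  # not the published equation's 26.34 -- the two printed columns disagree
  # and the data wins here
  expect_equal(fit$beta0, 26.79, tolerance = 0.005)

  expect_equal(anova_report(fit_quadratic(d, "TFC"), d)$r2, 0.9745,
               tolerance = 0.005)
  expect_equal(anova_report(fit_quadratic(d, "ABTS"), d)$r2, 0.9608,
               tolerance = 0.005)
  expect_equal(anova_report(fit_quadratic(d, "TPC"), d)$r2, 0.9533,
               tolerance = 0.005)
  # lack-of-fit probability from the single replicate triple
  expect_equal(a$lack_of_fit_p, 0.1138, tolerance = 0.005)
  expect_lte(a$adj_r2, a$r2)
  expect_true(all(a$coefficient_table$p_value >= 0 &
                    a$coefficient_table$p_value <= 1))
})

test_that("fit diagnostics: residual orthogonality and fitted-value identity", {
  d <- sf_design()
  for (r in c("DPPH", "TFC")) {
    fit <- fit_quadratic(d, r)
    X <- quadratic_model_matrix(coded_matrix(d))
    res <- attr(fit, "fit")$residuals
    y <- response_values(d, r)
    expect_lt(max(abs(crossprod(X, res))) / sum(abs(y)), 1e-8)
    expect_equal(predict(fit, coded_matrix(d)), attr(fit, "fit")$fitted,
                 tolerance = 1e-10)
  }
})

test_that("fit quality is invariant to the affine factor coding", {
  d <- sf_design()
  # same runs, deliberately different coding (shifted centres, scaled steps)
  alt_factors <- list(
    factor_spec("ethanol", "%", centre = 40, step = 10, low = 5, high = 95),
    factor_spec("time", "min", centre = 2.5, step = 0.5, low = 0.5, high = 6),
    factor_spec("temperature", "degC", centre = 125, step = 15, low = 80,
                high = 160),
    factor_spec("power", "W", centre = 400, step = 100, low = 100, high = 800)
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(d, path)
  d_alt <- load_design_csv(path, factors = alt_factors)

  for (r in c("DPPH", "TFC")) {
    f1 <- fit_quadratic(d, r); f2 <- fit_quadratic(d_alt, r)
    a1 <- anova_report(f1, d); a2 <- anova_report(f2, d_alt)
    expect_equal(a1$r2, a2$r2, tolerance = 1e-10)
    expect_equal(a1$adj_r2, a2$adj_r2, tolerance = 1e-10)
    expect_equal(a1$lack_of_fit_p, a2$lack_of_fit_p, tolerance = 1e-8)
    expect_equal(attr(f1, "fit")$fitted, attr(f2, "fit")$fitted,
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient and undersized designs error informatively", {
  d <- sf_design()
  trunc10 <- make_design(
    as.matrix(d$data[1:10, maeopt:::factor_names(d$factors)]),
    responses = list(DPPH = d$data$DPPH[1:10]))
  expect_error(fit_quadratic(trunc10, "DPPH"), "rank-deficient")

  # collinear: power column an exact affine image of temperature
  act <- as.matrix(d$data[, maeopt:::factor_names(d$factors)])
  act[, "power"] <- 450 + (act[, "temperature"] - 130) * 7.5
  coll <- make_design(act, responses = list(DPPH = d$data$DPPH))
  expect_error(fit_quadratic(coll, "DPPH"), "collinear")

  expect_error(fit_quadratic(d, "nope"), "no response column")
})

test_that("published coefficient fixtures evaluate as printed", {
  eq7 <- sf_models("DPPH")
  expect_equal(predict(eq7, c(0, 0, 0, 0)), 26.34, tolerance = 0)
  expect_equal(predict(sf_models("ABTS"), c(0, 0, 0, 0)), 41.84,
               tolerance = 0)
  expect_equal(predict(sf_models("TPC"), c(0, 0, 0, 0)), 35.48,
               tolerance = 0)
  # against the independent term-by-term evaluator at a non-trivial point
  x <- c(0.5, -1, 0.25, 2)
  beta <- unname(coef(eq7))
  expect_equal(predict(eq7, x), eval_quad(beta, x), tolerance = 1e-12)
  # all-zero model predicts zero anywhere
  zero <- quadratic_model("null", 0, rep(0, 4), rep(0, 4), rep(0, 6))
  expect_equal(predict(zero, x), 0)
  # actual-unit evaluation agrees with explicit coding
  expect_equal(predict_actual(eq7, c(50, 3, 140, 600)),
               predict(eq7, c(0, 0, 0.5, 1)), tolerance = 1e-12)
})

test_that("quadratic models survive a JSON round trip", {
  fit <- fit_quadratic(sf_design(), "ABTS")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  m2 <- read_model_json(path)
  expect_equal(coef(m2), coef(fit), tolerance = 1e-12)
  expect_equal(m2$response, "ABTS")
  x <- c(1.2, -0.7, 0.3, -1.5)
  expect_equal(predict(m2, x), predict(fit, x), tolerance = 1e-12)
})

test_that("anova_report refuses models without fit internals and designs without replicates", {
  d <- sf_design()
  expect_error(anova_report(sf_models("DPPH"), d), "fit_quadratic")
  # no replicates: lack of fit undefined, not fabricated
  d1 <- build_ccd(n_centre = 1)
  set.seed(5)
  y <- apply(coded_matrix(d1), 1, function(x) eval_quad(rnorm(15), x)) +
    rnorm(25, 0, 0.5)
  dd <- make_design(as.matrix(d1$data[, maeopt:::factor_names(d1$factors)]),
                    responses = list(Y = y))
  a <- anova_report(fit_quadratic(dd, "Y"), dd)
  expect_true(is.na(a$lack_of_fit_p))
})
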