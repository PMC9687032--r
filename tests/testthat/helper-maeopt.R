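# Shared fixtures and independent oracles for the test suite.

# Independent second-order polynomial evaluator: explicit term-by-term
# formula, deliberately not sharing code with the package's model matrix.
eval_quad <- function(beta, x) {
  # beta: b0, b1..b4, b11..b44, b12, b13, b14, b23, b24, b34
  beta[1] +
    beta[2] * x[1] + beta[3] * x[2] + beta[4] * x[3] + beta[5] * x[4] +
    beta[6] * x[1]^2 + beta[7] * x[2]^2 + beta[8] * x[3]^2 + beta[9] * x[4]^2 +
    beta[10] * x[1] * x[2] + beta[11] * x[1] * x[3] + beta[12] * x[1] * x[4] +
    beta[13] * x[2] * x[3] + beta[14] * x[2] * x[4] + beta[15] * x[3] * x[4]
}

# Build a design_table from an actual-unit matrix plus response columns.
make_design <- function(actual, responses = list(),
                        factors = default_factors()) {
  colnames(actual) <- vapply(factors, `[[`, character(1), "name")
  data <- data.frame(run_id = seq_len(nrow(actual)), actual,
                     check.names = FALSE)
  for (r in names(responses)) data[[r]] <- responses[[r]]
  maeopt:::new_design_table(data, factors, responses = names(responses))
}

coded_box <- rbind(low = rep(-2, 4), high = rep(2, 4))
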