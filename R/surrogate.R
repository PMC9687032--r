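#' @keywords internal
#' Min-max scaler to [-1, 1] (the MATLAB mapminmax convention)
fit_scaler <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  if (any(hi - lo <= 0)) stop("degenerate column range; cannot scale")
  list(min = lo, max = hi)
}

scale_fwd <- function(x, s) {
  sweep(sweep(x, 2, s$min, "-"), 2, (s$max - s$min) / 2, "/") - 1
}

scale_inv <- function(xs, s) {
  sweep(sweep(xs + 1, 2, (s$max - s$min) / 2, "*"), 2, s$min, "+")
}

net_forward <- function(w, Xs) {
  # Xs: n x 4 scaled inputs; returns list(H: hidden x n, Y: n x k scaled)
  A <- w$W1 %*% t(Xs) + w$b1            # hidden x n
  H <- tanh(A)
  Y <- t(w$W2 %*% H + w$b2)             # n x k
  list(H = H, Y = Y)
}

unpack_weights <- function(theta, n_in, n_hidden, n_out) {
  i1 <- n_hidden * n_in
  i2 <- i1 + n_hidden
  i3 <- i2 + n_out * n_hidden
  list(W1 = matrix(theta[1:i1], n_hidden, n_in),
       b1 = theta[(i1 + 1):i2],
       W2 = matrix(theta[(i2 + 1):i3], n_out, n_hidden),
       b2 = theta[(i3 + 1):length(theta)])
}

pack_weights <- function(w) c(as.vector(w$W1), w$b1, as.vector(w$W2), w$b2)

# Residual vector (sample-major, outputs within sample) and its Jacobian
# with respect to the packed weight vector.
net_residual_jacobian <- function(theta, Xs, Ys, n_hidden, jacobian = TRUE) {
  n_in <- ncol(Xs); n_out <- ncol(Ys); n <- nrow(Xs)
  w <- unpack_weights(theta, n_in, n_hidden, n_out)
  fw <- net_forward(w, Xs)
  R <- fw$Y - Ys                         # n x k
  r <- as.vector(t(R))                   # sample-major
  if (!jacobian) return(list(r = r))
  nw <- length(theta)
  J <- matrix(0, n * n_out, nw)
  i1 <- n_hidden * n_in; i2 <- i1 + n_hidden; i3 <- i2 + n_out * n_hidden
  for (s in seq_len(n)) {
    h <- fw$H[, s]
    dh <- 1 - h^2
    x <- Xs[s, ]
    for (k in seq_len(n_out)) {
      row <- (s - 1) * n_out + k
      bp <- w$W2[k, ] * dh               # hidden-length backprop factor
      J[row, 1:i1] <- as.vector(outer(bp, x))          # dW1 (column-major)
      J[row, (i1 + 1):i2] <- bp                        # db1
      J[row, i2 + k + seq(0, n_out * (n_hidden - 1), by = n_out)] <- h  # dW2 row k
      J[row, i3 + k] <- 1                              # db2
    }
  }
  list(r = r, J = J)
}

#' Train the 4-16-4 feed-forward neural surrogate
#'
#' Trains a single-hidden-layer perceptron (tanh hidden activation,
#' linear output) mapping the four extraction factors to the response
#' set, after min-max scaling of inputs and outputs to \[-1, 1\].
#' Weights start from the Nguyen-Widrow layout (hidden units spread
#' evenly over the scaled input range). The default optimizer is a direct
#' Levenberg-Marquardt iteration on the full weight vector (the network
#' has at most a few hundred weights, so the normal equations are solved
#' exactly); `algorithm = "bfgs"` selects a quasi-Newton fit of the same
#' objective. Runs are split into training / validation / test subsets by
#' seeded shuffling, and training stops early once the validation MSE has
#' not improved for `patience` accepted steps; the returned network
#' carries the final (training-MSE-minimizing) weights and records the
#' epoch of best validation MSE.
#'
#' All randomness (weight initialization and the data split) derives from
#' `seed`; the global RNG state is restored on exit, and repeated calls
#' with identical inputs return identical networks.
#'
#' @param design A `design_table` holding the responses.
#' @param responses Response columns to model jointly (default all four).
#' @param hidden_units Hidden-layer width (default 16).
#' @param seed Integer seed.
#' @param max_epochs Maximum accepted optimizer steps.
#' @param split Fractions of runs assigned to training, validation and
#'   test; must sum to 1.
#' @param patience Accepted steps without validation improvement before
#'   stopping (set 0 to disable early stopping; requires no validation
#'   split).
#' @param algorithm `"lm"` (Levenberg-Marquardt, default) or `"bfgs"`.
#'
#' @return An object of class `surrogate_net` with the fitted weights,
#'   scalers, split indices, `best_epoch` and a per-epoch `training_log`
#'   (train/validation/test MSE in scaled units).
#' @examples
#' \donttest{
#' net <- train_surrogate(sf_design(), seed = 1)
#' predict_surrogate(net, c(50, 3, 130, 450))
#' }
#' @export
train_surrogate <- function(design, responses = design$responses,
                            hidden_units = 16, seed = 1,
                            max_epochs = 100,
                            split = c(0.70, 0.15, 0.15), patience = 6,
                            algorithm = c("lm", "bfgs")) {
  algorithm <- match.arg(algorithm)
  if (hidden_units < 1) stop("hidden_units must be >= 1")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  n <- n_runs(design)
  if (n < 10L) stop("need at least 10 runs to train the surrogate")
  if (!length(responses)) stop("no responses to model")
  Y <- sapply(responses, function(r) response_values(design, r))
  if (!all(is.finite(Y))) stop("non-finite response values")
  X <- as.matrix(design$data[, factor_names(design$factors)])

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(seed)

  perm <- sample.int(n)
  n_train <- max(1L, round(split[1] * n))
  n_val <- round(split[2] * n)
  idx_train <- perm[seq_len(n_train)]
  idx_val <- if (n_val > 0) perm[n_train + seq_len(n_val)] else integer(0)
  idx_test <- setdiff(perm, c(idx_train, idx_val))
  if (patience > 0 && !length(idx_val))
    stop("degenerate split: early stopping (patience > 0) needs a ",
         "non-empty validation set")

  in_scaler <- fit_scaler(X)
  out_scaler <- fit_scaler(Y)
  Xs <- scale_fwd(X, in_scaler); Ys <- scale_fwd(Y, out_scaler)
  n_in <- ncol(Xs); n_out <- ncol(Ys)

  # Nguyen-Widrow initialization for the tanh layer (inputs in [-1,1]):
  # unit weight vectors scaled to 0.7 * H^(1/n_in), biases spread evenly.
  nw_beta <- 0.7 * hidden_units^(1 / n_in)
  W1 <- matrix(stats::runif(hidden_units * n_in, -1, 1), hidden_units, n_in)
  W1 <- W1 / sqrt(rowSums(W1^2)) * nw_beta
  b1 <- nw_beta * seq(-1, 1, length.out = hidden_units) * sign(W1[, 1])
  theta <- c(as.vector(W1), b1,
             stats::runif(n_out * hidden_units + n_out, -0.5, 0.5))

  split_mse <- function(th, idx) {
    if (!length(idx)) return(NA_real_)
    rr <- net_residual_jacobian(th, Xs[idx, , drop = FALSE],
                                Ys[idx, , drop = FALSE], hidden_units,
                                jacobian = FALSE)$r
    mean(rr^2)
  }

  log_rows <- list()
  best_val <- Inf; best_epoch <- 0L; stall <- 0L

  if (algorithm == "lm") {
    lambda <- 1e-3
    rj <- net_residual_jacobian(theta, Xs[idx_train, , drop = FALSE],
                                Ys[idx_train, , drop = FALSE], hidden_units)
    sse <- sum(rj$r^2)
    for (epoch in seq_len(max_epochs)) {
      A <- crossprod(rj$J); g <- crossprod(rj$J, rj$r)
      accepted <- FALSE
      while (lambda <= 1e10) {
        delta <- tryCatch(solve(A + lambda * diag(nrow(A)), -g),
                          error = function(e) NULL)
        if (!is.null(delta)) {
          cand <- theta + as.vector(delta)
          r_new <- net_residual_jacobian(cand, Xs[idx_train, , drop = FALSE],
                                         Ys[idx_train, , drop = FALSE],
                                         hidden_units, jacobian = FALSE)$r
          if (sum(r_new^2) < sse) {
            theta <- cand; sse <- sum(r_new^2)
            lambda <- max(lambda / 10, 1e-12)
            accepted <- TRUE
            break
          }
        }
        lambda <- lambda * 10
      }
      if (!accepted) break   # lambda exhausted: converged
      rj <- net_residual_jacobian(theta, Xs[idx_train, , drop = FALSE],
                                  Ys[idx_train, , drop = FALSE], hidden_units)
      val_mse <- split_mse(theta, idx_val)
      log_rows[[epoch]] <- data.frame(
        epoch = epoch, train_mse = sse / (length(idx_train) * n_out),
        val_mse = val_mse, test_mse = split_mse(theta, idx_test),
        lambda = lambda)
      if (length(idx_val)) {
        if (val_mse < best_val - 1e-12) {
          best_val <- val_mse; best_epoch <- epoch
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (patience > 0 && stall >= patience) break
        }
      } else {
        best_epoch <- epoch
      }
    }
  } else {
    Xtr <- Xs[idx_train, , drop = FALSE]; Ytr <- Ys[idx_train, , drop = FALSE]
    fn <- function(th) sum(net_residual_jacobian(th, Xtr, Ytr, hidden_units,
                                                 jacobian = FALSE)$r^2)
    gr <- function(th) {
      rj <- net_residual_jacobian(th, Xtr, Ytr, hidden_units)
      2 * as.vector(crossprod(rj$J, rj$r))
    }
    opt <- stats::optim(theta, fn, gr, method = "BFGS",
                        control = list(maxit = max_epochs))
    theta <- opt$par
    best_epoch <- NA_integer_
    log_rows[[1]] <- data.frame(
      epoch = 1L, train_mse = opt$value / (length(idx_train) * n_out),
      val_mse = split_mse(theta, idx_val),
      test_mse = split_mse(theta, idx_test), lambda = NA_real_)
    if (length(idx_val)) best_val <- split_mse(theta, idx_val)
  }

  structure(
    list(weights = unpack_weights(theta, n_in, hidden_units, n_out),
         input_scaler = in_scaler, output_scaler = out_scaler,
         responses = responses, factors = design$factors,
         hidden_units = hidden_units, seed = seed, algorithm = algorithm,
         best_epoch = best_epoch,
         split = list(train = sort(idx_train), validation = sort(idx_val),
                      test = sort(idx_test)),
         training_log = do.call(rbind, log_rows)),
    class = "surrogate_net"
  )
}

#' @export
print.surrogate_net <- function(x, ...) {
  cat(sprintf(
    "<surrogate_net> %d-%d-%d (%s, seed %d), best validation epoch %s\n",
    length(x$input_scaler$min), x$hidden_units, length(x$responses),
    x$algorithm, x$seed, as.character(x$best_epoch)))
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  invisible(x)
}

#' Predict responses from a trained surrogate network
#'
#' Scales the actual-unit input, runs the forward pass and unscales the
#' outputs.
#'
#' @param net A `surrogate_net`.
#' @param actual Length-4 vector or matrix of actual-unit settings.
#' @return A named vector (single point) or matrix of predicted responses.
#' @export
predict_surrogate <- function(net, actual) {
  vec <- is.null(dim(actual))
  m <- if (vec) matrix(actual, nrow = 1) else as.matrix(actual)
  if (ncol(m) != length(net$input_scaler$min))
    stop("expected ", length(net$input_scaler$min), " input columns")
  if (!all(is.finite(m))) stop("non-finite input")
  Xs <- scale_fwd(m, net$input_scaler)
  Ys <- net_forward(net$weights, Xs)$Y
  out <- scale_inv(Ys, net$output_scaler)
  colnames(out) <- net$responses
  if (vec) out[1, ] else out
}

#' Serialize a surrogate network to JSON
#'
#' Stores scalers, weight matrices and training metadata at full
#' precision; `read_net_json()` reconstructs an equivalent predictor.
#'
#' @param net A `surrogate_net`.
#' @param path JSON file path.
#' @return `path` (write) or a `surrogate_net` (read).
#' @export
write_net_json <- function(net, path) {
  x <- list(
    hidden_units = net$hidden_units, responses = net$responses,
    seed = net$seed, algorithm = net$algorithm, best_epoch = net$best_epoch,
    input_scaler = net$input_scaler, output_scaler = net$output_scaler,
    W1 = net$weights$W1, b1 = net$weights$b1,
    W2 = net$weights$W2, b2 = net$weights$b2
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_net_json
#' @export
read_net_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(weights = list(W1 = as.matrix(x$W1), b1 = as.numeric(x$b1),
                        W2 = as.matrix(x$W2), b2 = as.numeric(x$b2)),
         input_scaler = lapply(x$input_scaler, as.numeric),
         output_scaler = lapply(x$output_scaler, as.numeric),
         responses = as.character(x$responses), factors = default_factors(),
         hidden_units = x$hidden_units, seed = x$seed,
         algorithm = x$algorithm, best_epoch = x$best_epoch,
         split = NULL, training_log = NULL),
    class = "surrogate_net"
  )
}
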