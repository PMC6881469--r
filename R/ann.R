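#' Network and training configuration
#'
#' Settings for the multilayer perceptron and its Levenberg-Marquardt
#' trainer. The reference architecture is 3 inputs (one per bacterial
#' channel), 12 hidden neurons (one per pollutant) with hyperbolic-tangent
#' activation, and 6 log-sigmoid outputs forming the binary codeword.
#'
#' The reference training protocol runs for up to 250,000 epochs with an MSE
#' goal of 1e-10; the operative stopping rule at that goal is the MSE
#' criterion, not the epoch cap. The default desk-scale epoch cap is 2,000,
#' which is ample for the damped Gauss-Newton steps to converge on datasets
#' of this size; the full-scale cap remains available via `max_epochs`.
#'
#' @param n_input,n_hidden,n_output Layer sizes.
#' @param max_epochs Epoch cap; one epoch is one full-batch
#'   Levenberg-Marquardt iteration (Jacobian evaluation plus the inner
#'   damping search that ends in an accepted step).
#' @param mse_goal Stop once the mean squared error falls to this value.
#' @param lambda_init Initial damping factor.
#' @param lambda_up,lambda_down Multiplicative damping increase on a rejected
#'   step and decrease on an accepted step.
#' @param lambda_max Damping overflow limit; training stops (converged) when
#'   the damping exceeds it.
#' @param init_range Half-width of the uniform weight initialization
#'   `U(-init_range, init_range)`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(n_input = 3, n_hidden = 12, n_output = 6,
                       max_epochs = 2000, mse_goal = 1e-10,
                       lambda_init = 1e-3, lambda_up = 10, lambda_down = 10,
                       lambda_max = 1e10, init_range = 0.5, seed = 1) {
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1,
            max_epochs >= 1, mse_goal > 0,
            lambda_init > 0, lambda_up > 1, lambda_down > 1, lambda_max > 0,
            init_range > 0)
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output), max_epochs = as.integer(max_epochs),
                 mse_goal = mse_goal, lambda_init = lambda_init,
                 lambda_up = lambda_up, lambda_down = lambda_down,
                 lambda_max = lambda_max, init_range = init_range,
                 seed = as.integer(seed)),
            class = "ann_config")
}

n_params <- function(cfg) {
  cfg$n_hidden * cfg$n_input + cfg$n_hidden +
    cfg$n_output * cfg$n_hidden + cfg$n_output
}

# Pack/unpack the weight vector: W1 (n_hidden x n_input, row-major by
# as.vector of the matrix), b1, W2 (n_output x n_hidden), b2.
unpack_weights <- function(w, cfg) {
  ni <- cfg$n_input; nh <- cfg$n_hidden; no <- cfg$n_output
  i <- 0L
  W1 <- matrix(w[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  b1 <- w[i + seq_len(nh)]; i <- i + nh
  W2 <- matrix(w[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  b2 <- w[i + seq_len(no)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

pack_weights <- function(wl) {
  c(as.vector(wl$W1), wl$b1, as.vector(wl$W2), wl$b2)
}

init_weights <- function(cfg) {
  with_seed(cfg$seed, stats::runif(n_params(cfg), -cfg$init_range, cfg$init_range))
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Forward pass of the perceptron
#'
#' Computes `output = logsig(W2 %*% tanh(W1 %*% x + b1) + b2)` for each input
#' row. Outputs are strictly inside (0, 1) by the log-sigmoid.
#'
#' @param weights A weight vector (as stored in a fitted model) or the list
#'   returned by the internal unpacker; a fitted `sensor_ann` object is also
#'   accepted.
#' @param x Input matrix (one row per sample) or a single input vector.
#' @param config An [ann_config()]; taken from the model when `weights` is a
#'   `sensor_ann`.
#' @return A list with `hidden` (N x n_hidden activations) and `output`
#'   (N x n_output values in (0, 1)).
#' @export
ann_forward <- function(weights, x, config = NULL) {
  if (inherits(weights, "sensor_ann")) {
    config <- weights$config
    weights <- weights$weights
  }
  if (is.null(config)) stop("config required when weights is a bare vector")
  wl <- if (is.list(weights)) weights else unpack_weights(weights, config)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != config$n_input)
    stop("input has ", ncol(x), " columns; network expects ", config$n_input)
  H <- tanh(sweep(x %*% t(wl$W1), 2, wl$b1, "+"))
  O <- logistic(sweep(H %*% t(wl$W2), 2, wl$b2, "+"))
  list(hidden = H, output = O)
}

# Jacobian of the stacked network outputs with respect to the weight vector,
# by backpropagation. Residuals/outputs are stacked output-major: rows of J
# are ordered (output k = 1..no) x (sample n = 1..N), i.e. row (k-1)*N + n.
# Returns list(J, output).
ann_jacobian <- function(w, X, cfg) {
  wl <- unpack_weights(w, cfg)
  N <- nrow(X); ni <- cfg$n_input; nh <- cfg$n_hidden; no <- cfg$n_output
  fw <- ann_forward(wl, X, cfg)
  H <- fw$hidden; O <- fw$output
  S2 <- O * (1 - O)          # d logistic
  D1 <- 1 - H^2              # d tanh
  np <- n_params(cfg)
  J <- matrix(0, N * no, np)
  c_W1 <- seq_len(nh * ni)
  c_b1 <- nh * ni + seq_len(nh)
  c_W2 <- nh * ni + nh + seq_len(no * nh)
  c_b2 <- nh * ni + nh + no * nh + seq_len(no)
  for (k in seq_len(no)) {
    rows <- (k - 1L) * N + seq_len(N)
    sk <- S2[, k]                                  # N
    # output-layer weights W2[k, j] and bias b2[k]
    Jk_W2 <- matrix(0, N, no * nh)
    Jk_W2[, (seq_len(nh) - 1L) * no + k] <- sk * H # W2 stored column-major (no x nh)
    J[rows, c_W2] <- Jk_W2
    J[rows, c_b2[k]] <- sk
    # hidden layer: G[n, j] = sk * W2[k, j] * (1 - H^2)
    G <- sk * sweep(D1, 2, wl$W2[k, ], "*")        # N x nh
    # W1[j, i] stored column-major (nh x ni): column index (i-1)*nh + j
    J[rows, c_W1] <- G[, rep(seq_len(nh), times = ni)] *
      X[, rep(seq_len(ni), each = nh)]
    J[rows, c_b1] <- G
  }
  list(J = J, output = O)
}

#' Train a perceptron by the Levenberg-Marquardt algorithm
#'
#' Low-level trainer for an `n_input`-`n_hidden`-`n_output` network with
#' tanh hidden and log-sigmoid output activations, minimizing the mean
#' squared error against 0/1 targets. Each epoch evaluates the full-batch
#' residual `e` and its Jacobian `J` at the current weights and solves the
#' damped normal equations \eqn{(J^T J + \lambda I)\,\delta = J^T e}. A step
#' is accepted only if it lowers the MSE, upon which the damping is divided
#' by `lambda_down`; otherwise the damping is multiplied by `lambda_up` and
#' the step is re-solved within the same epoch (the classical inner damping
#' search). Training stops at the MSE goal, the epoch cap, or when the
#' damping overflows `lambda_max` without finding a descent step (a local
#' minimum), and returns the best-MSE weights seen.
#'
#' @param X Input matrix (N x n_input).
#' @param Y Target matrix (N x n_output) of 0/1 codeword bits.
#' @param config An [ann_config()] whose layer sizes match `X` and `Y`.
#' @return A list with `weights` (best weight vector), `mse` (final MSE),
#'   `history` (MSE after each accepted step, strictly decreasing),
#'   `epochs` (step attempts used), `stop_reason` (`"mse_goal"`,
#'   `"max_epochs"` or `"lambda_overflow"`), and `config`.
#' @examples
#' # XOR with a 2-2-1 network
#' X <- rbind(c(0,0), c(0,1), c(1,0), c(1,1))
#' Y <- matrix(c(0, 1, 1, 0), ncol = 1)
#' fit <- train_lm(X, Y, ann_config(n_input = 2, n_hidden = 2, n_output = 1,
#'                                  max_epochs = 200, seed = 0))
#' fit$mse
#' @export
train_lm <- function(X, Y, config = ann_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 1) stop("dataset is empty")
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ")
  if (ncol(X) != config$n_input || ncol(Y) != config$n_output)
    stop("data dimensions do not match the network configuration")
  w <- init_weights(config)
  lam <- config$lambda_init
  jb <- ann_jacobian(w, X, config)
  e <- as.vector(Y) - as.vector(jb$output)   # both stacked output-major
  mse <- mean(e^2)
  JtJ <- crossprod(jb$J)
  Jte <- crossprod(jb$J, e)
  history <- numeric(0)
  epoch <- 0L
  stop_reason <- "max_epochs"
  np <- n_params(config)
  while (epoch < config$max_epochs) {
    if (mse <= config$mse_goal) { stop_reason <- "mse_goal"; break }
    epoch <- epoch + 1L
    accepted <- FALSE
    # inner damping search: raise lambda until a descent step is found
    while (lam <= config$lambda_max) {
      delta <- tryCatch(
        solve(JtJ + diag(lam, np), Jte),
        error = function(err) NULL)
      if (is.null(delta)) {
        if (lam * config$lambda_up > config$lambda_max)
          stop("Levenberg-Marquardt normal equations singular at damping ", lam,
               " (epoch ", epoch, ", mse ", signif(mse, 6), ")")
        lam <- lam * config$lambda_up
        next
      }
      w_try <- w + as.vector(delta)
      o_try <- ann_forward(w_try, X, config)$output
      e_try <- as.vector(Y) - as.vector(o_try)
      mse_try <- mean(e_try^2)
      if (mse_try < mse) {
        w <- w_try
        mse <- mse_try
        e <- e_try
        history <- c(history, mse)
        lam <- lam / config$lambda_down
        jb <- ann_jacobian(w, X, config)
        JtJ <- crossprod(jb$J)
        Jte <- crossprod(jb$J, e)
        accepted <- TRUE
        break
      }
      lam <- lam * config$lambda_up
    }
    if (!accepted) { stop_reason <- "lambda_overflow"; break }
  }
  if (mse <= config$mse_goal) stop_reason <- "mse_goal"
  list(weights = w, mse = mse, history = history, epochs = epoch,
       stop_reason = stop_reason, config = config)
}
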