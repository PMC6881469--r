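#' Fit the pollutant-identification network to labeled sensor responses
#'
#' Trains the 3-12-6 perceptron on a labeled response dataset: the three
#' normalized channel responses are the inputs, and the 6-bit codeword of the
#' sample's (pollutant, quantized concentration) class is the 0/1 regression
#' target. Training uses the full-batch Levenberg-Marquardt algorithm (see
#' [train_lm()]). Inputs are fed unscaled: the responses are already
#' dimensionless quantities of order one.
#'
#' @param data A data frame with channel columns `e_coli`, `m_capsulatus`,
#'   `s_oneidensis`, a `pollutant` column, and either a `level_uM` column of
#'   grid levels or a `concentration_uM` column of true concentrations (which
#'   are quantized to the grid with [quantize_concentration()]). Typically
#'   produced by [generate_dataset()] or [read_dataset_csv()].
#' @param config An [ann_config()]; layer sizes must remain 3-x-6.
#' @return An object of class `sensor_ann`: a list with `weights`, `config`,
#'   `mse`, `history`, `epochs`, `stop_reason`, and the `training` data used.
#' @seealso [predict.sensor_ann()], [evaluate_calls()]
#' @examples
#' \donttest{
#' train <- generate_dataset(n_per_class = 5, noise_cv = 0.10, seed = 42)
#' net <- ann_fit(train, ann_config(max_epochs = 300, seed = 1))
#' predict(net, train[1:3, ])
#' }
#' @export
ann_fit <- function(data, config = ann_config()) {
  if (config$n_input != 3 || config$n_output != 6)
    stop("the sensor network has 3 inputs and 6 outputs")
  X <- response_matrix(data)
  lev <- if ("level_uM" %in% names(data)) data$level_uM
         else if ("concentration_uM" %in% names(data))
           quantize_concentration(data$concentration_uM)
         else stop("data must carry a level_uM or concentration_uM column")
  if (!"pollutant" %in% names(data)) stop("data must carry a pollutant column")
  codes <- encode_class(data$pollutant, lev)
  Y <- codeword_bits(codes)
  fit <- train_lm(X, Y, config)
  structure(list(weights = fit$weights, config = config, mse = fit$mse,
                 history = fit$history, epochs = fit$epochs,
                 stop_reason = fit$stop_reason,
                 training = data, call = match.call()),
            class = "sensor_ann")
}

# data frame (or matrix) -> N x 3 response matrix in channel order
response_matrix <- function(data) {
  ch <- channel_names()
  if (is.matrix(data)) {
    if (ncol(data) != 3) stop("response matrix must have 3 columns")
    return(unname(data))
  }
  miss <- setdiff(ch, names(data))
  if (length(miss))
    stop("data is missing channel column(s): ", paste(miss, collapse = ", "))
  as.matrix(data[, ch])
}

# codeword strings -> N x 6 0/1 matrix
codeword_bits <- function(codes) {
  t(vapply(strsplit(codes, ""), function(b) as.integer(b), integer(6)))
}

#' @export
print.sensor_ann <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Sensor-array pollutant network (%d-%d-%d, tanh/log-sigmoid)\n",
              cfg$n_input, cfg$n_hidden, cfg$n_output))
  cat(sprintf("  trained on %d samples, %d epochs (%s)\n",
              nrow(x$training), x$epochs, x$stop_reason))
  cat(sprintf("  final MSE: %.4g\n", x$mse))
  invisible(x)
}

#' @export
summary.sensor_ann <- function(object, ...) {
  calls <- predict(object, object$training)
  truth_lev <- if ("level_uM" %in% names(object$training)) object$training$level_uM
               else quantize_concentration(object$training$concentration_uM)
  acc <- mean(calls$pollutant == object$training$pollutant)
  lacc <- mean(calls$level_uM == truth_lev)
  out <- list(config = object$config, mse = object$mse, epochs = object$epochs,
              stop_reason = object$stop_reason,
              n_train = nrow(object$training),
              training_pollutant_accuracy = acc,
              training_level_accuracy = lacc)
  class(out) <- "summary.sensor_ann"
  out
}

#' @export
print.summary.sensor_ann <- function(x, ...) {
  cat(sprintf("Sensor-array pollutant network (%d-%d-%d)\n",
              x$config$n_input, x$config$n_hidden, x$config$n_output))
  cat(sprintf("  %d training samples; %d epochs (%s); final MSE %.4g\n",
              x$n_train, x$epochs, x$stop_reason, x$mse))
  cat(sprintf("  training-set pollutant accuracy: %.1f%%\n",
              100 * x$training_pollutant_accuracy))
  cat(sprintf("  training-set level accuracy:     %.1f%%\n",
              100 * x$training_level_accuracy))
  invisible(x)
}

#' @export
coef.sensor_ann <- function(object, ...) {
  unpack_weights(object$weights, object$config)
}

#' Predict pollutant calls from sensor responses
#'
#' Runs the forward pass on each response triple and decodes the six
#' continuous outputs into a pollutant call: thresholding at 0.5 gives a
#' bitstring, mapped to the nearest valid codeword (Hamming distance, ties to
#' the smallest code integer).
#'
#' @param object A fitted `sensor_ann`.
#' @param newdata Data frame with the three channel columns, or an N x 3
#'   matrix; defaults to the training data.
#' @param ... Unused.
#' @return A data frame of calls: `codeword`, `pollutant`, `group`,
#'   `level_uM` and the raw outputs `raw_1` .. `raw_6`.
#' @export
predict.sensor_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training
  X <- response_matrix(newdata)
  O <- ann_forward(object, X)$output
  decode_output(O)
}

#' @export
fitted.sensor_ann <- function(object, ...) {
  ann_forward(object, response_matrix(object$training))$output
}

#' Residuals of the fitted network
#'
#' The 0/1 codeword targets of the training samples minus the network's
#' continuous outputs, as an N x 6 matrix.
#'
#' @param object A fitted `sensor_ann`.
#' @param ... Unused.
#' @export
residuals.sensor_ann <- function(object, ...) {
  data <- object$training
  lev <- if ("level_uM" %in% names(data)) data$level_uM
         else quantize_concentration(data$concentration_uM)
  Y <- codeword_bits(encode_class(data$pollutant, lev))
  Y - fitted(object)
}

#' Plot the training history
#'
#' Mean squared error after each accepted Levenberg-Marquardt step, on a log
#' scale.
#'
#' @param x A fitted `sensor_ann`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sensor_ann <- function(x, ...) {
  if (!length(x$history)) {
    warning("no accepted steps to plot")
    return(invisible(x))
  }
  graphics::plot(seq_along(x$history), x$history, type = "l", log = "y",
                 xlab = "accepted step", ylab = "MSE",
                 main = "Levenberg-Marquardt training history", ...)
  invisible(x)
}
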