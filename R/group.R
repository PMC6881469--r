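#' Fit group centroids for coarse pollutant screening
#'
#' The pseudo-3D screening stage: in the 3-channel response space the three
#' pollutant groups (heavy metals, pesticides, petrochemicals) occupy
#' distinct regions, so a sample can be coarsely classified by the nearest
#' per-group centroid. The highest concentration level (1 mM) is excluded by
#' default before fitting, because at that level all three bacteria are
#' strongly inhibited and the groups collapse together.
#'
#' @param data Labeled samples: a data frame with the three channel columns
#'   plus `pollutant` (and `level_uM` or `concentration_uM`, used only for
#'   the top-level exclusion).
#' @param exclude_top_level Drop samples at the 1000 uM level before fitting.
#' @return An object of class `group_model`: list with `centroids` (3 x 3
#'   matrix, one row per group in fixed order heavy_metals, pesticides,
#'   petrochemicals), `groups`, and the pollutant-to-group `membership` map.
#' @export
fit_group_centroids <- function(data, exclude_top_level = TRUE) {
  reg <- pollutant_registry()
  if (!"pollutant" %in% names(data)) stop("data must carry a pollutant column")
  X <- response_matrix(data)
  grp <- reg$group[match(data$pollutant, reg$pollutant)]
  if (anyNA(grp)) stop("data contains unregistered pollutant names")
  keep <- rep(TRUE, nrow(data))
  if (exclude_top_level) {
    lev <- if ("level_uM" %in% names(data)) data$level_uM
           else if ("concentration_uM" %in% names(data))
             quantize_concentration(data$concentration_uM)
           else rep(NA_real_, nrow(data))
    keep <- is.na(lev) | lev < 1000
  }
  groups <- c("heavy_metals", "pesticides", "petrochemicals")
  cent <- matrix(NA_real_, 3, 3, dimnames = list(groups, channel_names()))
  for (g in groups) {
    idx <- keep & grp == g
    if (!any(idx)) stop("no samples left in group '", g, "' after exclusion")
    cent[g, ] <- colMeans(X[idx, , drop = FALSE])
  }
  structure(list(centroids = cent, groups = groups,
                 membership = stats::setNames(reg$group, reg$pollutant)),
            class = "group_model")
}

#' @export
print.group_model <- function(x, ...) {
  cat("Pollutant-group centroid model (nearest centroid in response space)\n")
  print(round(x$centroids, 4))
  invisible(x)
}

#' Classify responses into pollutant groups
#'
#' Assigns each 3-channel response to the group of its nearest centroid
#' (Euclidean distance); exact ties break by the fixed group order
#' heavy_metals < pesticides < petrochemicals.
#'
#' @param model A fitted [fit_group_centroids()] model.
#' @param response A data frame with the channel columns, an N x 3 matrix, or
#'   a single response vector of length 3.
#' @return Character vector of group labels.
#' @export
classify_group <- function(model, response) {
  if (!inherits(model, "group_model")) stop("model must be a group_model")
  if (is.null(dim(response)) && is.numeric(response))
    response <- matrix(response, nrow = 1)
  X <- response_matrix(response)
  d <- vapply(model$groups, function(g)
    rowSums(sweep(X, 2, model$centroids[g, ])^2), numeric(nrow(X)))
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  # max.col(-d, "first") => first minimum: ties break by fixed group order
  model$groups[max.col(-d, ties.method = "first")]
}

#' @export
predict.group_model <- function(object, newdata, ...) {
  classify_group(object, newdata)
}

#' Evaluate pollutant calls against ground truth
#'
#' Compares decoded pollutant calls with the true labels and reports identity,
#' group and concentration-level accuracies plus a 12 x 12 pollutant
#' confusion table (rows: truth, columns: call).
#'
#' @param calls A data frame of calls with `pollutant` and `level_uM` columns
#'   (as returned by [predict.sensor_ann()]).
#' @param truth A data frame with true `pollutant` and `level_uM` (or
#'   `concentration_uM`, quantized to the grid) columns, the same length.
#' @return An object of class `sensor_eval`: list with `pollutant_accuracy`,
#'   `group_accuracy`, `level_accuracy`, `n`, and `confusion`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (nrow(calls) != nrow(truth))
    stop("calls and truth have different lengths (", nrow(calls), " vs ",
         nrow(truth), ")")
  reg <- pollutant_registry()
  truth_lev <- if ("level_uM" %in% names(truth)) truth$level_uM
               else quantize_concentration(truth$concentration_uM)
  tg <- reg$group[match(truth$pollutant, reg$pollutant)]
  cg <- reg$group[match(calls$pollutant, reg$pollutant)]
  lv <- factor(truth$pollutant, levels = reg$pollutant)
  lc <- factor(calls$pollutant, levels = reg$pollutant)
  structure(list(
    pollutant_accuracy = mean(calls$pollutant == truth$pollutant),
    group_accuracy = mean(cg == tg),
    level_accuracy = mean(calls$level_uM == truth_lev),
    n = nrow(calls),
    confusion = table(truth = lv, call = lc)
  ), class = "sensor_eval")
}

#' @export
print.sensor_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d samples\n", x$n))
  cat(sprintf("  pollutant identity accuracy: %.1f%%\n", 100 * x$pollutant_accuracy))
  cat(sprintf("  pollutant group accuracy:    %.1f%%\n", 100 * x$group_accuracy))
  cat(sprintf("  concentration level accuracy: %.1f%%\n", 100 * x$level_accuracy))
  invisible(x)
}
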