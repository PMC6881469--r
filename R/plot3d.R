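#' Pseudo-3D scatter of the three sensing channels
#'
#' Draws the classic screening view: each sample's three-channel response as
#' a point in 3D, one axis per bacterial channel, colored by pollutant group.
#' Heavy metals, pesticides and petrochemicals fall into distinct regions of
#' this space (the direction of increasing concentration points away from the
#' origin). The projection is a fixed-viewpoint perspective rendered with
#' base graphics, so vector output is deterministic for fixed data and style.
#'
#' @param data A data frame with the channel columns `e_coli`,
#'   `m_capsulatus`, `s_oneidensis` and optionally `pollutant` (used for
#'   group coloring). May have zero rows, in which case only axes are drawn.
#' @param path Optional output file; extension `.svg` or `.pdf` selects the
#'   device. `NULL` draws on the current device.
#' @param theta,phi Viewing angles in degrees (azimuth, colatitude).
#' @param main Plot title.
#' @return Invisibly, the number of points drawn.
#' @export
plot_response_3d <- function(data, path = NULL, theta = 40, phi = 20,
                             main = "Sensor-array responses") {
  reg <- pollutant_registry()
  n <- nrow(data)
  cols <- rep("grey30", n)
  grp <- NULL
  if (n > 0 && "pollutant" %in% names(data)) {
    grp <- reg$group[match(data$pollutant, reg$pollutant)]
    pal <- c(heavy_metals = "blue", pesticides = "darkgreen",
             petrochemicals = "red")
    cols <- unname(pal[grp])
  }
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    if (ext == "svg") grDevices::svg(path, width = 7, height = 6)
    else if (ext == "pdf") grDevices::pdf(path, width = 7, height = 6)
    else stop("unsupported figure format: ", ext)
    on.exit(grDevices::dev.off())
  }
  lim <- if (n > 0) {
    X <- response_matrix(data)
    range(0, X)
  } else c(0, 1)
  # empty persp box supplies the 3D projection matrix
  pmat <- graphics::persp(lim, lim, matrix(lim[1], 2, 2), zlim = lim,
                          theta = theta, phi = phi, expand = 0.8,
                          border = NA, col = NA, box = TRUE, axes = TRUE,
                          ticktype = "detailed",
                          xlab = "E. coli", ylab = "M. capsulatus",
                          zlab = "S. oneidensis", main = main)
  if (n > 0) {
    X <- response_matrix(data)
    pt <- grDevices::trans3d(X[, 1], X[, 2], X[, 3], pmat)
    graphics::points(pt, pch = 19, col = cols, cex = 0.8)
    if (!is.null(grp))
      graphics::legend("topleft", legend = names(table(grp)), bty = "n",
                       col = c(heavy_metals = "blue", pesticides = "darkgreen",
                               petrochemicals = "red")[names(table(grp))],
                       pch = 19, cex = 0.8)
  }
  invisible(n)
}
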