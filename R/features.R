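#' Read the anodic current from a cyclic voltammogram
#'
#' Returns the current on the anodic (increasing-potential) branch at the
#' requested potential, linearly interpolated between the two bracketing
#' samples; exact when a sample sits on the potential. The default read
#' potential of +0.5 V is the sweep limit at which the inhibition response is
#' evaluated.
#'
#' @param scan A CV scan data frame with columns `potential_V`, `current_uA`,
#'   `branch` (as produced by [simulate_cv()] or [read_cv_csv()]).
#' @param potential_V Read potential (V); must lie within the anodic branch's
#'   range.
#' @return Current in uA (length 1).
#' @export
anodic_current <- function(scan, potential_V = 0.5) {
  need <- c("potential_V", "current_uA", "branch")
  miss <- setdiff(need, names(scan))
  if (length(miss))
    stop("scan is missing column(s): ", paste(miss, collapse = ", "))
  an <- scan[scan$branch == "anodic", ]
  if (nrow(an) < 1) stop("scan has no anodic branch")
  if (potential_V < min(an$potential_V) || potential_V > max(an$potential_V))
    stop("potential ", potential_V, " V lies outside the anodic sweep range [",
         min(an$potential_V), ", ", max(an$potential_V), "] V")
  an <- an[order(an$potential_V), ]
  stats::approx(an$potential_V, an$current_uA, xout = potential_V, ties = mean)$y
}

#' Normalized inhibition response
#'
#' The relative change of the anodic current against the pollutant-free
#' reference: \deqn{\Delta I_A / I_{A0} = (I_A - I_{A0}) / I_{A0}}
#' This is the per-channel statistic fed to the classifier; it rises as
#' pollutant-damaged bacteria lose their insulating ability.
#'
#' @param I_A Anodic current after pollutant exposure (uA); vectorized.
#' @param I_A0 Reference anodic current in pollutant-free buffer (uA, > 0).
#' @return `(I_A - I_A0) / I_A0`, dimensionless.
#' @export
relative_change <- function(I_A, I_A0) {
  if (any(!is.finite(I_A0)) || any(I_A0 <= 0))
    stop("reference current I_A0 must be strictly positive")
  (I_A - I_A0) / I_A0
}

#' Fit the equivalent circuit to an impedance spectrum
#'
#' Estimates the electrolyte resistance `R_el`, double-layer resistance
#' `R_db` and double-layer capacitance `C_db` of the series-R / parallel-RC
#' circuit from Nyquist data. Initial estimates come from the circuit's
#' limiting behavior — `R_el` from the highest-frequency `Z_re`, `R_db` from
#' the low-frequency `Z_re` minus `R_el`, and `C_db` from the apex frequency
#' of the semicircle via `C_db = 1/(omega_apex * R_db)` — and are refined by
#' damped nonlinear least squares on the stacked real and imaginary residuals
#' with unit weights. Parameters are optimized on the log scale, which keeps
#' them strictly positive.
#'
#' @param spectrum An impedance spectrum data frame with columns
#'   `frequency_Hz`, `z_re_ohm`, `z_im_ohm`.
#' @return An object of class `circuit_fit`: a list with elements
#'   `R_el_ohm`, `R_db_ohm`, `C_db_F`, `initial` (the pre-refinement
#'   estimates), `rss` and `rss_initial` (residual sums of squares), and
#'   `converged`.
#' @examples
#' sp <- simulate_impedance(100, 1e4, 1e-6)
#' fit_equivalent_circuit(sp)
#' @export
fit_equivalent_circuit <- function(spectrum) {
  need <- c("frequency_Hz", "z_re_ohm", "z_im_ohm")
  miss <- setdiff(need, names(spectrum))
  if (length(miss))
    stop("spectrum is missing column(s): ", paste(miss, collapse = ", "))
  sp <- spectrum[order(spectrum$frequency_Hz), ]
  f <- sp$frequency_Hz
  if (log10(max(f) / min(f)) < 2)
    stop("spectrum must span at least two frequency decades")
  # initial estimates from the limiting behavior
  R_el0 <- max(sp$z_re_ohm[which.max(f)], .Machine$double.eps)
  R_db0 <- max(sp$z_re_ohm[which.min(f)] - R_el0, .Machine$double.eps)
  i_apex <- which.max(-sp$z_im_ohm)
  if (i_apex == 1L || i_apex == nrow(sp))
    stop("sweep does not bracket the semicircle apex")
  C_db0 <- 1 / (2 * pi * f[i_apex] * R_db0)
  init <- c(R_el_ohm = R_el0, R_db_ohm = R_db0, C_db_F = C_db0)

  resid_fn <- function(logp) {
    p <- exp(logp)
    z <- circuit_impedance(p[1], p[2], p[3], f)
    c(Re(z) - sp$z_re_ohm, Im(z) - sp$z_im_ohm)
  }
  rss_initial <- sum(resid_fn(log(init))^2)
  fit <- minpack.lm::nls.lm(par = log(init), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- exp(fit$par)
  rss <- sum(resid_fn(fit$par)^2)
  if (rss > rss_initial) {   # refinement must never degrade the fit
    p <- init
    rss <- rss_initial
  }
  structure(list(R_el_ohm = unname(p[1]), R_db_ohm = unname(p[2]),
                 C_db_F = unname(p[3]), initial = init,
                 rss = rss, rss_initial = rss_initial,
                 converged = fit$info %in% 1:4),
            class = "circuit_fit")
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("Equivalent-circuit fit (R_el + R_db || C_db)\n")
  cat(sprintf("  R_el = %.6g ohm\n  R_db = %.6g ohm\n  C_db = %.6g F\n",
              x$R_el_ohm, x$R_db_ohm, x$C_db_F))
  cat(sprintf("  residual SS: %.4g (initial %.4g)\n", x$rss, x$rss_initial))
  invisible(x)
}
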