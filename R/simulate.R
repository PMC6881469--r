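# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and a stream label, so that
# independent draws (channels, datasets) come from decoupled streams.
sub_seed <- function(seed, stream) {
  s <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 69069 + s * 12345) %% 2147483647)
}

#' Bare-electrode cyclic-voltammogram baseline profile
#'
#' Describes the current profile of an uncoated screen-printed gold electrode
#' in phosphate buffer: Gaussian-shaped anodic and cathodic redox peaks over a
#' linear capacitive background. Default peak positions follow the
#' characteristic PBS electrochemistry on gold: an anodic peak near +0.35 V
#' and a cathodic peak near -0.15 V.
#'
#' @param anodic_peak_V,cathodic_peak_V Peak center potentials (V).
#' @param anodic_peak_uA,cathodic_peak_uA Peak amplitudes (uA, positive).
#' @param capacitive_uA Half-width of the capacitive current envelope (uA):
#'   the anodic branch is offset by `+capacitive_uA`, the cathodic branch by
#'   `-capacitive_uA`.
#' @param slope_uA_per_V Linear background slope (uA/V).
#' @param peak_width_V Gaussian peak standard deviation (V).
#' @return An object of class `cv_baseline` (a parameter list).
#' @export
cv_baseline <- function(anodic_peak_V = 0.35, cathodic_peak_V = -0.15,
                        anodic_peak_uA = 30, cathodic_peak_uA = 20,
                        capacitive_uA = 5, slope_uA_per_V = 10,
                        peak_width_V = 0.08) {
  stopifnot(anodic_peak_uA > 0, cathodic_peak_uA > 0, peak_width_V > 0)
  structure(list(anodic_peak_V = anodic_peak_V, cathodic_peak_V = cathodic_peak_V,
                 anodic_peak_uA = anodic_peak_uA, cathodic_peak_uA = cathodic_peak_uA,
                 capacitive_uA = capacitive_uA, slope_uA_per_V = slope_uA_per_V,
                 peak_width_V = peak_width_V),
            class = "cv_baseline")
}

# Baseline current (uA) at potential v on a given branch.
baseline_current <- function(baseline, v, branch) {
  g <- function(v0) exp(-(v - v0)^2 / (2 * baseline$peak_width_V^2))
  bg <- baseline$slope_uA_per_V * v
  ifelse(branch == "anodic",
         bg + baseline$capacitive_uA + baseline$anodic_peak_uA * g(baseline$anodic_peak_V),
         bg - baseline$capacitive_uA - baseline$cathodic_peak_uA * g(baseline$cathodic_peak_V))
}

#' Simulate a cyclic voltammogram of a bacteria-coated electrode
#'
#' Generates a two-branch potential sweep over -0.5 .. +0.5 V whose current is
#' the bare-electrode baseline shape scaled by
#' `coverage_attenuation * (1 + response_scale)`. The attenuation models the
#' insulating bacterial layer (immobilized bacteria reduce the DC current
#' roughly threefold); `response_scale` models the fractional current recovery
#' when pollutants damage the bacteria and degrade their insulation, so that
#' reading the anodic current at +0.5 V and normalizing against the
#' `response_scale = 0` trace returns `response_scale` exactly.
#'
#' @param baseline A [cv_baseline()] profile.
#' @param coverage_attenuation Multiplicative current attenuation of the
#'   bacterial coating, in (0, 1]. 1 means a bare electrode.
#' @param response_scale Fractional inhibition response (>= -1).
#' @param scan_rate_mV_s Sweep rate (mV/s), recorded in the output.
#' @param step_mV Potential step between samples (mV).
#' @param noise_cv Optional multiplicative Gaussian noise coefficient of
#'   variation applied to the current (default 0: deterministic).
#' @param seed Optional integer seed for the noise draw.
#' @return A data frame of class `cv_scan` with columns `potential_V`,
#'   `current_uA`, `branch` (`"anodic"` for the increasing-potential leg,
#'   `"cathodic"` for the return leg), plus attribute `scan_rate_mV_s`.
#' @export
simulate_cv <- function(baseline = cv_baseline(), coverage_attenuation = 1,
                        response_scale = 0, scan_rate_mV_s = 10, step_mV = 5,
                        noise_cv = 0, seed = NULL) {
  if (!inherits(baseline, "cv_baseline")) stop("baseline must be a cv_baseline object")
  if (!is.finite(coverage_attenuation) || coverage_attenuation <= 0 ||
      coverage_attenuation > 1)
    stop("coverage_attenuation must lie in (0, 1]")
  if (response_scale < -1) stop("response_scale must be >= -1")
  if (scan_rate_mV_s <= 0) stop("scan_rate must be positive")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  v_up <- seq(-0.5, 0.5, by = step_mV / 1000)
  v_down <- rev(v_up)
  pot <- c(v_up, v_down)
  branch <- rep(c("anodic", "cathodic"), c(length(v_up), length(v_down)))
  cur <- coverage_attenuation * (1 + response_scale) * baseline_current(baseline, pot, branch)
  if (noise_cv > 0)
    cur <- with_seed(seed, cur * (1 + stats::rnorm(length(cur), 0, noise_cv)))
  out <- data.frame(potential_V = pot, current_uA = cur, branch = branch,
                    stringsAsFactors = FALSE)
  attr(out, "scan_rate_mV_s") <- scan_rate_mV_s
  class(out) <- c("cv_scan", "data.frame")
  out
}

#' Default impedance frequency sweep
#'
#' Log-spaced frequency grid over the instrument's 100 mHz to 100 kHz range,
#' 50 points per decade by default (dense enough to resolve the Nyquist
#' semicircle apex).
#'
#' @param f_min_Hz,f_max_Hz Sweep limits (Hz).
#' @param points_per_decade Grid density.
#' @return Ascending numeric vector of frequencies (Hz).
#' @export
default_frequencies <- function(f_min_Hz = 0.1, f_max_Hz = 1e5,
                                points_per_decade = 50) {
  stopifnot(f_min_Hz > 0, f_max_Hz > f_min_Hz, points_per_decade >= 1)
  n_dec <- log10(f_max_Hz / f_min_Hz)
  10^seq(log10(f_min_Hz), log10(f_max_Hz), length.out = ceiling(n_dec * points_per_decade) + 1)
}

# Complex impedance of the series-R / parallel-RC equivalent circuit.
circuit_impedance <- function(R_el_ohm, R_db_ohm, C_db_F, frequency_Hz) {
  w <- 2 * pi * frequency_Hz
  R_el_ohm + R_db_ohm / (1 + 1i * w * R_db_ohm * C_db_F)
}

#' Simulate an electrochemical impedance spectrum
#'
#' Computes the impedance of the simplified equivalent circuit of a
#' bacteria-coated electrode — electrolyte resistance `R_el` in series with a
#' parallel double-layer resistance/capacitance pair (`R_db`, `C_db`):
#' \deqn{Z(\omega) = R_{el} + \frac{R_{db}}{1 + i\omega R_{db} C_{db}}}
#' The imaginary part is capacitive and therefore negative; Nyquist plots of
#' this circuit trace a semicircle of diameter `R_db` whose apex
#' (`-Z_im = R_db/2`) sits at `omega = 1/(R_db * C_db)`. Optional
#' multiplicative Gaussian noise is applied independently to the real and
#' imaginary parts.
#'
#' @param R_el_ohm,R_db_ohm Electrolyte and double-layer resistances (ohm).
#' @param C_db_F Double-layer capacitance (F).
#' @param frequencies Positive frequencies (Hz); default [default_frequencies()].
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Optional integer seed for the noise draw.
#' @return A data frame of class `impedance_spectrum` with columns
#'   `frequency_Hz`, `z_re_ohm`, `z_im_ohm` (negative for capacitive behavior).
#' @export
simulate_impedance <- function(R_el_ohm, R_db_ohm, C_db_F,
                               frequencies = default_frequencies(),
                               noise_cv = 0, seed = NULL) {
  if (any(c(R_el_ohm, R_db_ohm, C_db_F) <= 0) ||
      any(!is.finite(c(R_el_ohm, R_db_ohm, C_db_F))))
    stop("circuit parameters must be strictly positive")
  if (any(frequencies <= 0)) stop("frequencies must be strictly positive")
  if (is.unsorted(frequencies)) stop("frequencies must be ascending")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  z <- circuit_impedance(R_el_ohm, R_db_ohm, C_db_F, frequencies)
  zre <- Re(z); zim <- Im(z)
  if (noise_cv > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(2 * length(z), 0, noise_cv), ncol = 2))
    zre <- zre * (1 + noise[, 1])
    zim <- zim * (1 + noise[, 2])
  }
  out <- data.frame(frequency_Hz = frequencies, z_re_ohm = zre, z_im_ohm = zim)
  class(out) <- c("impedance_spectrum", "data.frame")
  out
}

#' Generate a labeled synthetic response dataset
#'
#' Emits `n_per_class` samples for each of the 60 (pollutant, level) classes.
#' Each sample's three-channel response is the noise-free mean from
#' [response_surface()] perturbed by independent multiplicative Gaussian noise
#' per channel, `response * (1 + eps)` with `eps ~ N(0, noise_cv)`, truncated
#' below at -1 (the anodic current cannot fall below zero). The default noise
#' level of 10% matches the stated reproducibility of the current and
#' impedance measurements.
#'
#' @param n_per_class Samples per class (>= 1).
#' @param noise_cv Multiplicative noise coefficient of variation (>= 0).
#' @param seed Optional integer seed; a fixed seed makes the dataset
#'   bit-reproducible.
#' @param concentration_jitter If `TRUE`, the true spiked concentration of
#'   each sample is drawn log-uniformly within a quarter-decade of its grid
#'   level (`10^U(-0.25, 0.25)` times the level) and the mean response is
#'   evaluated at the jittered concentration. If `FALSE` (default) all samples
#'   sit exactly on the grid.
#' @return A data frame with columns `e_coli`, `m_capsulatus`,
#'   `s_oneidensis`, `pollutant`, `concentration_uM` (the true spiked
#'   concentration) and `level_uM` (the grid level of the class).
#' @export
generate_dataset <- function(n_per_class = 1, noise_cv = 0.10, seed = NULL,
                             concentration_jitter = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  cb <- codebook()
  n <- nrow(cb) * n_per_class
  df <- data.frame(
    pollutant = rep(cb$pollutant, each = n_per_class),
    level_uM = rep(cb$level_uM, each = n_per_class),
    stringsAsFactors = FALSE
  )
  with_seed(if (is.null(seed)) NULL else sub_seed(seed, "dataset"), {
    conc <- if (concentration_jitter)
      df$level_uM * 10^stats::runif(n, -0.25, 0.25) else df$level_uM
    resp <- matrix(0, n, 3, dimnames = list(NULL, channel_names()))
    for (ch in channel_names()) {
      mu <- numeric(n)
      for (p in unique(df$pollutant)) {
        idx <- which(df$pollutant == p)
        mu[idx] <- response_surface(ch, p, conc[idx])
      }
      eps <- stats::rnorm(n, 0, noise_cv)
      resp[, ch] <- pmax(mu * (1 + eps), -1)
    }
    out <- data.frame(resp, pollutant = df$pollutant, concentration_uM = conc,
                      level_uM = df$level_uM, stringsAsFactors = FALSE)
    out
  })
}
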