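test_that("cv simulation scales the baseline shape", {
  bare <- simulate_cv(coverage_attenuation = 1, response_scale = 0)
  expect_s3_class(bare, "cv_scan")
  expect_true(all(bare$potential_V >= -0.5 & bare$potential_V <= 0.5))
  expect_setequal(unique(bare$branch), c("anodic", "cathodic"))
  # the insulating bacterial layer reduces the current threefold
  coated <- simulate_cv(coverage_attenuation = 1 / 3, response_scale = 0)
  expect_equal(coated$current_uA, bare$current_uA / 3)
  # identity scaling at attenuation 1, response 0: the +0.5 V read equals the
  # bare-electrode baseline value (exact node, +0.5 V is a sweep sample)
  prof <- cv_baseline()
  expect_equal(anodic_current(bare, 0.5),
               baseline_current(prof, 0.5, "anodic"))
})

test_that("extracting the +0.5 V response from a simulated scan returns response_scale", {
  ref <- simulate_cv(coverage_attenuation = 1 / 3, response_scale = 0)
  for (s in c(-0.2, 0, 0.37, 1.5)) {
    scan <- simulate_cv(coverage_attenuation = 1 / 3, response_scale = s)
    expect_equal(relative_change(anodic_current(scan), anodic_current(ref)), s)
  }
})

test_that("cv simulation validates its domain", {
  expect_error(simulate_cv(coverage_attenuation = 0), "0, 1")
  expect_error(simulate_cv(coverage_attenuation = 1.2), "0, 1")
  expect_error(simulate_cv(response_scale = -1.5), ">= -1")
})

test_that("impedance spectra obey the equivalent-circuit limits", {
  sp <- simulate_impedance(100, 1e4, 1e-6)
  # high-frequency limit: Z_re -> R_el; low-frequency: Z_re -> R_el + R_db
  expect_lt(abs(sp$z_re_ohm[nrow(sp)] - 100) / 100, 0.01)
  expect_lt(abs(sp$z_re_ohm[1] - 10100) / 10100, 0.01)
  # capacitive sign convention
  expect_true(all(sp$z_im_ohm < 0))
  # semicircle apex: max(-Z_im) = R_db/2 at omega = 1/(R_db C_db) = 100 rad/s
  expect_equal(max(-sp$z_im_ohm), 5000, tolerance = 1e-3)
  f_apex <- sp$frequency_Hz[which.max(-sp$z_im_ohm)]
  expect_equal(2 * pi * f_apex, 100, tolerance = 0.05)
})

test_that("impedance limits hold across circuit parameters on the default sweep", {
  # limiting-value checks require the RC corner frequency to sit well inside
  # the 0.1 Hz - 100 kHz sweep; these time constants (1 ms - 0.1 s) do
  for (R_el in c(10, 100)) for (R_db in c(1e3, 1e4)) for (C_db in c(1e-6, 1e-5)) {
    sp <- simulate_impedance(R_el, R_db, C_db)
    expect_lt(abs(sp$z_re_ohm[nrow(sp)] - R_el) / R_el, 0.01)
    lo <- R_el + R_db
    expect_lt(abs(sp$z_re_ohm[1] - lo) / lo, 0.01)
    expect_equal(max(-sp$z_im_ohm), R_db / 2, tolerance = 1e-3)
  }
})

test_that("impedance noise is multiplicative and seeded", {
  a <- simulate_impedance(100, 1e4, 1e-6, noise_cv = 0.1, seed = 5)
  b <- simulate_impedance(100, 1e4, 1e-6, noise_cv = 0.1, seed = 5)
  expect_identical(a, b)
  c <- simulate_impedance(100, 1e4, 1e-6, noise_cv = 0.1, seed = 6)
  expect_false(identical(a, c))
  expect_error(simulate_impedance(-1, 1e4, 1e-6), "positive")
  expect_error(simulate_impedance(100, 1e4, 1e-6, frequencies = c(0, 1)),
               "positive")
})

test_that("zero-noise datasets reproduce the anchor triples exactly", {
  d <- generate_dataset(n_per_class = 1, noise_cv = 0, seed = 1)
  expect_equal(nrow(d), 60L)
  t1 <- load_table1()
  for (i in seq_len(nrow(t1))) {
    row <- d[d$pollutant == t1$pollutant[i] & d$level_uM == t1$level_uM[i], ]
    expect_equal(unlist(row[, channel_names()], use.names = FALSE),
                 unlist(t1[i, channel_names()], use.names = FALSE))
  }
  # clamped end levels duplicate the nearest anchored level
  lo <- d[d$level_uM == 0.1, channel_names()]
  l1 <- d[d$level_uM == 1, channel_names()]
  expect_equal(lo, l1, ignore_attr = TRUE)
})

test_that("dataset generation is bit-reproducible under a fixed seed", {
  a <- generate_dataset(n_per_class = 3, noise_cv = 0.1, seed = 42)
  b <- generate_dataset(n_per_class = 3, noise_cv = 0.1, seed = 42)
  expect_identical(a, b)
  c <- generate_dataset(n_per_class = 3, noise_cv = 0.1, seed = 43)
  expect_false(identical(a, c))
})

test_that("per-class sample means converge to the anchors at large n", {
  d <- generate_dataset(n_per_class = 200, noise_cv = 0.10, seed = 1)
  t1 <- load_table1()
  rel_err <- numeric(0)
  for (i in seq_len(nrow(t1))) {
    rows <- d$pollutant == t1$pollutant[i] & d$level_uM == t1$level_uM[i]
    for (ch in channel_names()) {
      m <- mean(d[rows, ch])
      rel_err <- c(rel_err, abs(m - t1[i, ch]) / abs(t1[i, ch]))
    }
  }
  # standard error of the relative mean is 0.10/sqrt(200) = 0.0071: nearly
  # all of the 108 class/channel means sit within 2%, and on average well
  # within 1%
  expect_gte(mean(rel_err <= 0.02), 0.95)
  expect_lte(mean(rel_err), 0.01)
  # sample coefficient of variation approaches the generative noise level
  cvs <- vapply(seq_len(nrow(t1)), function(i) {
    rows <- d$pollutant == t1$pollutant[i] & d$level_uM == t1$level_uM[i]
    stats::sd(d[rows, "e_coli"]) / abs(mean(d[rows, "e_coli"]))
  }, numeric(1))
  expect_equal(mean(cvs), 0.10, tolerance = 0.05)
})

test_that("concentration jitter stays within a quarter decade of the level", {
  d <- generate_dataset(n_per_class = 10, noise_cv = 0, seed = 7,
                        concentration_jitter = TRUE)
  ratio <- log10(d$concentration_uM / d$level_uM)
  expect_true(all(ratio >= -0.25 & ratio <= 0.25))
  expect_gt(stats::sd(ratio), 0)
  # jittered concentrations still quantize back to their class level
  expect_equal(quantize_concentration(d$concentration_uM), d$level_uM)
})
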