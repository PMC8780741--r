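test_that("analytical wavelength selection ranks by absorbance range", {
  ph <- seq(2, 12, 0.5)
  # flat series: no diagnostic wavelength anywhere
  flat <- spectral_series(c(250, 300), ph,
                          matrix(0.4, length(ph), 2))
  expect_error(select_analytical_wavelengths(flat), "no analytical wavelength")

  # generator ground truth: chromophores at 262/316/355 dominate
  s <- gen_spectra(noise_sd = 0, seed = 1)
  expect_setequal(select_analytical_wavelengths(s, k = 3), c(262, 316, 355))
  # oracle: exhaustive per-column range computation gives the same ranking
  rng <- apply(s$absorbance, 2, function(a) diff(range(a)))
  expect_equal(select_analytical_wavelengths(s, k = 3),
               s$wavelengths_nm[order(rng, decreasing = TRUE)][1:3])

  # exactly one pH-varying wavelength
  one <- spectral_series(c(250, 310), ph,
                         cbind(0.4, sigmoid_curve(ph, 6)))
  expect_equal(select_analytical_wavelengths(one, k = 1), 310)
})

test_that("crossing-point estimator handles a symmetric step and sigmoids", {
  # linear-between-plateaus step, inflection midway between pH 5 and 6
  ph <- 3:8
  a <- c(0.1, 0.1, 0.1, 0.9, 0.9, 0.9)
  expect_equal(pka_from_crossing(ph, a)$value, 5.5)

  # sigmoids on a 0.5-pH grid recover the configured pKa within 0.1
  for (pka in c(5.48, 10.49)) {
    ph <- seq(pka - 3, pka + 3, by = 0.5)
    est <- pka_from_crossing(ph, sigmoid_curve(ph, pka))
    expect_lt(abs(est$value - pka), 0.1)
  }

  # no-transition error
  expect_error(pka_from_crossing(3:8, rep(0.5, 6)), "no detectable transition")
})

test_that("crossing-point estimate agrees with a full sigmoid fit and is
           accurate to half the grid spacing across the pKa range", {
  for (pka in seq(3, 11, by = 0.8)) {
    ph <- seq(pka - 2.5, pka + 2.5, by = 0.25)
    a <- sigmoid_curve(ph, pka)
    est <- pka_from_crossing(ph, a)$value
    expect_lt(abs(est - pka), 0.125)               # half of 0.25 spacing
    expect_lt(abs(est - sigmoid_fit_pka(ph, a)), 0.15)  # oracle agreement
  }
})

test_that("replicate averaging converges to truth as noise shrinks", {
  pka <- 6.2
  ph <- seq(3.5, 9, by = 0.25)
  err <- vapply(c(0.02, 0.002), function(noise) {
    ests <- lapply(1:6, function(r) {
      set.seed(100 + r)
      a <- sigmoid_curve(ph, pka) + rnorm(length(ph), 0, noise)
      pka_from_crossing(ph, a)
    })
    avg <- summarize_pka_replicates(ests)
    expect_gte(avg$sd, 0)
    abs(avg$value - pka)
  }, numeric(1))
  expect_lt(err[2], err[1])     # error shrinks with the noise
  expect_lt(err[2], 0.02)
})

test_that("temperature adjustment is linear with a caller-supplied slope", {
  base <- pka_from_crossing(seq(3, 8, 0.5),
                            sigmoid_curve(seq(3, 8, 0.5), 5.48))
  expect_equal(adjust_pka_temperature(base, 37, 0)$value, base$value)

  base$value <- 5.48
  expect_equal(adjust_pka_temperature(base, 37, 0.06 / 14)$value, 5.54)
  acid <- base
  acid$value <- 10.49
  acid$character <- "acidic"
  adj <- adjust_pka_temperature(acid, 37, -0.16 / 14)
  expect_equal(adj$value, 10.33)
  expect_equal(adj$character, "acidic")
  expect_equal(adj$temperature_C, 37)

  # out-of-range result is an error
  expect_error(adjust_pka_temperature(base, 37, 1), "out of range")
})

test_that("estimate_pkas recovers both transitions from a full spectral series", {
  s <- gen_spectra(pka1 = 5.48, pka2 = 10.49, noise_sd = 0)
  est <- estimate_pkas(s, k = 3, split_ph = 8)
  expect_lt(abs(est$basic$value - 5.48), 0.25)   # half of the 0.5 grid
  expect_lt(abs(est$acidic$value - 10.49), 0.25)
  expect_equal(est$basic$character, "basic")
})
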