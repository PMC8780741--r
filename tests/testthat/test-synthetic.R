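test_that("generators are deterministic in the seed and independent by assay", {
  a <- gen_spectra(noise_sd = 0.01, seed = 42)
  b <- gen_spectra(noise_sd = 0.01, seed = 42)
  expect_identical(a$absorbance, b$absorbance)
  expect_false(identical(a$absorbance,
                         gen_spectra(noise_sd = 0.01, seed = 43)$absorbance))

  t1 <- gen_transwell(noise_sd = 0.02, seed = 42)
  t2 <- gen_transwell(noise_sd = 0.02, seed = 42)
  expect_identical(t1$ab$receiver_concentrations,
                   t2$ab$receiver_concentrations)

  # substreams: different assay names hash to different seeds
  expect_false(substream_seed(42, "spectra") == substream_seed(42, "transwell"))
  expect_identical(substream_seed(42, "spectra"), substream_seed(42, "spectra"))
  expect_true(substream_seed(2^30, "perfusion") < 2^31)
})

test_that("every generator embeds its truth record", {
  expect_equal(attr(gen_spectra(seed = 1), "truth")$pka1, 5.48)
  m <- speciation_model(12, 5.54, 10.33, pksp = 8.4)
  expect_s3_class(attr(gen_solubility(m, seed = 1), "truth")$model,
                  "speciation_model")
  expect_equal(gen_transwell(seed = 1)$truth$papp_true, 3.83e-5)
  expect_equal(attr(gen_perfusion(seed = 1), "truth")$peff_true, 9.2e-5)
})

test_that("spectra generator: zero-amplitude wavelengths are not analytical", {
  chrom <- data.frame(wavelength = c(262, 316, 355, 280),
                      baseline = c(0.6, 0.15, 0.05, 0.4),
                      amp1 = c(-0.45, 0.4, 0.2, 0),
                      amp2 = c(0.25, -0.1, 0.45, 0))
  s <- gen_spectra(chromophores = chrom, noise_sd = 0, seed = 1)
  expect_false(280 %in% select_analytical_wavelengths(s, k = 3))
})

test_that("noise-free generation composed with the estimator is the identity", {
  # spectra -> crossing point
  s <- gen_spectra(noise_sd = 0, seed = 9)
  est <- estimate_pkas(s, split_ph = 8)
  truth <- attr(s, "truth")
  expect_lt(abs(est$basic$value - truth$pka1), 0.25)
  expect_lt(abs(est$acidic$value - truth$pka2), 0.25)

  # solubility -> refinement
  m <- speciation_model(12, 5.54, 10.33, pksp = 8.4)
  pts <- gen_solubility(m, ph_list = c(1.5, 2.5, 3.5, 4.5, 6, 7, 8, 9),
                        noise_sd_log = 0, n_reps = 1, seed = 1,
                        use_activity = FALSE)
  fit <- refine_model(pts, speciation_model(20, 5.54, 10.33, pksp = 8),
                      use_activity = FALSE)
  expect_equal(fit$model$s0, 12, tolerance = 1e-5)

  # transwell -> papp fit (both forward routes)
  for (method in c("recursion", "ode")) {
    tw <- gen_transwell(noise_sd = 0, method = method, seed = 2)
    expect_equal(fit_papp(tw$ab)$papp, tw$truth$papp_true, tolerance = 0.01)
  }

  # perfusion -> Doluisio pipeline
  pa <- gen_perfusion(noise_sd = 0, water_flux_rate = 0.05, seed = 3)
  expect_equal(fit_perfusion(pa)$peff, attr(pa, "truth")$peff_true,
               tolerance = 1e-6)
})

test_that("transwell generator reproduces the built-in efflux asymmetry", {
  tw <- gen_transwell(papp_true = 3.83e-5, efflux_asymmetry = 0.22,
                      noise_sd = 0, seed = 4)
  er <- efflux_ratio(fit_papp(tw$ba)$papp, fit_papp(tw$ab)$papp)
  expect_equal(er, 0.22, tolerance = 0.01)
})

test_that("solubility generator produces the U-shaped salt-limited profile", {
  m <- speciation_model(12, 5.54, 10.33, pksp = 8.4)
  grid <- seq(1, 12, by = 0.25)
  pts <- gen_solubility(m, ph_list = grid, noise_sd_log = 0, n_reps = 1,
                        seed = 1)
  s <- pts$solubility
  acid_max <- grid[which.max(s[grid < 5])]
  expect_gt(acid_max, 3)       # acidic-branch maximum between pH 3 and 5
  expect_lt(acid_max, 5)
  plateau_min <- min(s[grid > 5 & grid < 10])
  expect_lt(plateau_min, max(s[grid < 5]))  # U: plateau below the acid peak
  expect_gt(s[length(s)], plateau_min)      # basic branch rises again
  expect_lt(s[1], max(s[grid < 5]))         # common-ion downturn at low pH
})

test_that("perfusion generator rejects schedules that drain the loop", {
  expect_error(gen_perfusion(water_flux_rate = 0.5,
                             times = seq(0, 30, 5)), "drains the loop")
})
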