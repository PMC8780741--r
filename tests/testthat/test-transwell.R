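blank_assay <- function(...) {
  transwell_assay("A-B", q_total = 200, ...)
}

test_that("replacement dilution factor", {
  expect_equal(dilution_factor(2.0, 0), 1)
  expect_equal(dilution_factor(2.0, 0.2), 0.9)
  expect_equal(dilution_factor(20, 2), dilution_factor(2.0, 0.2))
  expect_error(dilution_factor(2, 2), "sample_volume")
})

test_that("forward series limits: zero flux and equilibrium", {
  a <- blank_assay(sample_volume = 0)
  expect_equal(forward_receiver_series(a, 0), rep(0, 5))
  # large papp: receiver reaches Q/(Vr+Vd) at every post-zero time
  fast <- forward_receiver_series(a, 1e-2)
  expect_equal(fast[-1], rep(a$q_total / (a$v_receiver + a$v_donor), 4),
               tolerance = 1e-6)
})

test_that("forward recursion matches a fine-step RK4 integration with sampling", {
  for (papp in c(5e-6, 3.83e-5)) {
    a <- blank_assay()
    rec <- forward_receiver_series(a, papp)
    rk <- rk4_receiver_series(a, papp)
    expect_equal(rec[-1], rk[-1], tolerance = 5e-3)
  }
})

test_that("forward model conserves mass through sampling events", {
  a <- blank_assay()
  tr <- forward_receiver_series(a, 2e-5, full = TRUE)
  f <- dilution_factor(a$v_receiver, a$sample_volume)
  # post-sampling receiver + implied donor + cumulative sampled == total
  total <- a$v_receiver * tr$c_receiver * f +
    a$v_donor * tr$c_donor_implied + tr$sampled_mass
  expect_equal(total, rep(a$q_total, nrow(tr)), tolerance = 1e-9)
})

test_that("predicted receiver concentration is nondecreasing in papp", {
  # below the equilibrium-saturation regime; at saturation the sampled-mass
  # feedback makes late times insensitive to papp
  a <- blank_assay()
  grid <- 10^seq(-7, -4, length.out = 15)
  series <- sapply(grid, function(p) forward_receiver_series(a, p))
  for (row in 2:5) expect_true(all(diff(series[row, ]) >= -1e-12))
})

test_that("fit inverts the forward model for any admissible geometry", {
  geoms <- list(
    list(vr = 2.0, vd = 2.0, sv = 0.2, times = c(0, 15, 30, 60, 90)),
    list(vr = 1.5, vd = 2.5, sv = 0.1, times = c(0, 10, 20, 45, 75, 120)),
    list(vr = 0.5, vd = 1.2, sv = 0.05, times = c(0, 5, 30, 50)))
  for (g in geoms) {
    a <- transwell_assay("A-B", v_receiver = g$vr, v_donor = g$vd,
                         sample_volume = g$sv, sample_times = g$times,
                         q_total = 100 * g$vd)
    truth <- 3.83e-5
    a$receiver_concentrations <- forward_receiver_series(a, truth)
    fit <- fit_papp(a)
    expect_equal(fit$papp, truth, tolerance = 1e-2)
  }
})

test_that("geometric similarity leaves the fitted papp unchanged", {
  a <- blank_assay()
  a$receiver_concentrations <- forward_receiver_series(a, 2.5e-5)
  scaled <- transwell_assay("A-B",
                            v_receiver = a$v_receiver * 1000,
                            v_donor = a$v_donor * 1000,
                            membrane_area = a$membrane_area * 1000,
                            sample_volume = a$sample_volume * 1000,
                            sample_times = a$sample_times,
                            receiver_concentrations = a$receiver_concentrations,
                            q_total = a$q_total * 1000)
  expect_equal(fit_papp(scaled)$papp, fit_papp(a)$papp, tolerance = 1e-9)
})

test_that("degenerate receiver series fit to zero permeability", {
  a <- blank_assay()
  a$receiver_concentrations <- rep(0, 5)
  fit <- fit_papp(a)
  expect_equal(fit$papp, 0)
  expect_match(fit$flag, "all-zero")
})

test_that("efflux ratio and reference comparison", {
  expect_equal(efflux_ratio(1, 1), 1)
  expect_equal(efflux_ratio(0.85e-5, 3.83e-5), 0.22, tolerance = 0.01)
  expect_equal(round(efflux_ratio(0.28e-5, 2.46e-5), 2), 0.11)
  expect_error(efflux_ratio(1e-5, 0), "papp_ab")

  expect_equal(compare_to_reference(2e-5, 2e-5)$class, "high")  # inclusive
  expect_equal(compare_to_reference(0, 2e-5)$class, "low")
  cmp <- compare_to_reference(4e-5, 2e-5)
  expect_equal(cmp$class, "high")
  expect_equal(cmp$ratio, 2)
})

test_that("replicate summaries and the Welch comparison behave sanely", {
  res <- lapply(c(3.7e-5, 3.9e-5, 3.8e-5), function(p)
    structure(list(papp = p, direction = "A-B"), class = "papp_result"))
  s <- summarize_papp(res)
  expect_equal(s$papp_mean, 3.8e-5)
  expect_equal(s$n, 3)
  set.seed(1)
  out <- papp_t_test(rnorm(6, 3.8, 0.1), rnorm(6, 0.9, 0.1))
  expect_true(out$significant)
})
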