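jm20_model <- function(pksp = NULL, s0 = 12.0)
  speciation_model(s0 = s0, pka1 = 5.54, pka2 = 10.33, pksp = pksp)

test_that("Henderson-Hasselbalch ampholyte branch matches closed-form anchors", {
  m <- jm20_model()
  # far from both pKa values both ionized fractions are negligible
  expect_equal(hh_solubility_ampholyte(8.0, m), m$s0, tolerance = 0.02)
  # at pH = pKa1 the compound is half protonated: S = 2 S0
  expect_equal(hh_solubility_ampholyte(m$pka1, m), 2 * m$s0, tolerance = 0.01)
  # direct evaluation at physiological pH
  expect_equal(hh_solubility_ampholyte(7.4, m), 12.19, tolerance = 0.002)
})

test_that("Davies activity model", {
  expect_equal(davies_gamma(0), 1)
  expect_equal(davies_gamma(0.1), 0.782, tolerance = 1e-3)
  # z^2 scaling: gamma(z=2) = gamma(z=1)^4
  expect_equal(davies_gamma(0.05, 2), davies_gamma(0.05, 1)^4)
  expect_error(davies_gamma(-0.1), "ionic strength")
})

test_that("salt branch obeys the solubility product and locates pHmax", {
  m <- jm20_model(pksp = 8.5)
  # doubling chloride halves the branch well below pKa1
  s1 <- salt_branch_solubility(2, m, 0.05)
  s2 <- salt_branch_solubility(2, m, 0.10)
  expect_equal(s2 / s1, 0.5, tolerance = 1e-9)
  # neutral/anion fractions negligible at low pH: S ~ Ksp/[Cl] * MW * 1e3
  expect_equal(salt_branch_solubility(1.5, m, 0.05),
               10^(-8.5) / 0.05 * m$molecular_weight * 1000,
               tolerance = 1e-3)
  expect_error(salt_branch_solubility(2, m, 0), "chloride")
  expect_error(salt_branch_solubility(2, jm20_model(), 0.05), "no salt phase")

  # pHmax equals the root of (salt - HH) found by independent bisection
  cl <- 0.01
  root <- uniroot(function(p) salt_branch_solubility(p, m, cl) -
                    hh_solubility_ampholyte(p, m),
                  lower = 2, upper = 10, tol = 1e-10)$root
  s_at <- function(p) min(salt_branch_solubility(p, m, cl),
                          hh_solubility_ampholyte(p, m))
  # just below pHmax the salt limits; just above, the neutral solid does
  expect_equal(s_at(root - 1e-3),
               salt_branch_solubility(root - 1e-3, m, cl))
  expect_equal(s_at(root + 1e-3), hh_solubility_ampholyte(root + 1e-3, m))
})

test_that("titration engine reduces to the HH closed form without salt", {
  m <- jm20_model()
  sim <- simulate_titration(m, use_activity = FALSE)
  expect_equal(sim$s_calc, hh_solubility_ampholyte(sim$ph, m),
               tolerance = 1e-9)
  expect_true(all(sim$saturating_phase == "neutral"))
})

test_that("titration engine equals the two-branch minimum oracle at fixed chloride", {
  m <- jm20_model(pksp = 8.5)
  cl <- 0.05
  sim <- simulate_titration(m, use_activity = FALSE, fixed_chloride = cl)
  oracle <- pmin(hh_solubility_ampholyte(sim$ph, m),
                 salt_branch_solubility(sim$ph, m, cl, gamma = 1))
  expect_equal(sim$s_calc, oracle, tolerance = 1e-6)
  # phase rule: reported value is always the minimum of the branches
  expect_true(all(sim$s_calc <= hh_solubility_ampholyte(sim$ph, m) * (1 + 1e-12)))
})

test_that("titrant chloride produces the common-ion downturn below pH 2", {
  m <- jm20_model(pksp = 8.5)
  sim <- simulate_titration(m, titrant_hcl = TRUE)
  low <- sim[sim$ph <= 2 & sim$saturating_phase == "salt", ]
  expect_gt(nrow(low), 3)
  expect_true(all(diff(low$s_calc) > 0))  # S falls as pH falls
})

test_that("ampholyte-with-salt profile is U-shaped with one interior minimum", {
  m <- jm20_model(pksp = 8.2)
  sim <- simulate_titration(m, chloride_background = 0.001)
  # below pHmax the salt limits; above, the neutral solid takes over
  expect_setequal(unique(sim$saturating_phase), c("salt", "neutral"))
  neutral <- sim[sim$saturating_phase == "neutral", ]
  i_min <- which.min(neutral$s_calc)
  expect_gt(i_min, 1)                  # interior minimum on the plateau
  expect_lt(i_min, nrow(neutral))
  s <- log10(neutral$s_calc)
  expect_lte(sum(diff(sign(diff(s))) != 0), 1)  # single down-then-up bend
})

test_that("refinement recovers exact-data parameters and reports residuals", {
  truth <- jm20_model(pksp = 8.4)
  ph <- c(1.5, 2.5, 3.5, 4.5, 6, 7, 8, 9)
  pts <- data.frame(
    ph = ph,
    solubility = preformr:::predict_point_solubility(truth, ph,
                                                     use_activity = FALSE),
    sd = 0, chloride = 0)
  start <- jm20_model(pksp = 7.6, s0 = 25)
  fit <- refine_model(pts, start, free = c("s0", "pksp"),
                      use_activity = FALSE)
  expect_true(fit$converged)
  expect_lt(fit$weighted_sse, 1e-12)
  expect_equal(log10(fit$model$s0), log10(truth$s0), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$model$pksp, truth$pksp, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_length(fit$residuals, nrow(pts))

  expect_error(refine_model(pts[1:2, ], start), "at least 3")
  expect_error(refine_model(pts, start, free = c("s0", "pksp"),
                            exclude_ph = ph[-(1:1)]), "fewer usable points")
})

test_that("refinement on noisy synthetic profiles is unbiased for s0", {
  truth <- jm20_model(pksp = 8.4)
  ph <- c(seq(1.5, 5, by = 0.7), seq(6, 10, by = 0.7))[1:12]
  err <- vapply(1:100, function(seed) {
    pts <- gen_solubility(truth, ph, noise_sd_log = 0.05, n_reps = 1,
                          seed = seed, use_activity = FALSE)
    fit <- refine_model(pts, jm20_model(pksp = 8.0, s0 = 20),
                        use_activity = FALSE)
    log10(fit$model$s0) - log10(truth$s0)
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.02)          # bias in log10 units
  expect_lt(abs(median(10^err - 1)), 0.10) # median s0 within 10%
})

test_that("calculated solubility table interpolates the titration grid", {
  m <- jm20_model(pksp = 8.4)
  tab_grid <- calculated_solubility_table(m, c(3.0, 7.0),
                                          use_activity = FALSE)
  sim <- simulate_titration(m, use_activity = FALSE)
  expect_equal(tab_grid$s_calc, sim$s_calc[match(c(3.0, 7.0), sim$ph)],
               tolerance = 1e-12)
  # neutral-region grid pH with no salt equals the closed form
  m0 <- jm20_model()
  expect_equal(calculated_solubility_table(m0, 7.8, use_activity = FALSE)$s_calc,
               hh_solubility_ampholyte(7.8, m0), tolerance = 1e-9)
  # off-grid interpolation agrees with a half-step simulation
  half <- simulate_titration(m, step = 0.1, use_activity = FALSE)
  off <- calculated_solubility_table(m, 6.5, use_activity = FALSE)$s_calc
  expect_equal(off, half$s_calc[match(6.5, round(half$ph, 10))],
               tolerance = 5e-3)
  expect_error(calculated_solubility_table(m, 42), "outside simulated range")
})
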