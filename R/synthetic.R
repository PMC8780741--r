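# Seeded synthetic assays with embedded ground truth. One global seed fans
# out to per-assay substreams by a stable polynomial hash of the assay name,
# so generating one assay never perturbs another's stream.

#' Derive a per-assay substream seed from a global seed
#'
#' Stable polynomial hash of the assay name folded into the global seed,
#' reduced modulo 2^31 - 1 so it is always a valid R integer seed.
#'
#' @param seed global integer seed.
#' @param name assay name (character).
#' @return Integer seed.
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- seed %% m
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

#' Generate a synthetic absorbance-pH spectral series
#'
#' Each wavelength carries a baseline plus sigmoidal contributions from the
#' two deprotonation steps, A(pH) = baseline + amp1/(1 + 10^(pKa1 - pH)) +
#' amp2/(1 + 10^(pKa2 - pH)), with additive Gaussian noise (absorbance
#' noise on a spectrophotometer is approximately additive). The default
#' chromophore table places the pH-sensitive wavelengths at 262, 316 and
#' 355 nm plus two nearly inert distractors.
#'
#' @param pka1,pka2 true dissociation constants (pka1 < pka2).
#' @param ph_grid pH ladder (must span both transitions).
#' @param chromophores data.frame with columns `wavelength`, `baseline`,
#'   `amp1`, `amp2`; NULL for the default table.
#' @param noise_sd additive Gaussian noise sd (AU).
#' @param seed global seed.
#' @return A [spectral_series()] with a `truth` attribute recording the
#'   generator parameters.
#' @export
gen_spectra <- function(pka1 = 5.48, pka2 = 10.49,
                        ph_grid = seq(2, 12.5, by = 0.5),
                        chromophores = NULL, noise_sd = 0, seed = 1) {
  if (pka1 >= pka2) stop("pka1 must be < pka2")
  if (min(ph_grid) > pka1 - 1 || max(ph_grid) < pka2 + 1)
    warning("pH grid does not span both transitions with a plateau margin")
  if (is.null(chromophores))
    chromophores <- data.frame(
      wavelength = c(262, 316, 355, 240, 300),
      baseline   = c(0.60, 0.15, 0.05, 0.50, 0.30),
      amp1       = c(-0.45, 0.40, 0.20, 0.01, 0.00),
      amp2       = c(0.25, -0.10, 0.45, 0.00, 0.01))
  set.seed(substream_seed(seed, "spectra"))
  frac1 <- 1 / (1 + 10^(pka1 - ph_grid))
  frac2 <- 1 / (1 + 10^(pka2 - ph_grid))
  A <- sapply(seq_len(nrow(chromophores)), function(j)
    chromophores$baseline[j] + chromophores$amp1[j] * frac1 +
      chromophores$amp2[j] * frac2)
  if (noise_sd > 0)
    A <- A + matrix(stats::rnorm(length(A), 0, noise_sd), nrow(A), ncol(A))
  A <- pmax(A, 0)
  out <- spectral_series(chromophores$wavelength, ph_grid, A,
                         temperature_C = 23)
  attr(out, "truth") <- list(pka1 = pka1, pka2 = pka2, noise_sd = noise_sd,
                             seed = seed, chromophores = chromophores)
  out
}

#' Generate synthetic solubility-pH measurements
#'
#' Measured solubility is the model's predicted value times a lognormal
#' error, S_meas = S_calc(pH) * 10^eps with eps ~ N(0, noise_sd_log);
#' per-point sd is taken from the replicate spread.
#'
#' @param model true [speciation_model()].
#' @param ph_list pH values to measure at.
#' @param chloride buffer chloride background per point (mol/L).
#' @param titrant_hcl if TRUE, add the strong-acid chloride (~\[H+\]) that a
#'   low-pH buffer adjusted with HCl carries, so the common-ion downturn
#'   below pH 2 is part of the emulated profile.
#' @param noise_sd_log lognormal noise sd in log10 units.
#' @param n_reps replicates per point.
#' @param seed global seed.
#' @param use_activity passed to the predictor.
#' @return data.frame (`ph`, `solubility`, `sd`, `chloride`) with a `truth`
#'   attribute.
#' @export
gen_solubility <- function(model, ph_list = c(1.2, 3.5, 4.0, 4.5, 6.8, 7.4),
                           chloride = 0, titrant_hcl = TRUE,
                           noise_sd_log = 0.05, n_reps = 3,
                           seed = 1, use_activity = TRUE) {
  stopifnot(inherits(model, "speciation_model"))
  set.seed(substream_seed(seed, "solubility"))
  chloride <- rep_len(chloride, length(ph_list))
  if (titrant_hcl && !is.null(model$pksp))
    chloride <- chloride + pmax(0, 10^(-ph_list) - 1e-7)
  s_true <- predict_point_solubility(model, ph_list, chloride, use_activity)
  reps <- sapply(seq_along(ph_list), function(i)
    s_true[i] * 10^stats::rnorm(n_reps, 0, noise_sd_log))
  reps <- matrix(reps, nrow = n_reps)
  out <- data.frame(
    ph = ph_list,
    solubility = colMeans(reps),
    sd = if (n_reps > 1) apply(reps, 2, stats::sd) else 0,
    chloride = chloride)
  attr(out, "truth") <- list(model = model, noise_sd_log = noise_sd_log,
                             n_reps = n_reps, seed = seed, s_true = s_true)
  out
}

#' Generate a bidirectional synthetic transwell assay pair
#'
#' Builds matched A-B and B-A assays from the non-sink forward model (or an
#' independent fine-step ODE integration, to avoid testing the fit against
#' its own forward recursion) with multiplicative lognormal noise on the
#' receiver concentrations. The B-A assay uses papp_true *
#' efflux_asymmetry.
#'
#' @param papp_true absorptive-direction permeability (cm/s).
#' @param efflux_asymmetry ratio Papp(B-A)/Papp(A-B) built into the truth.
#' @param donor_concentration initial donor concentration (uM).
#' @param v_receiver,v_donor,membrane_area,sample_volume,sample_times assay
#'   geometry (defaults: 2 mL / 2 mL, 4.2 cm^2, 0.2 mL, 0/15/30/60/90 min).
#' @param noise_sd multiplicative noise sd (fraction, lognormal).
#' @param method "recursion" for the interval-exact forward model,
#'   "ode" for fine-step numerical integration (deSolve) with sampling
#'   events.
#' @param seed global seed.
#' @return List with `ab` and `ba` ([transwell_assay()] objects, measured
#'   receiver series filled in) and `truth`.
#' @export
gen_transwell <- function(papp_true = 3.83e-5, efflux_asymmetry = 0.22,
                          donor_concentration = 100,
                          v_receiver = 2.0, v_donor = 2.0,
                          membrane_area = 4.2, sample_volume = 0.2,
                          sample_times = c(0, 15, 30, 60, 90),
                          noise_sd = 0, method = c("recursion", "ode"),
                          seed = 1) {
  method <- match.arg(method)
  stopifnot(papp_true >= 0)
  set.seed(substream_seed(seed, "transwell"))
  build <- function(direction, papp) {
    assay <- transwell_assay(direction, v_receiver, v_donor, membrane_area,
                             sample_volume, sample_times,
                             donor_concentrations = c(donor_concentration, NA),
                             q_total = v_donor * donor_concentration)
    clean <- if (method == "recursion")
      forward_receiver_series(assay, papp)
    else
      ode_receiver_series(assay, papp)
    # multiplicative lognormal: noise_sd is the sd of the log10-scale error
    noisy <- clean * 10^stats::rnorm(length(clean), 0, noise_sd)
    assay$receiver_concentrations <- noisy
    # end-of-run donor concentration from the model trace
    trace <- forward_receiver_series(assay, papp, c_receiver0 = 0, full = TRUE)
    assay$donor_concentrations <- c(donor_concentration,
                                    trace$c_donor_implied[nrow(trace)])
    assay
  }
  ab <- build("A-B", papp_true)
  ba <- build("B-A", papp_true * efflux_asymmetry)
  list(ab = ab, ba = ba,
       truth = list(papp_true = papp_true,
                    efflux_asymmetry = efflux_asymmetry,
                    noise_sd = noise_sd, method = method, seed = seed))
}

#' Fine-step ODE receiver series (independent of the interval recursion)
#'
#' Integrates the two-compartment mass-transfer ODE with deSolve between
#' sampling events, applying the sampling mass removal and replacement
#' dilution at each listed time.
#'
#' @param assay a [transwell_assay()].
#' @param papp cm/s.
#' @return Receiver concentrations (uM) at `assay$sample_times`
#'   (pre-sampling values).
#' @export
ode_receiver_series <- function(assay, papp) {
  vr <- assay$v_receiver
  vd <- assay$v_donor
  kA <- papp * assay$membrane_area * 60  # cm^3/min
  f <- dilution_factor(vr, assay$sample_volume)
  deriv <- function(t, y, p) {
    flux <- kA * (y[2] - y[1])  # uM * cm^3/min = nmol/min
    list(c(flux / vr, -flux / vd))
  }
  times <- assay$sample_times
  cr0 <- 0
  cd0 <- assay$q_total / vd
  y <- c(cr = cr0, cd = cd0)
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    if (i > 1) {
      sol <- deSolve::lsoda(y, c(times[i - 1], times[i]), deriv, NULL,
                            rtol = 1e-10, atol = 1e-12)
      y <- c(cr = sol[nrow(sol), 2], cd = sol[nrow(sol), 3])
    }
    out[i] <- y[1]
    y[1] <- y[1] * f  # sample + replace
  }
  out
}

#' Generate a synthetic closed-loop perfusion assay
#'
#' Luminal drug mass decays first order with ka = 2 Peff / r (r from the
#' cylinder assumption); the luminal volume shrinks linearly at
#' `water_flux_rate`, so the measured concentration C_e = mass / V_t is
#' biased upward until the volume correction is applied. Noise is
#' multiplicative lognormal.
#'
#' @param peff_true effective permeability (cm/s), >= 0.
#' @param length_cm segment length (cm).
#' @param v0 initial luminal volume (mL).
#' @param water_flux_rate net water absorption rate (mL/min, >= 0).
#' @param times sampling schedule (minutes).
#' @param c0 initial luminal concentration (uM).
#' @param noise_sd lognormal noise sd (log10 units).
#' @param segment segment label.
#' @param seed global seed.
#' @return A [perfusion_assay()] with a `truth` attribute.
#' @export
gen_perfusion <- function(peff_true = 9.20e-5, length_cm = 30, v0 = 10,
                          water_flux_rate = 0, times = seq(0, 30, by = 5),
                          c0 = 100, noise_sd = 0,
                          segment = "duodenum", seed = 1) {
  stopifnot(peff_true >= 0)
  set.seed(substream_seed(seed, "perfusion"))
  r <- effective_radius(length_cm, v0)
  ka_min <- 2 * peff_true / r * 60  # 1/min
  v_t <- v0 - water_flux_rate * times
  if (any(v_t <= 0))
    stop("water flux drains the loop within the schedule")
  mass <- c0 * v0 * exp(-ka_min * times)   # nmol
  c_e <- mass / v_t * 10^stats::rnorm(length(times), 0, noise_sd)
  out <- perfusion_assay(segment, times, c_e, v0 = v0, v_t = v_t,
                         length_cm = length_cm, perfusion_volume = v0)
  attr(out, "truth") <- list(peff_true = peff_true, ka_min = ka_min, r = r,
                             water_flux_rate = water_flux_rate,
                             noise_sd = noise_sd, seed = seed)
  out
}
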