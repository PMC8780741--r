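# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: the transwell oracle is a hand-rolled
# fixed-step RK4 on the two-compartment ODE, and the pKa oracle is a full
# sigmoid least-squares fit on the raw curve.

# RK4 integration of the two-compartment transwell system with sampling
# events (mass removal + replacement dilution) at every sample time.
rk4_receiver_series <- function(assay, papp, dt_min = 0.01) {
  vr <- assay$v_receiver
  vd <- assay$v_donor
  kA <- papp * assay$membrane_area * 60  # cm^3/min
  f <- (vr - assay$sample_volume) / vr
  deriv <- function(y) {
    flux <- kA * (y[2] - y[1])
    c(flux / vr, -flux / vd)
  }
  times <- assay$sample_times
  y <- c(0, assay$q_total / vd)
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    if (i > 1) {
      span <- times[i] - times[i - 1]
      nstep <- max(1L, ceiling(span / dt_min))
      h <- span / nstep
      for (s in seq_len(nstep)) {
        k1 <- deriv(y)
        k2 <- deriv(y + h / 2 * k1)
        k3 <- deriv(y + h / 2 * k2)
        k4 <- deriv(y + h * k3)
        y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    out[i] <- y[1]
    y[1] <- y[1] * f
  }
  out
}

# Dense-grid sigmoid least-squares pKa fit (independent of the
# crossing-point estimator).
sigmoid_fit_pka <- function(ph, absorbance) {
  start <- list(a = min(absorbance), b = max(absorbance) - min(absorbance),
                p = ph[which.min(abs(absorbance - mean(range(absorbance))))])
  # warnOnly + suppressWarnings: on noiseless data nls stops on the zero
  # residual convergence criterion, which it reports as a warning
  fit <- suppressWarnings(
    stats::nls(absorbance ~ a + b / (1 + 10^(p - ph)),
               start = start,
               control = stats::nls.control(warnOnly = TRUE)))
  unname(stats::coef(fit)["p"])
}

# Noise-free single-transition absorbance sigmoid.
sigmoid_curve <- function(ph, pka, a_low = 0.1, a_high = 0.9) {
  a_low + (a_high - a_low) / (1 + 10^(pka - ph))
}
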