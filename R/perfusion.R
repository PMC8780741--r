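#' Closed-loop intestinal perfusion assay
#'
#' Container for one animal/segment time course from the closed-loop
#' (Doluisio) in situ perfusion technique: luminal drug concentration
#' sampled over time, with the luminal volume at each time (or measured
#' only at the endpoints, in which case it is linearly interpolated) to
#' correct for net water flux.
#'
#' @param segment one of "duodenum", "jejunum", "ileum", "whole".
#' @param times sampling times (minutes), strictly increasing, >= 0.
#' @param concentrations_measured luminal concentrations C_e (uM).
#' @param v0 initial luminal volume (mL).
#' @param v_t luminal volume at each time (mL); a length-2 vector is read
#'   as (initial, final) and interpolated linearly over `times`.
#' @param length_cm length of the perfused segment (cm).
#' @param perfusion_volume nominal perfusion volume used for the effective
#'   radius (mL).
#' @return Object of class `perfusion_assay`.
#' @export
perfusion_assay <- function(segment = c("duodenum", "jejunum", "ileum", "whole"),
                            times, concentrations_measured,
                            v0 = 10, v_t = NULL, length_cm,
                            perfusion_volume = 10) {
  segment <- match.arg(segment)
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("times must be strictly increasing and start >= 0")
  if (length(concentrations_measured) != length(times))
    stop("concentrations and times lengths differ")
  if (any(concentrations_measured < 0)) stop("concentrations must be >= 0")
  if (v0 <= 0 || length_cm <= 0 || perfusion_volume <= 0)
    stop("volumes and length must be > 0")
  if (is.null(v_t)) v_t <- rep(v0, length(times))
  if (length(v_t) == 2 && length(times) > 2)
    v_t <- stats::approx(range(times), v_t, xout = times)$y
  if (length(v_t) != length(times)) stop("v_t must align with times")
  if (any(v_t <= 0)) stop("volumes must be > 0")
  structure(
    list(segment = segment, times = times,
         concentrations_measured = concentrations_measured,
         v0 = v0, v_t = v_t, length_cm = length_cm,
         perfusion_volume = perfusion_volume),
    class = "perfusion_assay")
}

#' Water-flux volume correction
#'
#' Net water absorption shrinks the luminal volume and concentrates the
#' drug; rescaling each measured concentration by the volume ratio,
#' C_t = C_e * V_t / V_0, restores a quantity proportional to the true
#' luminal mass so that only permeation drives its decline.
#'
#' @param c_e measured concentration (uM), vectorized.
#' @param v_t luminal volume at the sampling time (mL).
#' @param v0 initial luminal volume (mL).
#' @return Corrected concentration C_t (uM).
#' @export
volume_corrected_concentration <- function(c_e, v_t, v0) {
  if (any(v_t <= 0) || any(v0 <= 0)) stop("volumes must be > 0")
  c_e * v_t / v0
}

#' First-order luminal disappearance fit
#'
#' Nonlinear least squares of C_t = C0 exp(-ka t) in concentration space
#' (not log-linearized), with ka constrained non-negative; a log-space fit
#' is available for strongly multiplicative noise.
#'
#' @param times minutes.
#' @param c_t volume-corrected concentrations (uM), > 0, at least 3 points.
#' @param log_space fit log(C) = log(C0) - ka t instead.
#' @return List with `ka` (1/min), `c0` (uM), `sse`, `flag`.
#' @export
fit_first_order <- function(times, c_t, log_space = FALSE) {
  if (length(times) < 3) stop("need at least 3 time points")
  if (any(c_t <= 0)) stop("corrected concentrations must be > 0")
  slope <- stats::coef(stats::lm(log(c_t) ~ times))[2]
  if (slope >= 0) {
    return(list(ka = 0, c0 = mean(c_t),
                sse = sum((c_t - mean(c_t))^2),
                flag = "non-decaying series; ka fixed at 0"))
  }
  start <- c(log_c0 = log(max(c_t)), ka = -slope)
  resid <- function(p) {
    pred <- exp(p[1] - p[2] * times)
    if (log_space) log(c_t) - log(pred) else c_t - pred
  }
  fit <- minpack.lm::nls.lm(
    par = start, lower = c(-Inf, 0), fn = resid,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12))
  if (!fit$info %in% 1:4)
    stop("first-order fit did not converge: ", fit$message)
  list(ka = unname(fit$par[2]), c0 = unname(exp(fit$par[1])),
       sse = sum(fit$fvec^2), flag = character(0))
}

#' Effective intestinal radius from the cylinder assumption
#'
#' The perfused segment is treated as a cylinder holding the perfusion
#' volume: V = pi r^2 L, so r = sqrt(V / (pi L)).
#'
#' @param length_cm segment length (cm), > 0.
#' @param perfusion_volume_mL perfusion volume (mL = cm^3), > 0.
#' @return Radius (cm).
#' @export
effective_radius <- function(length_cm, perfusion_volume_mL) {
  if (length_cm <= 0 || perfusion_volume_mL <= 0)
    stop("length and volume must be > 0")
  sqrt(perfusion_volume_mL / (pi * length_cm))
}

#' Effective permeability from the absorption rate constant
#'
#' For a cylindrical lumen of radius r, first-order disappearance with rate
#' ka corresponds to Peff = r ka / 2 (ka converted from 1/min to 1/s).
#'
#' @param ka absorption rate constant (1/min), >= 0.
#' @param r effective radius (cm), > 0.
#' @return Peff (cm/s).
#' @export
peff_from_ka <- function(ka, r) {
  if (ka < 0) stop("ka must be >= 0")
  if (r <= 0) stop("r must be > 0")
  r * (ka / 60) / 2
}

#' Full Doluisio pipeline for one assay
#'
#' Volume-corrects the time course, fits the first-order disappearance and
#' converts the rate constant to an effective permeability through the
#' cylinder radius.
#'
#' @param assay a [perfusion_assay()].
#' @param log_space passed to [fit_first_order()].
#' @return Object of class `perfusion_fit`: `ka` (1/min), `c0` (uM), `r`
#'   (cm), `peff` (cm/s), `segment`, `flag`.
#' @export
fit_perfusion <- function(assay, log_space = FALSE) {
  stopifnot(inherits(assay, "perfusion_assay"))
  c_t <- volume_corrected_concentration(assay$concentrations_measured,
                                        assay$v_t, assay$v0)
  fo <- fit_first_order(assay$times, c_t, log_space = log_space)
  r <- effective_radius(assay$length_cm, assay$perfusion_volume)
  structure(
    list(ka = fo$ka, c0 = fo$c0, r = r, peff = peff_from_ka(fo$ka, r),
         segment = assay$segment, sse = fo$sse, flag = fo$flag),
    class = "perfusion_fit")
}

#' Summarize per-animal perfusion fits by segment
#'
#' @param fits list of `perfusion_fit` objects.
#' @return data.frame with `segment`, `peff_mean`, `peff_sd`, `n` (cm/s).
#' @export
summarize_peff <- function(fits) {
  stopifnot(all(vapply(fits, inherits, logical(1), "perfusion_fit")))
  seg <- vapply(fits, `[[`, character(1), "segment")
  peff <- vapply(fits, `[[`, numeric(1), "peff")
  out <- do.call(rbind, lapply(split(peff, seg), function(v)
    data.frame(peff_mean = mean(v),
               peff_sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n = length(v))))
  data.frame(segment = rownames(out), out, row.names = NULL)
}
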