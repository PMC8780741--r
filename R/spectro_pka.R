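#' Absorbance-pH spectral series
#'
#' Container for UV-Vis absorbance read at a set of wavelengths over a pH
#' ladder, the raw material of spectrophotometric pKa determination.
#'
#' @param wavelengths_nm numeric vector of wavelengths (nm).
#' @param ph_values numeric vector of pH values, strictly increasing.
#' @param absorbance numeric matrix (AU), rows = pH values, columns =
#'   wavelengths; all entries must be non-negative.
#' @param temperature_C temperature of the determination (degrees C).
#' @param cosolvent_fraction volume fraction of organic cosolvent in the
#'   buffers (kept at or below 0.02 so the apparent pKa is unshifted).
#' @return An object of class `spectral_series`.
#' @export
spectral_series <- function(wavelengths_nm, ph_values, absorbance,
                            temperature_C = 23, cosolvent_fraction = 0.02) {
  absorbance <- as.matrix(absorbance)
  if (is.unsorted(ph_values, strictly = TRUE))
    stop("ph_values must be strictly increasing")
  if (nrow(absorbance) != length(ph_values) ||
      ncol(absorbance) != length(wavelengths_nm))
    stop("absorbance must be length(ph_values) x length(wavelengths_nm)")
  if (any(absorbance < 0)) stop("absorbance values must be >= 0")
  if (cosolvent_fraction > 0.02)
    warning("cosolvent fraction above 2% v/v may shift the apparent pKa")
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         ph_values = as.numeric(ph_values),
         absorbance = absorbance,
         temperature_C = temperature_C,
         cosolvent_fraction = cosolvent_fraction),
    class = "spectral_series")
}

#' Pick the most pH-sensitive analytical wavelengths
#'
#' A wavelength is diagnostic for pKa work when its absorbance changes with
#' pH, so wavelengths are ranked by their absorbance range across the pH
#' ladder and the top `k` are returned.
#'
#' @param series a [spectral_series()].
#' @param k number of wavelengths to return.
#' @param epsilon minimum absorbance range (AU) below which a wavelength is
#'   considered pH-insensitive.
#' @return Numeric vector of `k` wavelengths (nm), sorted by decreasing
#'   absorbance range.
#' @export
select_analytical_wavelengths <- function(series, k = 3, epsilon = 1e-6) {
  stopifnot(inherits(series, "spectral_series"))
  if (length(series$ph_values) < 2) stop("need at least 2 pH points")
  rng <- apply(series$absorbance, 2, function(a) diff(range(a)))
  if (all(rng < epsilon))
    stop("no analytical wavelength: absorbance is pH-independent everywhere")
  keep <- which(rng >= epsilon)
  keep <- keep[order(rng[keep], decreasing = TRUE)]
  if (k > length(keep))
    stop("only ", length(keep), " pH-sensitive wavelengths available")
  series$wavelengths_nm[keep[seq_len(k)]]
}

#' Crossing-point pKa from a single absorbance-pH curve
#'
#' Graphical crossing-point estimate of a dissociation constant from an
#' absorbance-pH sigmoid at one analytical wavelength. The two plateau
#' absorbances define a mid-absorbance level (their mean); the pKa is the pH
#' at which the curve crosses that level, obtained by solving the linear
#' equation through the two data points closest to the crossing. At the
#' crossing the two protonation states contribute equally, so that pH is the
#' pKa.
#'
#' @param ph_values numeric, strictly increasing, at least 4 points spanning
#'   the transition.
#' @param absorbance numeric, absorbance (AU) at the analytical wavelength.
#' @param epsilon minimum successive absorbance change (AU) required to call
#'   a transition.
#' @param wavelength_nm,temperature_C metadata carried into the estimate.
#' @return An object of class `pka_estimate`: list with `value`, `sd` (NA
#'   for a single curve; see [summarize_pka_replicates()]), `character`
#'   ("acidic" if absorbance increases with pH at this wavelength is not
#'   informative on its own, so the label is taken from the caller via
#'   `character`), `wavelength_nm`, `temperature_C` and `flag`.
#' @param character "acidic" or "basic" assignment of the transition.
#' @export
pka_from_crossing <- function(ph_values, absorbance, epsilon = 1e-4,
                              wavelength_nm = NA_real_, temperature_C = 23,
                              character = c("basic", "acidic")) {
  character <- match.arg(character)
  if (length(ph_values) < 4) stop("need at least 4 pH points")
  if (is.unsorted(ph_values, strictly = TRUE))
    stop("ph_values must be strictly increasing")
  if (length(absorbance) != length(ph_values))
    stop("absorbance and ph_values lengths differ")
  dA <- diff(absorbance)
  if (max(abs(dA)) < epsilon)
    stop("no detectable transition: absorbance change below epsilon")
  a_lo <- absorbance[1]
  a_hi <- absorbance[length(absorbance)]
  a_mid <- (a_lo + a_hi) / 2
  # segments whose endpoints bracket the mid-absorbance level
  cross <- which((absorbance[-length(absorbance)] - a_mid) *
                   (absorbance[-1] - a_mid) <= 0)
  flag <- character(0)
  steepest <- which.max(abs(dA) / diff(ph_values))
  if (length(cross) == 0) {
    i <- steepest
    flag <- c(flag, "no mid-level crossing; used steepest segment")
  } else if (length(cross) > 1) {
    i <- cross[which.min(abs(cross - steepest))]
  } else {
    i <- cross
  }
  slope <- (absorbance[i + 1] - absorbance[i]) / (ph_values[i + 1] - ph_values[i])
  if (abs(slope) < .Machine$double.eps) {
    est <- (ph_values[i] + ph_values[i + 1]) / 2
    flag <- c(flag, "flat crossing segment; midpoint used")
  } else {
    est <- ph_values[i] + (a_mid - absorbance[i]) / slope
  }
  if (est < ph_values[i] - diff(ph_values[i:(i + 1)]) ||
      est > ph_values[i + 1] + diff(ph_values[i:(i + 1)]))
    flag <- c(flag, "crossing outside bracketing interval")
  structure(
    list(value = est, sd = NA_real_, character = character,
         wavelength_nm = wavelength_nm, temperature_C = temperature_C,
         flag = flag),
    class = "pka_estimate")
}

#' Average pKa estimates over replicates
#'
#' Replicate curves are estimated independently; the reported value is their
#' mean and the uncertainty the sample standard deviation.
#'
#' @param estimates list of `pka_estimate` objects from replicate curves.
#' @return A single `pka_estimate` with `value` = mean and `sd` = sample sd.
#' @export
summarize_pka_replicates <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, logical(1), "pka_estimate")))
  vals <- vapply(estimates, `[[`, numeric(1), "value")
  out <- estimates[[1]]
  out$value <- mean(vals)
  out$sd <- if (length(vals) > 1) stats::sd(vals) else NA_real_
  out$flag <- unique(unlist(lapply(estimates, `[[`, "flag")))
  out
}

#' Adjust a pKa estimate to another temperature
#'
#' Linear correction value' = value + dpka_dT * (target - source). The
#' coefficient must be supplied by the caller (e.g. from a van't Hoff
#' analysis or a literature d(pKa)/dT); [jm20_config()] ships coefficients
#' back-derived from the compound's own 23 C / 37 C determinations.
#'
#' @param estimate a `pka_estimate`.
#' @param target_temperature_C temperature to adjust to (degrees C).
#' @param dpka_dT temperature coefficient (pKa units per degree C).
#' @return The adjusted `pka_estimate` (character and sd unchanged).
#' @export
adjust_pka_temperature <- function(estimate, target_temperature_C, dpka_dT) {
  stopifnot(inherits(estimate, "pka_estimate"))
  value <- estimate$value +
    dpka_dT * (target_temperature_C - estimate$temperature_C)
  if (value <= 0 || value >= 14)
    stop("temperature-adjusted pKa out of range (0, 14): ", round(value, 3))
  estimate$value <- value
  estimate$temperature_C <- target_temperature_C
  estimate
}

#' Estimate both pKa values of an ampholyte from a spectral series
#'
#' Convenience wrapper: selects analytical wavelengths, splits the pH ladder
#' at `split_ph` into the basic (lower) and acidic (upper) transitions, and
#' applies the crossing-point estimator to each window at each wavelength,
#' averaging across wavelengths.
#'
#' @param series a [spectral_series()].
#' @param k number of analytical wavelengths to use.
#' @param split_ph pH separating the two transitions (must lie on the
#'   plateau between them).
#' @return List with elements `basic` and `acidic`, each a `pka_estimate`
#'   averaged over the analytical wavelengths.
#' @export
estimate_pkas <- function(series, k = 3, split_ph = 8) {
  wl <- select_analytical_wavelengths(series, k)
  idx <- match(wl, series$wavelengths_nm)
  lo <- series$ph_values <= split_ph
  hi <- series$ph_values >= split_ph
  one <- function(rows, character) {
    ests <- lapply(idx, function(j) {
      pka_from_crossing(series$ph_values[rows], series$absorbance[rows, j],
                        wavelength_nm = series$wavelengths_nm[j],
                        temperature_C = series$temperature_C,
                        character = character)
    })
    summarize_pka_replicates(ests)
  }
  list(basic = one(lo, "basic"), acidic = one(hi, "acidic"))
}
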