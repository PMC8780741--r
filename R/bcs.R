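#' Dose number
#'
#' Do = D / (V0 * Cs): the number of reference volumes (250 mL by
#' regulatory convention) of medium needed to dissolve the dose at the
#' given solubility. Do <= 1 marks high solubility.
#'
#' @param dose_mg dose D (mg), > 0.
#' @param cs_mg_per_mL solubility at the pH of interest (mg/mL), > 0.
#' @param v0_mL reference volume (mL), default 250.
#' @return Dimensionless dose number.
#' @export
dose_number <- function(dose_mg, cs_mg_per_mL, v0_mL = 250) {
  if (any(dose_mg <= 0) || any(v0_mL <= 0)) stop("dose and volume must be > 0")
  if (any(cs_mg_per_mL <= 0)) stop("solubility must be > 0")
  dose_mg / (v0_mL * cs_mg_per_mL)
}

#' Weight-based highest dose
#'
#' @param dose_mg_per_kg dose per body weight (mg/kg), > 0.
#' @param body_weight_kg reference body weight (kg), > 0 (70 kg adult by
#'   convention).
#' @return Dose in mg.
#' @export
highest_dose_from_weight <- function(dose_mg_per_kg, body_weight_kg) {
  if (dose_mg_per_kg <= 0 || body_weight_kg <= 0)
    stop("dose and weight must be > 0")
  dose_mg_per_kg * body_weight_kg
}

#' Solubility class from dose numbers over a pH set
#'
#' High solubility requires the dose to dissolve at every pH of the
#' regulatory range, i.e. the worst-case (maximum) Do must be <= 1.
#'
#' @param do_by_ph named numeric vector or list mapping pH to Do; nonempty.
#' @return "high" or "low".
#' @export
solubility_class <- function(do_by_ph) {
  do_by_ph <- unlist(do_by_ph)
  if (length(do_by_ph) == 0) stop("empty dose-number map")
  if (max(do_by_ph) <= 1) "high" else "low"
}

#' Majority permeability class over multiple methods
#'
#' Classifies the compound per method against the matching reference value
#' (see [compare_to_reference()]) and takes the majority, keeping the full
#' evidence list.
#'
#' @param evidence data.frame with columns `method` and `class`
#'   ("high"/"low").
#' @return List with `class` (majority) and `evidence`.
#' @export
permeability_class <- function(evidence) {
  stopifnot(all(c("method", "class") %in% names(evidence)),
            nrow(evidence) >= 1)
  n_high <- sum(evidence$class == "high")
  list(class = if (n_high * 2 >= nrow(evidence)) "high" else "low",
       evidence = evidence)
}

#' Provisional BCS class from the two component classes
#'
#' (high, high) -> 1; (low, high) -> 2; (high, low) -> 3; (low, low) -> 4.
#'
#' @param solubility_class "high" or "low".
#' @param permeability_class "high" or "low".
#' @return Integer class 1-4.
#' @export
bcs_class <- function(solubility_class, permeability_class) {
  s <- match.arg(solubility_class, c("high", "low"))
  p <- match.arg(permeability_class, c("high", "low"))
  if (s == "high" && p == "high") 1L
  else if (s == "low" && p == "high") 2L
  else if (s == "high" && p == "low") 3L
  else 4L
}

#' Assemble a provisional BCS record
#'
#' @param do_by_ph named vector of dose numbers per pH.
#' @param perm_evidence data.frame (`method`, `class`) of per-method
#'   permeability classifications.
#' @param regulatory_ph_range pH window used for the solubility class
#'   (default the 1.2-6.8 regulatory range; other pH values are kept in the
#'   record but do not drive the class).
#' @return Object of class `bcs_record` with `do_by_ph`,
#'   `solubility_class`, `permeability_class`, `bcs_class`, `evidence`.
#' @export
bcs_record <- function(do_by_ph, perm_evidence,
                       regulatory_ph_range = c(1.2, 6.8)) {
  ph <- as.numeric(names(do_by_ph))
  if (any(is.na(ph))) stop("do_by_ph must be named by pH")
  in_range <- ph >= regulatory_ph_range[1] & ph <= regulatory_ph_range[2]
  if (!any(in_range)) stop("no pH inside the regulatory range")
  sol <- solubility_class(do_by_ph[in_range])
  perm <- permeability_class(perm_evidence)
  structure(
    list(do_by_ph = do_by_ph, solubility_class = sol,
         permeability_class = perm$class,
         bcs_class = bcs_class(sol, perm$class),
         evidence = perm$evidence),
    class = "bcs_record")
}

#' Predicted fraction absorbed from permeability
#'
#' Evaluates a caller-supplied permeability-to-Fabs correlation. Two
#' functional forms are supported: exponential saturation
#' Fabs = 100 (1 - exp(-k Peff)) with `parameters$k` > 0, and a logistic in
#' log10 Peff, Fabs = 100 / (1 + 10^(b (x50 - log10 Peff))) with
#' `parameters$x50` and `parameters$b` > 0. The result is clamped to
#' [0, 100]. The correlation coefficients come from a validated reference
#' set and must be supplied by the caller; none are shipped as defaults.
#'
#' @param peff permeability (cm/s), vectorized.
#' @param form "exponential-saturation" or "logistic".
#' @param parameters named list of coefficients.
#' @return Fabs in percent.
#' @export
predict_fabs <- function(peff,
                         form = c("exponential-saturation", "logistic"),
                         parameters) {
  form <- match.arg(form)
  if (form == "exponential-saturation") {
    if (is.null(parameters$k)) stop("missing parameter k")
    if (parameters$k <= 0) stop("k must be > 0")
    fabs <- 100 * (1 - exp(-parameters$k * peff))
  } else {
    if (is.null(parameters$x50) || is.null(parameters$b))
      stop("missing parameters x50 and/or b")
    if (parameters$b <= 0) stop("b must be > 0")
    fabs <- 100 / (1 + 10^(parameters$b * (parameters$x50 - log10(peff))))
    fabs[peff <= 0] <- 0
  }
  pmin(100, pmax(0, fabs))
}
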