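#' Measured solubility-pH profile of JM-20
#'
#' Shake-flask equilibrium solubility of the benzodiazepine-dihydropyridine
#' hybrid JM-20 at 37 C in six USP buffers, with the dose number computed for
#' a 140 mg dose (2 mg/kg x 70 kg) in 250 mL. The chloride background is the
#' buffer's chloride molarity: the pH 1.2 medium is an HCl/KCl buffer
#' (50 mL 0.2 M KCl + 13 mL 0.2 M HCl to 200 mL, 63 mM chloride); the
#' acetate, phosphate and borate buffers contribute none.
#'
#' @return A data.frame with columns `ph`, `solubility` (ug/mL), `sd`
#'   (ug/mL), `do` (dose number, dimensionless), `chloride` (mol/L buffer
#'   chloride background) and `temperature_C`.
#' @examples
#' jm20_solubility()
#' @export
jm20_solubility <- function() {
  data.frame(
    ph         = c(1.2, 3.5, 4.0, 4.5, 6.8, 7.4),
    solubility = c(9.18, 12.72, 25.38, 30.84, 11.30, 12.64),
    sd         = c(0.16, 0.83, 0.66, 1.29, 0.69, 0.36),
    do         = c(61.00, 44.03, 22.06, 18.16, 49.56, 44.30),
    chloride   = c(0.063, 0, 0, 0, 0, 0),
    temperature_C = 37
  )
}

#' Reported apparent permeability of JM-20 across epithelial monolayers
#'
#' Bidirectional apparent permeability coefficients (mean +/- sd, n
#' replicates) for JM-20 across MDCK, MDCK-MDR1 and Caco-2 monolayers at
#' 37 C, in units of 1e-5 cm/s.
#'
#' @return A data.frame with columns `cell_line`, `direction`, `papp_1e5`
#'   and `sd_1e5`.
#' @export
jm20_papp <- function() {
  data.frame(
    cell_line = rep(c("MDCK-MDR1", "MDCK", "Caco-2"), each = 2),
    direction = rep(c("A-B", "B-A"), 3),
    papp_1e5  = c(2.17, 0.96, 2.46, 0.28, 3.83, 0.85),
    sd_1e5    = c(0.22, 0.05, 0.11, 0.71, 0.18, 0.24)
  )
}

#' Reported effective intestinal permeability of JM-20 (closed-loop perfusion)
#'
#' Segment-wise effective permeability of JM-20 from the closed-loop rat
#' perfusion model (mean +/- sd over n = 4 animals), with the metoprolol
#' reference values measured under the same conditions, in 1e-5 cm/s.
#'
#' @return A data.frame with columns `segment`, `peff_1e5`, `sd_1e5`,
#'   `metoprolol_1e5`.
#' @export
jm20_peff <- function() {
  data.frame(
    segment        = c("duodenum", "jejunum", "ileum"),
    peff_1e5       = c(9.20, 6.63, 6.82),
    sd_1e5         = c(0.89, 1.30, 1.44),
    metoprolol_1e5 = c(NA, 6.23, 9.5)
  )
}

#' Default study configuration for JM-20
#'
#' Bundles the compound-level constants used throughout the JM-20 analyses:
#' molecular weight, the spectrophotometric pKa values at 23 C, their 37 C
#' counterparts, the linear temperature coefficients that connect the two
#' temperatures (back-derived from that pair of determinations, not an
#' independently measured d(pKa)/dT), the dose convention and the
#' metoprolol reference permeabilities per method.
#'
#' @return A named list.
#' @export
jm20_config <- function() {
  list(
    compound = "JM-20",
    molecular_weight = 404.4,
    pka = list(
      basic  = list(value = 5.48, sd = 0.19, temperature_C = 23),
      acidic = list(value = 10.49, sd = 0.17, temperature_C = 23)
    ),
    pka_37C = c(basic = 5.54, acidic = 10.33),
    # back-derived: (5.54 - 5.48)/14 and (10.33 - 10.49)/14 per degree C
    dpka_dT = c(basic = 0.06 / 14, acidic = -0.16 / 14),
    dose = list(dose_mg_per_kg = 2, body_weight_kg = 70, v0_mL = 250),
    # metoprolol Papp/Peff under matching conditions (1e-5 cm/s); the cell
    # reference is the Caco-2/MDCK-scale value commonly used for the
    # high-permeability cut-off in this assay family
    reference = list(
      compound = "metoprolol",
      transwell_1e5 = 2.0,
      perfusion_1e5 = c(jejunum = 6.23, ileum = 9.5)
    )
  )
}
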