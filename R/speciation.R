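#' Ampholyte speciation-solubility model
#'
#' Parameter container for the solubility-pH model of an ordinary ampholyte
#' XH with a basic centre (XH2+ <-> XH + H+, pKa1) and an acidic centre
#' (XH <-> X- + H+, pKa2), optionally precipitating as a hydrochloride salt
#' XH2+Cl- with solubility product Ksp.
#'
#' @param s0 intrinsic solubility of the neutral species (ug/mL).
#' @param pka1 basic pKa (protonation of the neutral form).
#' @param pka2 acidic pKa (deprotonation of the neutral form).
#' @param pksp -log10 of the salt solubility product (mol^2/L^2 scale), or
#'   NULL for a model without a salt phase.
#' @param molecular_weight g/mol, used to convert molar speciation to
#'   mass-concentration solubility.
#' @param activity_A Debye-Huckel A coefficient (0.509 at 25 C).
#' @param activity_b Davies linear-term coefficient.
#' @return Object of class `speciation_model`.
#' @export
speciation_model <- function(s0, pka1, pka2, pksp = NULL,
                             molecular_weight = 404.4,
                             activity_A = 0.509, activity_b = 0.3) {
  if (s0 <= 0) stop("s0 must be > 0")
  if (pka1 >= pka2) stop("pka1 must be < pka2 for an ordinary ampholyte")
  if (!is.null(pksp) && !is.finite(pksp)) stop("pksp must be finite or NULL")
  structure(
    list(s0 = s0, pka1 = pka1, pka2 = pka2, pksp = pksp,
         molecular_weight = molecular_weight,
         activity_A = activity_A, activity_b = activity_b),
    class = "speciation_model")
}

#' Henderson-Hasselbalch solubility of an ampholyte
#'
#' Closed-form free-base branch: when the saturating solid is the neutral
#' ampholyte, S(pH) = S0 (1 + 10^(pKa1 - pH) + 10^(pH - pKa2)). Activity
#' coefficients are taken as unity and any salt phase is ignored.
#'
#' @param ph pH (vectorized).
#' @param model a [speciation_model()].
#' @return Solubility in ug/mL.
#' @export
hh_solubility_ampholyte <- function(ph, model) {
  stopifnot(inherits(model, "speciation_model"))
  model$s0 * (1 + 10^(model$pka1 - ph) + 10^(ph - model$pka2))
}

#' Davies activity coefficient
#'
#' log10 gamma = -A z^2 (sqrt(I)/(1 + sqrt(I)) - b I), the Davies extension
#' of Debye-Huckel theory, adequate for ionic strengths up to ~0.5 M.
#'
#' @param ionic_strength mol/L, >= 0 (vectorized).
#' @param charge integer ion charge.
#' @param A,b Davies coefficients (defaults 0.509 at 25 C and 0.3).
#' @return Activity coefficient gamma (dimensionless).
#' @export
davies_gamma <- function(ionic_strength, charge = 1, A = 0.509, b = 0.3) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  sqI <- sqrt(ionic_strength)
  10^(-A * charge^2 * (sqI / (1 + sqI) - b * ionic_strength))
}

#' Salt-limited solubility branch at fixed chloride
#'
#' Total dissolved drug when the hydrochloride salt XH2+Cl- is the
#' saturating phase and the chloride activity is controlled externally:
#' the cation concentration follows the solubility product,
#' \[XH2+\] = Ksp / (gamma^2 \[Cl-\]), and the neutral and anionic species
#' equilibrate with it, so S = \[XH2+\] (1 + 10^(pH - pKa1) +
#' 10^(2 pH - pKa1 - pKa2)), converted to ug/mL. Doubling the chloride
#' background halves the branch (the common-ion effect).
#'
#' @param ph pH (vectorized).
#' @param model a [speciation_model()] with a `pksp`.
#' @param chloride chloride concentration (mol/L), > 0.
#' @param gamma activity coefficient of the monovalent ions (default 1).
#' @return Solubility in ug/mL.
#' @export
salt_branch_solubility <- function(ph, model, chloride, gamma = 1) {
  stopifnot(inherits(model, "speciation_model"))
  if (is.null(model$pksp)) stop("model has no salt phase (pksp is NULL)")
  if (any(chloride <= 0)) stop("chloride must be > 0")
  ksp <- 10^(-model$pksp)
  bh <- ksp / (gamma^2 * chloride)
  s_molar <- bh * (1 + 10^(ph - model$pka1) + 10^(2 * ph - model$pka1 - model$pka2))
  s_molar * model$molecular_weight * 1000
}

# Salt branch when the dissolving salt itself supplies chloride on top of a
# background: solve [BH][BH + cl_bg] = Ksp/gamma^2 (positive quadratic root).
salt_branch_self <- function(ph, model, cl_background = 0, gamma = 1) {
  ksp_eff <- 10^(-model$pksp) / gamma^2
  bh <- (-cl_background + sqrt(cl_background^2 + 4 * ksp_eff)) / 2
  s_molar <- bh * (1 + 10^(ph - model$pka1) + 10^(2 * ph - model$pka1 - model$pka2))
  list(s = s_molar * model$molecular_weight * 1000, bh = bh)
}

# Dissolved-species molarities on the free-base branch (gamma = 1 ratios).
hh_species_molar <- function(ph, model) {
  s0_m <- model$s0 / (model$molecular_weight * 1000)
  list(bh = s0_m * 10^(model$pka1 - ph), x = s0_m * 10^(ph - model$pka2))
}

#' Simulate a full-range solubility-pH titration
#'
#' Sweeps the pH grid upward from `ph_start` to `ph_end` in steps of `step`,
#' at each point deciding the saturating solid phase (neutral ampholyte vs
#' hydrochloride salt; the phase rule picks whichever predicts the lower
#' total solubility), balancing chloride (buffer background plus strong-acid
#' titrant below neutrality plus the salt's own dissolution) and iterating
#' the ionic strength / Davies activity correction to a fixed point.
#'
#' @param model a [speciation_model()].
#' @param ph_start,ph_end,step pH grid (defaults 0 to 13 in steps of 0.2).
#' @param chloride_background buffer chloride (mol/L) present at every pH.
#' @param titrant_hcl if TRUE, strong-acid titrant chloride ~ \[H+\] is added
#'   below neutrality (the source of the common-ion downturn at low pH).
#' @param fixed_chloride if non-NULL, chloride is pinned at this value
#'   everywhere and the salt's own dissolution is not added to it (the
#'   fixed-chloride two-branch reduction).
#' @param use_activity if FALSE, gamma is forced to 1.
#' @param i_tol convergence tolerance of the ionic-strength fixed point
#'   (mol/L).
#' @param max_iter maximum fixed-point iterations per pH.
#' @return data.frame with columns `ph`, `ionic_strength`, `s_calc` (ug/mL),
#'   `saturating_phase` ("neutral" or "salt") and `chloride` (mol/L).
#' @export
simulate_titration <- function(model, ph_start = 0, ph_end = 13, step = 0.2,
                               chloride_background = 0, titrant_hcl = TRUE,
                               fixed_chloride = NULL, use_activity = TRUE,
                               i_tol = 1e-6, max_iter = 100) {
  stopifnot(inherits(model, "speciation_model"), step > 0)
  grid <- seq(ph_start, ph_end, by = step)
  out <- data.frame(ph = grid, ionic_strength = NA_real_, s_calc = NA_real_,
                    saturating_phase = NA_character_, chloride = NA_real_)
  for (g in seq_along(grid)) {
    ph <- grid[g]
    h <- 10^(-ph)
    oh <- 10^(ph - 14)
    cl_ext <- if (!is.null(fixed_chloride)) fixed_chloride else
      chloride_background + if (titrant_hcl) max(0, h - 1e-7) else 0
    I <- cl_ext + h + oh   # starting guess
    gamma <- 1
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      if (use_activity) gamma <- davies_gamma(I, 1, model$activity_A, model$activity_b)
      s_hh <- hh_solubility_ampholyte(ph, model)
      hh_sp <- hh_species_molar(ph, model)
      if (!is.null(model$pksp)) {
        if (!is.null(fixed_chloride)) {
          s_salt <- salt_branch_solubility(ph, model, fixed_chloride, gamma)
          bh_salt <- 10^(-model$pksp) / (gamma^2 * fixed_chloride)
        } else {
          sb <- salt_branch_self(ph, model, cl_ext, gamma)
          s_salt <- sb$s
          bh_salt <- sb$bh
        }
      } else {
        s_salt <- Inf
        bh_salt <- 0
      }
      if (s_salt < s_hh) {
        phase <- "salt"
        s_calc <- s_salt
        bh <- bh_salt
        x <- bh * 10^(2 * ph - model$pka1 - model$pka2)
      } else {
        phase <- "neutral"
        s_calc <- s_hh
        bh <- hh_sp$bh
        x <- hh_sp$x
      }
      cl_tot <- cl_ext +
        if (phase == "salt" && is.null(fixed_chloride)) bh else 0
      na <- max(0, oh + cl_tot + x - h - bh)  # electroneutrality balance
      I_new <- 0.5 * (h + oh + cl_tot + bh + x + na)
      if (!use_activity || abs(I_new - I) < i_tol) {
        I <- I_new
        converged <- TRUE
        break
      }
      I <- I_new
    }
    if (!converged)
      stop("ionic-strength fixed point did not converge at pH ", ph)
    out$ionic_strength[g] <- I
    out$s_calc[g] <- s_calc
    out$saturating_phase[g] <- phase
    out$chloride[g] <- cl_tot
  }
  out
}

# Predicted solubility (ug/mL) at measured-point conditions: free-base
# branch vs self-consistent salt branch at the point's buffer chloride,
# with one Davies pass when activity is on.
predict_point_solubility <- function(model, ph, chloride = 0,
                                     use_activity = TRUE) {
  n <- length(ph)
  chloride <- rep_len(chloride, n)
  vapply(seq_len(n), function(i) {
    gamma <- 1
    if (use_activity && !is.null(model$pksp)) {
      # estimate I from the salt branch at gamma = 1, then correct once more
      for (it in 1:25) {
        sb <- salt_branch_self(ph[i], model, chloride[i], gamma)
        hh_sp <- hh_species_molar(ph[i], model)
        salt_active <- sb$s < hh_solubility_ampholyte(ph[i], model)
        bh <- if (salt_active) sb$bh else hh_sp$bh
        I <- chloride[i] + 10^(-ph[i]) + 10^(ph[i] - 14) +
          if (salt_active) 2 * bh else bh
        g_new <- davies_gamma(I, 1, model$activity_A, model$activity_b)
        if (abs(g_new - gamma) < 1e-9) break
        gamma <- g_new
      }
    }
    s_hh <- hh_solubility_ampholyte(ph[i], model)
    if (is.null(model$pksp)) return(s_hh)
    s_salt <- salt_branch_self(ph[i], model, chloride[i], gamma)$s
    min(s_hh, s_salt)
  }, numeric(1))
}

#' Refine speciation-model constants against measured solubility
#'
#' Weighted nonlinear least-squares refinement in log-solubility space:
#' minimizes sum w_i (log10 S_meas,i - log10 S_calc,i)^2 with
#' w_i = 1/sigma_i^2, sigma_i the measurement sd propagated to log10 units
#' (sd / (S ln 10)) and floored at `sigma_floor`. The optimizer is
#' Levenberg-Marquardt (damped Gauss-Newton) on the weighted residuals.
#' Points named in `exclude_ph` are left out of the objective but their
#' residuals are still reported.
#'
#' @param points data.frame with columns `ph`, `solubility` (ug/mL) and
#'   optionally `sd` (ug/mL) and `chloride` (mol/L buffer background).
#' @param initial a [speciation_model()] supplying starting values and all
#'   fixed parameters.
#' @param free character subset of c("s0", "pksp", "pka1", "pka2") to
#'   refine; s0 is refined on the log10 scale.
#' @param exclude_ph pH values (matched within 1e-6) excluded from the fit.
#' @param sigma_floor minimum log10 sd (default 0.02) to avoid infinite
#'   weights on tiny reported sds.
#' @param use_activity apply Davies corrections at each point.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @return List of class `refinement_result`: `model` (refined),
#'   `weighted_sse`, `iterations`, `converged`, `residuals` (per-point
#'   log10 differences, all points), `excluded` (logical mask).
#' @export
refine_model <- function(points, initial, free = c("s0", "pksp"),
                         exclude_ph = NULL, sigma_floor = 0.02,
                         use_activity = TRUE, max_iter = 100) {
  stopifnot(inherits(initial, "speciation_model"))
  free <- match.arg(free, c("s0", "pksp", "pka1", "pka2"), several.ok = TRUE)
  if (nrow(points) < 3) stop("need at least 3 solubility points")
  if ("pksp" %in% free && is.null(initial$pksp))
    stop("refining pksp requires a starting value in `initial`")
  sd_col <- if ("sd" %in% names(points)) points$sd else rep(0, nrow(points))
  cl_col <- if ("chloride" %in% names(points)) points$chloride else rep(0, nrow(points))
  excluded <- rep(FALSE, nrow(points))
  if (!is.null(exclude_ph))
    excluded <- vapply(points$ph, function(p) any(abs(p - exclude_ph) < 1e-6),
                       logical(1))
  if (sum(!excluded) < length(free))
    stop("fewer usable points than free parameters")
  sigma <- pmax(sigma_floor, sd_col / (points$solubility * log(10)))
  w <- 1 / sigma^2

  theta0 <- vapply(free, function(p) switch(p,
    s0 = log10(initial$s0), pksp = initial$pksp,
    pka1 = initial$pka1, pka2 = initial$pka2), numeric(1))
  apply_theta <- function(theta) {
    m <- initial
    for (j in seq_along(free)) {
      m[[free[j]]] <- unname(if (free[j] == "s0") 10^theta[j] else theta[j])
    }
    m
  }
  resid_all <- function(theta) {
    m <- apply_theta(theta)
    s_calc <- predict_point_solubility(m, points$ph, cl_col, use_activity)
    log10(points$solubility) - log10(s_calc)
  }
  fn <- function(theta) (sqrt(w) * resid_all(theta))[!excluded]

  fit <- minpack.lm::nls.lm(
    par = theta0, fn = fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-10, ptol = 1e-10))
  converged <- fit$info %in% 1:4
  model <- apply_theta(fit$par)
  r <- resid_all(fit$par)
  structure(
    list(model = model,
         weighted_sse = sum((w * r^2)[!excluded]),
         iterations = fit$niter,
         converged = converged,
         info = fit$message,
         residuals = r,
         excluded = excluded),
    class = "refinement_result")
}

#' Calculated solubility at requested pH values
#'
#' Runs the titration simulator and interpolates log10 S linearly to the
#' requested pH values (grid pH values are returned exactly).
#'
#' @param model a refined [speciation_model()].
#' @param ph_list pH values; must lie within the simulated range.
#' @param ... passed to [simulate_titration()].
#' @return data.frame with columns `ph` and `s_calc` (ug/mL).
#' @export
calculated_solubility_table <- function(model, ph_list, ...) {
  sim <- simulate_titration(model, ...)
  if (any(ph_list < min(sim$ph) - 1e-9 | ph_list > max(sim$ph) + 1e-9))
    stop("requested pH outside simulated range [",
         min(sim$ph), ", ", max(sim$ph), "]")
  ls <- stats::approx(sim$ph, log10(sim$s_calc), xout = ph_list)$y
  data.frame(ph = ph_list, s_calc = 10^ls)
}
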