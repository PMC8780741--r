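# preformr

Early-stage biopharmaceutical preformulation analysis in R: estimate pKa
from absorbance–pH spectra, model and refine the solubility–pH profile of
an ampholyte with hydrochloride-salt formation, fit apparent permeability
from non-sink transwell assays and effective permeability from closed-loop
(Doluisio) intestinal perfusion, and combine dose number with
reference-compound permeability comparisons into a provisional BCS
(Biopharmaceutics Classification System) class.

The package is aimed at preformulation and DMPK scientists characterizing
a new chemical entity from the handful of small tables such programs
produce. Its worked example is JM-20, a neuroprotective
benzodiazepine–dihydropyridine hybrid and ordinary ampholyte
(pKa 5.54/10.33 at 37 °C, MW 404.4), whose measured solubility and
permeability tables ship with the package.

## The models

**Solubility.** For an ampholyte saturated with the neutral solid,
S(pH) = S₀(1 + 10^(pKa₁−pH) + 10^(pH−pKa₂)) (Henderson–Hasselbalch
branch). Below pH_max the hydrochloride salt is the stable solid and the
solubility product rules: [XH₂⁺] = Ksp/(γ²[Cl⁻]), with the Davies
equation for γ and the chloride balance including buffer background,
strong-acid titrant, and the salt's own dissolution. `simulate_titration()`
sweeps pH 0→13 in 0.2 steps with self-consistent ionic strength;
`refine_model()` fits S₀ and pKsp to measured (pH, S) points by weighted
nonlinear least squares in log₁₀ S (weights 1/σ², σ floored at 0.02 log
units). The dose number Do = D/(V₀·Cs) with V₀ = 250 mL classifies
solubility (high iff worst-case Do ≤ 1 over pH 1.2–6.8).

**Permeability.** Transwell assays are fitted with the interval-exact
non-sink solution: between samplings the receiver relaxes toward
Q/(V_r+V_d) at rate P_app·S·(1/V_r+1/V_d); each sampling removes mass and
dilutes by f = (V_r−v_s)/V_r. Perfusion time courses are volume-corrected
for water flux (C_t = C_e·V_t/V₀), fitted as C_t = C₀e^(−k_a t), and
converted via the cylinder radius r = √(V/(πL)) to P_eff = r·k_a/2.
Permeability class is assigned per method against a reference compound
(metoprolol) and majority-voted.

## Worked example

```r
library(preformr)

tab <- jm20_solubility()          # measured shake-flask table, 37 C
cfg <- jm20_config()

# dose numbers for the 2 mg/kg x 70 kg = 140 mg dose
do <- dose_number(140, tab$solubility / 1000)
round(do, 2)
#> [1] 61.00 44.03 22.06 18.16 49.56 44.30

# refine intrinsic solubility + salt term (pKa fixed at 37 C values,
# pH 1.2 excluded from the salt fit)
fit <- refine_model(tab,
                    speciation_model(20, 5.54, 10.33, pksp = 8),
                    free = c("s0", "pksp"), exclude_ph = 1.2)
round(fit$model$s0, 2)
#> [1] 11.79        # intrinsic solubility, ug/mL
round(fit$model$pksp, 2)
#> [1] 8.51

# provisional BCS class from the evidence
names(do) <- tab$ph
rec <- bcs_record(do, data.frame(method = c("MDCK", "Caco-2", "rat"),
                                 class = c("high", "high", "high")))
rec$bcs_class
#> [1] 2            # low solubility, high permeability
```

All six dose numbers are far above 1 (the 140 mg dose would need tens of
liters to dissolve), so the compound is low-solubility; its permeability
exceeds the metoprolol reference in every method, so the provisional class
is 2 — absorption is expected to be solubility-limited.

The `analysis/` directory holds the numbered workflow scripts
(`01_pka.R` … `05_bcs.R`) that run each stage end to end and write their
tables under `results/`. Stages whose raw measurements were never
published (spectra, transwell and perfusion time courses) run on seeded
synthetic assays generated at the reported values, with the generator
truth recorded alongside.

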