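#!/usr/bin/env Rscript
# Provisional BCS classification of JM-20.
#
# Combines the measured solubility table (dose numbers for the 140 mg dose,
# 2 mg/kg x 70 kg, in 250 mL) with per-method permeability classifications
# against metoprolol into the four-quadrant provisional class, and runs the
# whole pipeline end to end through the orchestrator.

suppressPackageStartupMessages(library(preformr))
dir.create("results", showWarnings = FALSE)
cfg <- jm20_config()
tab <- jm20_solubility()

dose <- highest_dose_from_weight(cfg$dose$dose_mg_per_kg,
                                 cfg$dose$body_weight_kg)
do <- dose_number(dose, tab$solubility / 1000, cfg$dose$v0_mL)
names(do) <- tab$ph
cat("dose:", dose, "mg; dose numbers:\n")
print(round(do, 2))

# permeability evidence: reported means per method vs matching references
papp <- jm20_papp()
peff <- jm20_peff()
evidence <- rbind(
  do.call(rbind, lapply(unique(papp$cell_line), function(cl) {
    v <- papp$papp_1e5[papp$cell_line == cl & papp$direction == "A-B"]
    data.frame(method = cl,
               class = compare_to_reference(
                 v, cfg$reference$transwell_1e5)$class)
  })),
  data.frame(method = "rat perfusion",
             class = compare_to_reference(
               max(peff$peff_1e5),
               max(cfg$reference$perfusion_1e5))$class))

rec <- bcs_record(do, evidence)
cat("\nsolubility class:", rec$solubility_class,
    "(worst-case Do", round(max(do), 1), "in pH 1.2-6.8)\n")
cat("permeability class:", rec$permeability_class, "\n")
print(rec$evidence, row.names = FALSE)
cat("provisional BCS class:", rec$bcs_class, "\n")

jsonlite::write_json(unclass(rec), "results/bcs_record.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE,
                     force = TRUE)

# end-to-end orchestrated run on the same inputs plus synthetic assay data
tw <- gen_transwell(papp_true = 3.83e-5, efflux_asymmetry = 0.22,
                    noise_sd = 0.02, seed = 20260920)
pa <- gen_perfusion(peff_true = 9.2e-5, water_flux_rate = 0.05,
                    noise_sd = 0.03, seed = 20260920)
report <- run_pipeline(list(
  pka = list(values = unname(cfg$pka_37C)),
  dose = cfg$dose,
  solubility = tab,
  speciation = list(
    initial = speciation_model(20, cfg$pka_37C[["basic"]],
                               cfg$pka_37C[["acidic"]], pksp = 8,
                               molecular_weight = cfg$molecular_weight),
    exclude_ph = 1.2),
  transwell = list(tw$ab, tw$ba),
  perfusion = list(pa),
  reference = list(transwell = cfg$reference$transwell_1e5 * 1e-5,
                   perfusion = max(cfg$reference$perfusion_1e5) * 1e-5)))
write_report(report, "results/bcs")
cat("\npipeline BCS class:", report$bcs$bcs_class,
    "| refined S0:", round(report$solubility$s0, 2), "ug/mL",
    "| efflux ratio:", round(report$transwell$efflux_ratio, 2), "\n")
cat("wrote results/bcs_record.json and results/bcs/\n")
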