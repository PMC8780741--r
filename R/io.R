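# Shared CSV ingestion with schema validation, plus the end-to-end study
# orchestrator. Concentrations are normalized to ug/mL (solubility) and uM
# (assay concentrations); permeability is cm/s throughout.

#' Read and validate a CSV table against a simple schema
#'
#' @param path CSV file (UTF-8, header row, '.' decimal separator).
#' @param required character vector of required column names.
#' @param numeric_cols columns that must parse as finite numbers.
#' @return data.frame of validated records.
#' @export
read_table <- function(path, required, numeric_cols = required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "),
         " in ", path)
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("unparseable number in column '", col, "', row ", bad[1],
           " of ", path)
    df[[col]] <- v
  }
  df
}

#' Read a solubility-pH table
#'
#' Expects columns `ph` and `solubility_ug_per_mL` (or
#' `solubility_mg_per_mL`, converted to ug/mL), optional `sd` (same unit)
#' and `chloride_M`.
#'
#' @param path CSV file.
#' @return data.frame with columns `ph`, `solubility` (ug/mL), `sd`,
#'   `chloride`.
#' @export
read_solubility_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  unit <- if ("solubility_ug_per_mL" %in% names(df)) 1
          else if ("solubility_mg_per_mL" %in% names(df)) 1000
          else stop("missing column(s): solubility_ug_per_mL (or _mg_per_mL) in ", path)
  df <- read_table(path, c("ph", grep("^solubility_", names(df), value = TRUE)[1]))
  sol_col <- grep("^solubility_", names(df), value = TRUE)[1]
  out <- data.frame(ph = df$ph, solubility = df[[sol_col]] * unit)
  out$sd <- if ("sd" %in% names(df)) as.numeric(df$sd) * unit else 0
  out$chloride <- if ("chloride_M" %in% names(df)) as.numeric(df$chloride_M) else 0
  out
}

#' Read a long-format absorbance-pH spectra table
#'
#' Expects columns `wavelength_nm`, `pH`, `absorbance` (one row per
#' reading); builds a [spectral_series()].
#'
#' @param path CSV file.
#' @param temperature_C temperature of the determination.
#' @return A [spectral_series()].
#' @export
read_spectra_table <- function(path, temperature_C = 23) {
  df <- read_table(path, c("wavelength_nm", "pH", "absorbance"))
  wl <- sort(unique(df$wavelength_nm))
  ph <- sort(unique(df$pH))
  A <- matrix(NA_real_, length(ph), length(wl))
  A[cbind(match(df$pH, ph), match(df$wavelength_nm, wl))] <- df$absorbance
  if (any(is.na(A))) stop("incomplete wavelength x pH grid in ", path)
  spectral_series(wl, ph, A, temperature_C = temperature_C)
}

#' Write a study report to disk
#'
#' Emits machine-readable JSON plus CSV tables (dose-number table,
#' permeability summary) for whatever stages the report contains.
#'
#' @param report list from [run_pipeline()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(report, paths[1], force = TRUE,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$solubility$do_table)) {
    p <- file.path(dir, "dose_numbers.csv")
    utils::write.csv(report$solubility$do_table, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(report$permeability$summary)) {
    p <- file.path(dir, "permeability.csv")
    utils::write.csv(report$permeability$summary, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Run the full preformulation pipeline
#'
#' Executes the available stages in dependency order: spectra -> pKa;
#' solubility -> speciation refinement -> dose numbers -> solubility class;
#' transwell/perfusion -> permeability classes; everything -> provisional
#' BCS class. Stages without inputs are skipped and recorded as absent; a
#' stage error is caught, recorded, and its dependents are marked skipped.
#'
#' @param config named list. Recognized blocks: `spectra` (a
#'   [spectral_series()] or file path), `pka` (list with `values`
#'   = c(pka1, pka2) to use directly, bypassing spectra), `solubility`
#'   (data.frame `ph`/`solubility`/`sd`/`chloride` or file path), `dose`
#'   (list `dose_mg` or `dose_mg_per_kg` + `body_weight_kg`, `v0_mL`),
#'   `speciation` (list `initial` model, `free`, `exclude_ph`),
#'   `transwell` (list of [transwell_assay()] objects, or a list with
#'   `ab`/`ba`), `perfusion` (list of [perfusion_assay()] objects),
#'   `reference` (list with `transwell` and/or `perfusion` reference
#'   permeabilities, cm/s), `split_ph` for the pKa windows.
#' @return List of class `study_report` with one element per stage plus
#'   `errors`.
#' @export
run_pipeline <- function(config) {
  report <- list(errors = list())
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- pKa ----------------------------------------------------------------
  pka_values <- NULL
  if (!is.null(config$pka$values)) {
    pka_values <- config$pka$values
    report$pka <- list(source = "supplied", pka1 = pka_values[1],
                       pka2 = pka_values[2])
  } else if (!is.null(config$spectra)) {
    report$pka <- run_stage("pka", {
      series <- config$spectra
      if (is.character(series)) series <- read_spectra_table(series)
      est <- estimate_pkas(series,
                           split_ph = if (is.null(config$split_ph)) 8
                                      else config$split_ph)
      pka_values <- c(est$basic$value, est$acidic$value)
      list(source = "spectra", pka1 = est$basic$value,
           pka2 = est$acidic$value, basic = est$basic, acidic = est$acidic)
    })
  }

  # --- dose ---------------------------------------------------------------
  dose_mg <- NULL
  if (!is.null(config$dose)) {
    dose_mg <- if (!is.null(config$dose[["dose_mg"]])) config$dose[["dose_mg"]]
      else highest_dose_from_weight(config$dose[["dose_mg_per_kg"]],
                                    config$dose[["body_weight_kg"]])
  }

  # --- solubility ---------------------------------------------------------
  if (!is.null(config$solubility)) {
    report$solubility <- run_stage("solubility", {
      pts <- config$solubility
      if (is.character(pts)) pts <- read_solubility_table(pts)
      out <- list(points = pts)
      if (!is.null(config$speciation$initial)) {
        ref <- refine_model(pts, config$speciation$initial,
                            free = if (is.null(config$speciation$free))
                              c("s0", "pksp") else config$speciation$free,
                            exclude_ph = config$speciation$exclude_ph)
        out$refinement <- ref
        out$s0 <- ref$model$s0
      }
      if (!is.null(dose_mg)) {
        v0 <- if (is.null(config$dose$v0_mL)) 250 else config$dose$v0_mL
        do <- dose_number(dose_mg, pts$solubility / 1000, v0)
        names(do) <- pts$ph
        out$do_table <- data.frame(ph = pts$ph,
                                   solubility_ug_per_mL = pts$solubility,
                                   do = round(do, 2))
        out$do_by_ph <- do
        out$solubility_class <- solubility_class(
          do[pts$ph >= 1.2 & pts$ph <= 6.8])
      }
      out
    })
  }

  # --- permeability -------------------------------------------------------
  evidence <- NULL
  perm_rows <- list()
  if (!is.null(config$transwell)) {
    report$transwell <- run_stage("transwell", {
      assays <- config$transwell
      if (inherits(assays, "transwell_assay")) assays <- list(assays)
      fits <- lapply(assays, fit_papp)
      ab <- Filter(function(x) x$direction == "A-B", fits)
      ba <- Filter(function(x) x$direction == "B-A", fits)
      out <- list(fits = fits)
      if (length(ab)) {
        papp_ab <- mean(vapply(ab, `[[`, numeric(1), "papp"))
        out$papp_ab <- papp_ab
        if (length(ba)) {
          papp_ba <- mean(vapply(ba, `[[`, numeric(1), "papp"))
          out$papp_ba <- papp_ba
          out$efflux_ratio <- efflux_ratio(papp_ba, papp_ab)
        }
        if (!is.null(config$reference$transwell)) {
          cmp <- compare_to_reference(papp_ab, config$reference$transwell)
          out$class <- cmp$class
          perm_rows[[length(perm_rows) + 1]] <-
            data.frame(method = "transwell", class = cmp$class)
        }
      }
      out
    })
  }
  if (!is.null(config$perfusion)) {
    report$perfusion <- run_stage("perfusion", {
      assays <- config$perfusion
      if (inherits(assays, "perfusion_assay")) assays <- list(assays)
      fits <- lapply(assays, fit_perfusion)
      summ <- summarize_peff(fits)
      out <- list(fits = fits, summary = summ)
      if (!is.null(config$reference$perfusion)) {
        cmp <- compare_to_reference(mean(summ$peff_mean),
                                    config$reference$perfusion)
        out$class <- cmp$class
        perm_rows[[length(perm_rows) + 1]] <-
          data.frame(method = "perfusion", class = cmp$class)
      }
      out
    })
  }
  if (length(perm_rows)) {
    evidence <- do.call(rbind, perm_rows)
    report$permeability <- c(permeability_class(evidence),
                             list(summary = evidence))
  }

  # --- BCS ----------------------------------------------------------------
  if (!is.null(report$solubility$do_by_ph) && !is.null(evidence)) {
    report$bcs <- run_stage("bcs", {
      bcs_record(report$solubility$do_by_ph, evidence)
    })
  } else {
    report$bcs <- list(
      bcs_class = NA_integer_,
      note = "undetermined: missing solubility and/or permeability evidence")
  }
  class(report) <- "study_report"
  report
}
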