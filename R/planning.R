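REPORT_SCHEMA_VERSION <- "avfsim-report/1"

#' Blood flow volume from a Doppler time-averaged velocity
#'
#' `BFV = TAV x pi (d/2)^2 x 60`: the cycle-averaged centerline-derived
#' velocity times the lumen cross-section, converted to mL/min
#' (cm/s x cm^2 x 60 s/min). The TAV is assumed already averaged over three
#' complete cardiac cycles at acquisition, as in the clinical protocol.
#'
#' @param tav time-averaged velocity, cm/s (>= 0).
#' @param diameter lumen diameter, mm (> 0).
#' @return mL/min (vectorized).
#' @examples
#' compute_bfv_from_tav(50, 4) # ~377 mL/min
#' @export
compute_bfv_from_tav <- function(tav, diameter) {
  stopifnot(all(tav >= 0), all(diameter > 0))
  area_cm2 <- pi * (diameter / 20)^2
  tav * area_cm2 * 60
}

# TAV measurement site -> segment providing the lumen diameter
TAV_DIAMETER_SITE <- c(brachial = "brachial-artery-mid",
                       radial = "radial-artery-mid",
                       ulnar = "ulnar-artery-mid")

#' Read a pre-operative patient form (JSON or CSV)
#'
#' The form mirrors the clinical pre-operative workflow: demographics and
#' clinical covariates (required), DUS diameters and TAVs (any subset), and
#' the planned AVF type and location. The dialect follows the file
#' extension. Validation reports every offending field at once.
#'
#' @param path `.json` (one object) or `.csv` (one row) file.
#' @return list of class `patient_form` with elements `patient`
#'   (`patient_record`), `dus` (`dus_measurements`), `config`
#'   (`avf_configuration`).
#' @export
read_patient_form <- function(path) {
  if (!file.exists(path)) stop("form file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (nrow(df) != 1)
        stop("CSV form must contain exactly one patient row (got ",
             nrow(df), "); split multi-patient tables first")
      csv_row_to_form(df[1, , drop = FALSE])
    },
    stop("unsupported form extension '.", ext, "' (use .json or .csv)"))
  form_from_list(raw)
}

csv_row_to_form <- function(row) {
  nm <- names(row)
  val <- function(f) if (f %in% nm && !is.na(row[[f]])) row[[f]] else NULL
  pat_fields <- c("age", "sex", "height", "weight", "systolic_pressure",
                  "diastolic_pressure", "hematocrit", "plasma_protein",
                  "hypertension", "diabetes", "heart_rate", "avf_arm")
  patient <- Filter(Negate(is.null), sapply(pat_fields, val,
                                            simplify = FALSE))
  pick_prefixed <- function(prefix, valid) {
    cols <- nm[startsWith(nm, prefix)]
    out <- list()
    for (cn in cols) {
      site <- gsub("\\.", "-", substring(cn, nchar(prefix) + 1))
      if (!is.na(row[[cn]])) out[[site]] <- row[[cn]]
    }
    out
  }
  list(patient = patient,
       dus = list(
         arterial_diameters = pick_prefixed("dia_", DUS_ARTERIAL_SITES),
         venous_diameters = pick_prefixed("vdia_", DUS_VENOUS_SITES),
         tav = pick_prefixed("tav_", DUS_TAV_SITES)),
       avf = list(location = val("avf_location"), kind = val("avf_kind")))
}

form_from_list <- function(raw) {
  errs <- character(0)
  p <- raw$patient
  if (is.null(p)) errs <- c(errs, "patient: block missing")
  required <- c("age", "sex", "height", "weight", "systolic_pressure",
                "diastolic_pressure", "hematocrit", "plasma_protein")
  missing <- required[!vapply(required, function(f)
    !is.null(p[[f]]) && !all(is.na(p[[f]])), TRUE)]
  if (length(missing) > 0)
    errs <- c(errs, paste0("patient: missing required field(s): ",
                           paste(missing, collapse = ", ")))
  if (is.null(raw$avf) || is.null(raw$avf$location) || is.null(raw$avf$kind))
    errs <- c(errs, "avf: planned location and kind are required")
  if (length(errs) > 0)
    stop("invalid patient form:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)

  patient <- patient_record(
    age = p$age, sex = p$sex, height = p$height, weight = p$weight,
    systolic_pressure = p$systolic_pressure,
    diastolic_pressure = p$diastolic_pressure,
    hematocrit = p$hematocrit, plasma_protein = p$plasma_protein,
    hypertension = p$hypertension %||% FALSE,
    diabetes = p$diabetes %||% FALSE,
    heart_rate = p$heart_rate,
    avf_arm = p$avf_arm %||% "left")
  dus <- dus_measurements(
    arterial_diameters = raw$dus$arterial_diameters,
    venous_diameters = raw$dus$venous_diameters,
    tav = raw$dus$tav)
  config <- avf_configuration(raw$avf$location, raw$avf$kind)
  structure(list(patient = patient, dus = dus, config = config),
            class = "patient_form")
}

#' Write a patient form to JSON
#' @param form `patient_form` (or a list with `patient`, `dus`, `config`).
#' @param path output `.json` path.
#' @return `path` invisibly.
#' @export
write_patient_form <- function(form, path) {
  pat <- form$patient
  payload <- list(
    patient = Filter(Negate(is.null), unclass(pat)),
    dus = list(
      arterial_diameters = as.list(form$dus$arterial_diameters),
      venous_diameters = as.list(form$dus$venous_diameters),
      tav = as.list(form$dus$tav)),
    avf = list(location = form$config$location, kind = form$config$kind))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Predict AVF outcome for a patient
#'
#' Composes the full pipeline (network personalization, periodic
#' hemodynamics, WSS-driven maturation) and assembles a prediction report:
#' pre-operative state, the 0-40 day time course of BFV and diameters at
#' the reporting sites, the day-40 headline brachial BFV, and diagnostics.
#' Deterministic: identical inputs give byte-identical reports.
#'
#' @param patient `patient_record`.
#' @param dus `dus_measurements`.
#' @param config `avf_configuration`; ignored when `compare_all = TRUE`.
#' @param settings `avf_settings`.
#' @param compare_all simulate all six (location x kind) configurations and
#'   return one report per configuration.
#' @param network optional pre-built generic network.
#' @return a `prediction_report`, or a named list of six when
#'   `compare_all = TRUE`.
#' @export
predict_avf <- function(patient, dus, config = NULL,
                        settings = avf_settings(), compare_all = FALSE,
                        network = NULL) {
  if (compare_all) {
    grid <- avf_configuration_grid()
    out <- lapply(grid, function(cf)
      predict_avf(patient, dus, cf, settings, FALSE, network))
    names(out) <- vapply(grid, avf_label, "")
    return(out)
  }
  if (is.null(config)) stop("an avf_configuration is required")
  sim <- simulate_maturation(patient, dus, config, settings, network)

  # DUS-derived pre-operative BFV where both TAV and diameter were measured
  dus_bfv <- list()
  for (site in names(sim_tav <- dus$tav)) {
    dseg <- TAV_DIAMETER_SITE[[site]]
    dmm <- dus$arterial_diameters[dseg]
    if (!is.na(dmm))
      dus_bfv[[site]] <- compute_bfv_from_tav(dus$tav[[site]], unname(dmm))
  }

  nd <- length(sim$days)
  structure(list(
    schema_version = REPORT_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("avfsim")),
    patient = Filter(Negate(is.null), unclass(sim_patient <- patient)),
    configuration = list(location = config$location, kind = config$kind,
                         label = avf_label(config)),
    preop = list(bfv_mlmin = sim$preop$bfv,
                 diameters_mm = sim$preop$diameters,
                 dus_bfv_mlmin = dus_bfv),
    maturation = list(days = sim$days,
                      bfv_mlmin = sim$bfv,
                      diameters_mm = sim$diameters),
    day40_brachial_bfv_mlmin = sim$bfv$brachial[nd],
    diagnostics = list(
      wss_converged = sim$wss_converged,
      wss_max_rel_error = max(sim$wss_rel_error),
      solver_cycles = sim$solver_cycles,
      hand_perfusion_mlmin = sim$hand_perfusion),
    units = list(bfv = "mL/min", diameters = "mm", days = "days",
                 pressures = "mmHg"),
    settings = unclass_settings(settings)
  ), class = "prediction_report")
}

unclass_settings <- function(s) {
  s <- unclass(s)
  rapply(s, function(x) x, how = "replace")
}

#' @export
print.prediction_report <- function(x, ...) {
  nd <- length(x$maturation$days)
  cat(sprintf("AVF prediction report (%s)\n", x$configuration$label))
  cat(sprintf("  pre-op brachial BFV %.0f mL/min -> day 0 %.0f -> day %g %.0f\n",
              x$preop$bfv_mlmin$brachial, x$maturation$bfv_mlmin$brachial[1],
              x$maturation$days[nd], x$day40_brachial_bfv_mlmin))
  cat(sprintf("  cephalic diameter day %g: %.2f mm; WSS homeostasis: %s\n",
              x$maturation$days[nd],
              x$maturation$diameters_mm$cephalic[nd],
              x$diagnostics$wss_converged))
  invisible(x)
}

#' Write a prediction report to JSON
#'
#' Machine-readable, schema-versioned JSON with explicit units; lossless
#' round trip through [read_report()]. No timestamps: identical predictions
#' produce byte-identical files.
#'
#' @param report `prediction_report`.
#' @param path output `.json` path.
#' @return `path` invisibly.
#' @export
write_report <- function(report, path) {
  if (report$day40_brachial_bfv_mlmin !=
        report$maturation$bfv_mlmin$brachial[length(report$maturation$days)])
    stop("report invariant violated: headline BFV must equal the final-day ",
         "brachial entry")
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a prediction report written by [write_report()]
#' @param path `.json` path.
#' @return `prediction_report`.
#' @export
read_report <- function(path) {
  r <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                          simplifyMatrix = FALSE)
  structure(r, class = "prediction_report")
}
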