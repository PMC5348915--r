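#' Patient record
#'
#' Demographic and clinical covariates that drive personalization of the
#' generic vascular network: body size sets vessel lengths and diameters and
#' the cardiac output (through body surface area and cardiac index), age and
#' the hypertension/diabetes flags stiffen the wall, and hematocrit and
#' plasma protein set blood viscosity.
#'
#' @param age years.
#' @param sex `"female"` or `"male"`.
#' @param height cm.
#' @param weight kg.
#' @param systolic_pressure,diastolic_pressure mmHg.
#' @param hematocrit percent (0-70 exclusive).
#' @param plasma_protein g/dL.
#' @param hypertension,diabetes logical flags.
#' @param heart_rate beats/min; `NULL` uses the settings default.
#' @param avf_arm `"left"` or `"right"` (the model arm is mirror-symmetric;
#'   the arm choice records which arm carries measurements and surgery).
#' @return validated list of class `patient_record`.
#' @examples
#' patient_record(age = 60, sex = "male", height = 170, weight = 75,
#'                systolic_pressure = 135, diastolic_pressure = 80,
#'                hematocrit = 33, plasma_protein = 6.5,
#'                hypertension = TRUE, diabetes = FALSE)
#' @export
patient_record <- function(age, sex, height, weight,
                           systolic_pressure, diastolic_pressure,
                           hematocrit, plasma_protein,
                           hypertension = FALSE, diabetes = FALSE,
                           heart_rate = NULL, avf_arm = "left") {
  p <- list(age = as.numeric(age), sex = as.character(sex),
            height = as.numeric(height), weight = as.numeric(weight),
            systolic_pressure = as.numeric(systolic_pressure),
            diastolic_pressure = as.numeric(diastolic_pressure),
            hematocrit = as.numeric(hematocrit),
            plasma_protein = as.numeric(plasma_protein),
            hypertension = isTRUE(as.logical(hypertension)),
            diabetes = isTRUE(as.logical(diabetes)),
            heart_rate = if (is.null(heart_rate)) NULL else as.numeric(heart_rate),
            avf_arm = as.character(avf_arm))
  class(p) <- "patient_record"
  validate_patient(p)
  p
}

#' Validate a patient record, reporting every violated invariant at once
#'
#' @param p `patient_record`.
#' @return `p` invisibly; stops with a message listing all offending fields.
#' @export
validate_patient <- function(p) {
  errs <- character(0)
  bad <- function(cond, msg) if (isTRUE(cond)) errs <<- c(errs, msg)
  num_ok <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

  for (f in c("age", "height", "weight", "systolic_pressure",
              "diastolic_pressure", "hematocrit", "plasma_protein")) {
    if (!num_ok(p[[f]])) errs <- c(errs, paste0(f, ": missing or non-numeric"))
  }
  if (num_ok(p$age)) bad(p$age <= 0, "age: must be > 0")
  bad(!p$sex %in% c("female", "male"), "sex: must be 'female' or 'male'")
  if (num_ok(p$height)) bad(p$height < 100 || p$height > 230,
                            "height: must be in [100, 230] cm")
  if (num_ok(p$weight)) bad(p$weight < 25 || p$weight > 250,
                            "weight: must be in [25, 250] kg")
  if (num_ok(p$hematocrit)) bad(p$hematocrit <= 0 || p$hematocrit >= 70,
                                "hematocrit: must be in (0, 70) percent")
  if (num_ok(p$systolic_pressure) && num_ok(p$diastolic_pressure)) {
    bad(!(p$systolic_pressure > p$diastolic_pressure &&
            p$diastolic_pressure > 0),
        "pressures: require systolic > diastolic > 0 mmHg")
  }
  if (num_ok(p$plasma_protein)) bad(p$plasma_protein <= 0,
                                    "plasma_protein: must be > 0 g/dL")
  if (!is.null(p$heart_rate)) bad(!num_ok(p$heart_rate) || p$heart_rate <= 0,
                                  "heart_rate: must be > 0 bpm")
  bad(!p$avf_arm %in% c("left", "right"), "avf_arm: must be 'left' or 'right'")

  if (length(errs) > 0)
    stop("invalid patient record:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(p)
}

#' Mean arterial pressure of a patient (mmHg)
#'
#' Conventional estimate DBP + (SBP - DBP)/3, used to set terminal bed
#' operating points in diagnostics.
#' @param p `patient_record`.
#' @return mmHg.
#' @export
mean_arterial_pressure <- function(p) {
  p$diastolic_pressure + (p$systolic_pressure - p$diastolic_pressure) / 3
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("patient: %s, %g y, %g cm, %g kg, BP %g/%g mmHg\n",
              x$sex, x$age, x$height, x$weight,
              x$systolic_pressure, x$diastolic_pressure))
  cat(sprintf("  Hct %g%%, protein %g g/dL, HTN %s, DM %s, AVF arm %s\n",
              x$hematocrit, x$plasma_protein, x$hypertension, x$diabetes,
              x$avf_arm))
  invisible(x)
}

# canonical DUS site names (= segment names in the generic network)
DUS_ARTERIAL_SITES <- c("brachial-artery-mid", "brachial-artery-elbow",
                        "radial-artery-mid", "radial-artery-distal",
                        "ulnar-artery-mid", "ulnar-artery-distal",
                        "subclavian-artery")
DUS_VENOUS_SITES <- c("cephalic-vein-wrist", "cephalic-vein-forearm",
                      "cephalic-vein-upper", "cephalic-arch",
                      "cubital-vein", "basilic-vein", "subclavian-vein")
DUS_TAV_SITES <- c("brachial", "radial", "ulnar")

#' Doppler-ultrasound measurement set
#'
#' Pre-operative B-mode diameters at the protocol's arterial and venous
#' stations and time-averaged velocities (TAV) on the brachial, radial and
#' ulnar arteries. Any subset may be supplied; missing sites keep the scaled
#' generic values.
#'
#' @param arterial_diameters named numeric vector/list, mm; names from
#'   `dus_sites()$arterial`.
#' @param venous_diameters named numeric vector/list, mm; names from
#'   `dus_sites()$venous`.
#' @param tav named numeric vector/list, cm/s; names from `dus_sites()$tav`.
#' @return list of class `dus_measurements`.
#' @examples
#' dus_measurements(arterial_diameters = c(`radial-artery-distal` = 2.4))
#' @export
dus_measurements <- function(arterial_diameters = NULL,
                             venous_diameters = NULL,
                             tav = NULL) {
  as_named_num <- function(x) {
    if (is.null(x) || length(x) == 0) return(numeric(0))
    v <- unlist(x)
    storage.mode(v) <- "double"
    v
  }
  d <- list(arterial_diameters = as_named_num(arterial_diameters),
            venous_diameters = as_named_num(venous_diameters),
            tav = as_named_num(tav))
  class(d) <- "dus_measurements"
  validate_dus(d)
  d
}

#' Valid DUS site names
#' @return list with `arterial`, `venous` and `tav` character vectors.
#' @export
dus_sites <- function() {
  list(arterial = DUS_ARTERIAL_SITES, venous = DUS_VENOUS_SITES,
       tav = DUS_TAV_SITES)
}

validate_dus <- function(d) {
  errs <- character(0)
  chk <- function(x, valid, label, positive) {
    if (length(x) == 0) return()
    unknown <- setdiff(names(x), valid)
    if (length(unknown) > 0)
      errs <<- c(errs, paste0(label, ": unknown site(s) ",
                              paste(unknown, collapse = ", "),
                              "; valid sites: ", paste(valid, collapse = ", ")))
    if (positive && any(!is.finite(x) | x <= 0))
      errs <<- c(errs, paste0(label, ": values must be positive and finite"))
    if (!positive && any(!is.finite(x) | x < 0))
      errs <<- c(errs, paste0(label, ": values must be >= 0 and finite"))
  }
  chk(d$arterial_diameters, DUS_ARTERIAL_SITES, "arterial_diameters", TRUE)
  chk(d$venous_diameters, DUS_VENOUS_SITES, "venous_diameters", TRUE)
  chk(d$tav, DUS_TAV_SITES, "tav", FALSE)
  if (length(errs) > 0)
    stop("invalid DUS measurements:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(d)
}

AVF_LOCATIONS <- c("radio-cephalic", "brachio-cephalic")
AVF_KINDS <- c("end-to-side", "end-to-end", "side-to-side")

#' AVF surgical configuration
#'
#' @param location `"radio-cephalic"` (lower arm, radial artery to cephalic
#'   vein at the wrist) or `"brachio-cephalic"` (upper arm, brachial artery
#'   to cephalic vein at the elbow).
#' @param kind anastomosis type: `"end-to-side"` (artery side to vein end;
#'   the clinical "side-to-end"), `"end-to-end"` or `"side-to-side"`.
#' @return list of class `avf_configuration`.
#' @export
avf_configuration <- function(location, kind) {
  location <- match.arg(location, AVF_LOCATIONS)
  kind <- match.arg(kind, AVF_KINDS)
  structure(list(location = location, kind = kind),
            class = "avf_configuration")
}

#' All location x kind AVF configurations
#' @return list of six `avf_configuration` objects.
#' @export
avf_configuration_grid <- function() {
  out <- list()
  for (loc in AVF_LOCATIONS) for (k in AVF_KINDS)
    out[[paste(loc, k, sep = "/")]] <- avf_configuration(loc, k)
  out
}

#' Short labels ("rc-se", "bc-ss", ...) for AVF configurations
#' @param config `avf_configuration`.
#' @return character scalar.
#' @export
avf_label <- function(config) {
  loc <- c(`radio-cephalic` = "rc", `brachio-cephalic` = "bc")[config$location]
  kind <- c(`end-to-side` = "se", `end-to-end` = "ee",
            `side-to-side` = "ss")[config$kind]
  unname(paste(loc, kind, sep = "-"))
}

#' Parse a short AVF label into a configuration
#' @param label e.g. `"rc-se"`, `"bc-ss"`.
#' @return `avf_configuration`.
#' @export
parse_avf_label <- function(label) {
  parts <- strsplit(tolower(label), "-")[[1]]
  if (length(parts) != 2) stop("unrecognized AVF label: ", label)
  loc <- switch(parts[1], rc = "radio-cephalic", bc = "brachio-cephalic",
                stop("unrecognized AVF location in label: ", label))
  kind <- switch(parts[2], se = "end-to-side", ee = "end-to-end",
                 ss = "side-to-side",
                 stop("unrecognized anastomosis kind in label: ", label))
  avf_configuration(loc, kind)
}
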