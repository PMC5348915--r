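#' Read cohort group specifications
#'
#' The packaged file carries, for each of the five AVF-configuration groups
#' of the usability cohort, the group size, the mean and SD of each
#' continuous covariate and the frequency of each flag. A custom CSV with
#' the same columns may be supplied.
#'
#' @param path CSV path; defaults to the packaged group table.
#' @return named list of `group_spec` objects.
#' @export
read_group_specs <- function(path = default_group_spec_file()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  specs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    structure(list(
      label = r$label, location = r$location, kind = r$kind, n = r$n,
      mean = list(age = r$age_mean, height = r$height_mean,
                  weight = r$weight_mean, sbp = r$sbp_mean, dbp = r$dbp_mean,
                  hematocrit = r$hct_mean, protein = r$protein_mean),
      sd = list(age = r$age_sd, height = r$height_sd, weight = r$weight_sd,
                sbp = r$sbp_sd, dbp = r$dbp_sd, hematocrit = r$hct_sd,
                protein = r$protein_sd),
      freq = list(female = r$female_freq, right_arm = r$right_arm_freq,
                  hypertension = r$hypertension_freq,
                  diabetes = r$diabetes_freq)
    ), class = "group_spec")
  })
  names(specs) <- df$label
  for (s in specs) validate_group_spec(s)
  specs
}

#' Path to the packaged group-specification table
#' @return file path.
#' @export
default_group_spec_file <- function() {
  system.file("extdata", "cohort_groups.csv", package = "avfsim",
              mustWork = TRUE)
}

validate_group_spec <- function(spec) {
  errs <- character(0)
  if (spec$n < 0) errs <- c(errs, "n must be >= 0")
  if (any(unlist(spec$sd) < 0)) errs <- c(errs, "SDs must be >= 0")
  fr <- unlist(spec$freq)
  if (any(fr < 0 | fr > 1)) errs <- c(errs, "frequencies must be in [0, 1]")
  if (length(errs) > 0)
    stop("invalid group spec '", spec$label, "': ",
         paste(errs, collapse = "; "), call. = FALSE)
  invisible(spec)
}

# truncated-normal draws by rejection (bounds are the type invariants, far
# in the tails for every covariate in the group table)
rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lo & draw < hi
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

# synthetic DUS diameter sampling ranges (mm, diameter) for a reference-size
# adult; physiologic plausibility constants, scaled by sqrt(BSA/BSA_ref).
# the group table carries no diameters, so these are package-level stand-ins.
SYNTH_DIAMETER_RANGES <- list(
  arterial = list(
    `brachial-artery-mid` = c(3.8, 5.2),
    `brachial-artery-elbow` = c(3.6, 5.0),
    `radial-artery-mid` = c(2.0, 3.2),
    `radial-artery-distal` = c(1.8, 3.0),
    `ulnar-artery-mid` = c(2.0, 3.2),
    `ulnar-artery-distal` = c(1.8, 3.0),
    `subclavian-artery` = c(6.0, 9.0)),
  venous = list(
    `cephalic-vein-wrist` = c(1.8, 3.0),
    `cephalic-vein-forearm` = c(2.0, 3.5),
    `cephalic-vein-upper` = c(2.2, 3.8),
    `cephalic-arch` = c(2.5, 4.0),
    `cubital-vein` = c(2.5, 5.0),
    `basilic-vein` = c(2.5, 5.0),
    `subclavian-vein` = c(7.0, 11.0)),
  tav = list(brachial = c(8, 20), radial = c(4, 12), ulnar = c(4, 12)))

#' Generate a synthetic patient cohort from a group specification
#'
#' Continuous covariates are drawn from truncated normal distributions at
#' the group's mean/SD (truncated at the patient-record invariant bounds);
#' flags are Bernoulli at the group frequencies; systolic/diastolic pairs
#' are redrawn jointly until systolic > diastolic > 0. Synthetic DUS
#' diameters are drawn uniformly from documented physiologic ranges and
#' scaled with body size (`sqrt(BSA/BSA_ref)`); TAVs are drawn from
#' physiologic velocity ranges. Fully reproducible given the seed.
#'
#' @param spec `group_spec`.
#' @param seed integer seed (required).
#' @param n cohort size; defaults to the group's `n`.
#' @param settings `avf_settings` (reference body size).
#' @return list of entries, each `list(patient, dus, config)`.
#' @export
generate_cohort <- function(spec, seed, n = spec$n,
                            settings = avf_settings()) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  validate_group_spec(spec)
  set.seed(seed)
  if (n == 0) return(list())
  config <- avf_configuration(spec$location, spec$kind)
  bsa_ref <- body_surface_area(settings$reference$height_cm,
                               settings$reference$weight_kg)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    age <- rtrunc_norm(1, spec$mean$age, spec$sd$age, 0, Inf)
    height <- rtrunc_norm(1, spec$mean$height, spec$sd$height, 100, 230)
    weight <- rtrunc_norm(1, spec$mean$weight, spec$sd$weight, 25, 250)
    repeat {
      sbp <- rtrunc_norm(1, spec$mean$sbp, spec$sd$sbp, 0, Inf)
      dbp <- rtrunc_norm(1, spec$mean$dbp, spec$sd$dbp, 0, Inf)
      if (sbp > dbp) break
    }
    hct <- rtrunc_norm(1, spec$mean$hematocrit, spec$sd$hematocrit, 0, 70)
    prot <- rtrunc_norm(1, spec$mean$protein, spec$sd$protein, 0, Inf)
    patient <- patient_record(
      age = age, sex = if (stats::runif(1) < spec$freq$female) "female"
                       else "male",
      height = height, weight = weight,
      systolic_pressure = sbp, diastolic_pressure = dbp,
      hematocrit = hct, plasma_protein = prot,
      hypertension = stats::runif(1) < spec$freq$hypertension,
      diabetes = stats::runif(1) < spec$freq$diabetes,
      avf_arm = if (stats::runif(1) < spec$freq$right_arm) "right" else "left")
    size_f <- sqrt(body_surface_area(height, weight) / bsa_ref)
    draw_ranges <- function(ranges, scale = 1) {
      v <- vapply(ranges, function(rg) stats::runif(1, rg[1], rg[2]), 1)
      v * scale
    }
    dus <- dus_measurements(
      arterial_diameters = draw_ranges(SYNTH_DIAMETER_RANGES$arterial, size_f),
      venous_diameters = draw_ranges(SYNTH_DIAMETER_RANGES$venous, size_f),
      tav = draw_ranges(SYNTH_DIAMETER_RANGES$tav))
    out[[i]] <- list(patient = patient, dus = dus, config = config)
  }
  out
}

#' A 40-day follow-up DUS record
#'
#' @param brachial_bfv,radial_bfv,ulnar_bfv measured BFV, mL/min (`NULL`
#'   when not acquired).
#' @param distal whether the record belongs to a distal (radio-cephalic)
#'   AVF, for which radial and ulnar BFV are required.
#' @param diameters optional named vector of follow-up diameters, mm.
#' @return list of class `follow_up_record`.
#' @export
follow_up_record <- function(brachial_bfv, radial_bfv = NULL,
                             ulnar_bfv = NULL, distal = TRUE,
                             diameters = NULL) {
  structure(list(brachial_bfv = brachial_bfv, radial_bfv = radial_bfv,
                 ulnar_bfv = ulnar_bfv, distal = isTRUE(distal),
                 diameters = diameters),
            class = "follow_up_record")
}

#' Quality-control filter for follow-up records
#'
#' A record fails as `"incomplete"` when required measurements are missing
#' (brachial always; radial and ulnar for distal-AVF records) and as
#' `"inconsistent"` when the brachial BFV is lower than the sum of radial
#' and ulnar BFV — physically impossible upstream of the bifurcation and a
#' signature of disturbed-flow measurement error. A pure predicate:
#' filtering commutes with cohort concatenation.
#'
#' @param record `follow_up_record`.
#' @return list with `pass` (logical) and `reason`
#'   (`NA`, `"incomplete"` or `"inconsistent"`).
#' @export
qc_follow_up <- function(record) {
  present <- function(x) !is.null(x) && length(x) == 1 && is.finite(x)
  required <- c(list(record$brachial_bfv),
                if (record$distal) list(record$radial_bfv, record$ulnar_bfv))
  if (!all(vapply(required, present, TRUE)))
    return(list(pass = FALSE, reason = "incomplete"))
  if (record$distal &&
        record$brachial_bfv < record$radial_bfv + record$ulnar_bfv)
    return(list(pass = FALSE, reason = "inconsistent"))
  list(pass = TRUE, reason = NA_character_)
}

#' Linear regression agreement between predicted and measured series
#'
#' Ordinary least squares of predicted on measured, with the Pearson
#' correlation and the two-sided p-value of the slope test.
#'
#' @param predicted,measured numeric series, mL/min, equal length >= 3.
#' @return list: `n`, `r`, `slope`, `intercept`, `p_value`.
#' @export
regression_stats <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length")
  if (length(predicted) < 3) stop("at least 3 pairs are required")
  if (stats::var(measured) == 0)
    stop("measured series has zero variance; regression is undefined")
  fit <- stats::lm(predicted ~ measured)
  # a perfect fit (noise-free validation) triggers lm's reliability notice;
  # the coefficients themselves are exact
  coefs <- withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  list(n = length(predicted),
       r = stats::cor(predicted, measured),
       slope = unname(coefs["measured", "Estimate"]),
       intercept = unname(coefs["(Intercept)", "Estimate"]),
       p_value = unname(coefs["measured", "Pr(>|t|)"]))
}

#' Bland-Altman agreement between predicted and measured series
#'
#' Per pair, the percent difference `100 (predicted - measured) / measured`
#' and the percent ratio `100 predicted / measured` are computed (the two
#' conventions used in method-agreement reporting; both are returned under
#' explicit names). Returns the mean and sample SD of the percent
#' difference, the limits of agreement (mean +/- 1.96 SD), and quartiles
#' (linear-interpolation convention, quantile type 7), min and max of the
#' percent ratio, with the pairwise averages for plotting.
#'
#' @param predicted,measured numeric series, equal length >= 2;
#'   `measured > 0` elementwise.
#' @return list of class `bland_altman`.
#' @export
bland_altman_stats <- function(predicted, measured) {
  if (length(predicted) != length(measured))
    stop("predicted and measured must have equal length")
  if (length(predicted) < 2) stop("at least 2 pairs are required")
  if (any(measured <= 0))
    stop("measured values must all be positive for percent agreement")
  pct_diff <- 100 * (predicted - measured) / measured
  pct_ratio <- 100 * predicted / measured
  m <- mean(pct_diff)
  s <- stats::sd(pct_diff)
  q <- stats::quantile(pct_ratio, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(
    n = length(predicted),
    mean_percent_difference = m,
    sd_percent_difference = s,
    limits_of_agreement = c(lower = m - 1.96 * s, upper = m + 1.96 * s),
    ratio_quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
    ratio_min = min(pct_ratio),
    ratio_max = max(pct_ratio),
    percent_difference = pct_diff,
    percent_ratio = pct_ratio,
    pair_average = (predicted + measured) / 2
  ), class = "bland_altman")
}

#' In-silico validation of the prediction pipeline
#'
#' Mirrors the clinical validation workflow on synthetic data: generate a
#' cohort per group, run the full prediction per patient, perturb the
#' predicted flows with multiplicative lognormal measurement noise to form
#' pseudo-"measured" 40-day values, apply the follow-up QC filter, and
#' compute the agreement statistics (regression over all retained records;
#' Bland-Altman over retained distal-AVF records, as in the clinical
#' analysis). With `noise_sigma = 0` the pseudo-measurements equal the
#' predictions and the statistics are exact (R = 1, 0% mean difference).
#'
#' @param specs list of `group_spec` (e.g. from [read_group_specs()]).
#' @param seed integer seed for cohort generation and noise.
#' @param settings `avf_settings`; cohort-scale runs typically reduce the
#'   solver resolution (see the package vignette).
#' @param noise_sigma lognormal sigma of the synthetic measurement noise.
#' @param n_per_group optional override of each group's size.
#' @param network optional pre-built generic network (rebuilt once and
#'   shared across patients otherwise).
#' @return `validation_stats`: `n`, `regression`, `bland_altman`, `qc`
#'   (exclusion bookkeeping), and the per-patient table.
#' @export
in_silico_validation <- function(specs, seed, settings = avf_settings(),
                                 noise_sigma = 0.2, n_per_group = NULL,
                                 network = NULL) {
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (is.null(network)) network <- build_generic_network()
  rows <- list()
  for (g in seq_along(specs)) {
    spec <- specs[[g]]
    n_g <- if (is.null(n_per_group)) spec$n else n_per_group
    cohort <- generate_cohort(spec, seed = seed + g, n = n_g,
                              settings = settings)
    for (entry in cohort) {
      rep <- predict_avf(entry$patient, entry$dus, entry$config, settings,
                         network = network)
      nd <- length(rep$maturation$days)
      rows[[length(rows) + 1]] <- list(
        group = spec$label,
        distal = spec$location == "radio-cephalic",
        pred_brachial = rep$maturation$bfv_mlmin$brachial[nd],
        pred_radial = if (spec$location == "radio-cephalic")
          rep$maturation$bfv_mlmin$radial[nd] else NA_real_)
    }
  }
  # synthetic measurement noise, seeded separately from cohort generation.
  # Errors within one DUS exam are correlated: a shared per-patient factor
  # (operator, insonation conditions) carries most of the variance, with a
  # smaller independent per-vessel term; total lognormal sigma is
  # noise_sigma. True ulnar flow is what remains of the brachial flow after
  # the radial and the side-branch beds (~10%) are taken out.
  set.seed(seed + 10000L)
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(group = r$group, distal = r$distal,
               pred_brachial = r$pred_brachial, pred_radial = r$pred_radial)))
  nr <- nrow(tab)
  e_shared <- stats::rnorm(nr, 0, noise_sigma * sqrt(0.9))
  vessel <- function() exp(e_shared + stats::rnorm(nr, 0,
                                                   noise_sigma * sqrt(0.1)))
  true_ulnar <- pmax(0.9 * tab$pred_brachial - tab$pred_radial,
                     0.01 * tab$pred_brachial)
  tab$meas_brachial <- tab$pred_brachial * vessel()
  tab$meas_radial <- ifelse(tab$distal, tab$pred_radial * vessel(), NA)
  tab$meas_ulnar <- ifelse(tab$distal, true_ulnar * vessel(), NA)
  qc <- lapply(seq_len(nr), function(i) {
    qc_follow_up(follow_up_record(
      brachial_bfv = tab$meas_brachial[i],
      radial_bfv = if (tab$distal[i]) tab$meas_radial[i],
      ulnar_bfv = if (tab$distal[i]) tab$meas_ulnar[i],
      distal = tab$distal[i]))
  })
  tab$qc_pass <- vapply(qc, `[[`, TRUE, "pass")
  tab$qc_reason <- vapply(qc, `[[`, NA_character_, "reason")
  keep <- tab[tab$qc_pass, , drop = FALSE]
  if (nrow(keep) < 3)
    stop("fewer than 3 records survive QC; enlarge the cohort")
  reg <- regression_stats(keep$pred_brachial, keep$meas_brachial)
  dist <- keep[keep$distal, , drop = FALSE]
  ba <- if (nrow(dist) >= 2)
    bland_altman_stats(dist$pred_brachial, dist$meas_brachial) else NULL
  structure(list(
    n = nrow(keep),
    regression = reg,
    bland_altman = ba,
    qc = list(n_total = nr, n_excluded = sum(!tab$qc_pass),
              reasons = table(tab$qc_reason[!tab$qc_pass])),
    table = tab,
    noise_sigma = noise_sigma
  ), class = "validation_stats")
}

#' @export
print.validation_stats <- function(x, ...) {
  cat(sprintf("in-silico validation: n = %d (of %d; %d excluded by QC)\n",
              x$n, x$qc$n_total, x$qc$n_excluded))
  cat(sprintf("  regression: R = %.3f, slope = %.3f, intercept = %.1f\n",
              x$regression$r, x$regression$slope, x$regression$intercept))
  if (!is.null(x$bland_altman))
    cat(sprintf(
      "  Bland-Altman (distal): %.2f +/- %.2f%%, ratio quartiles %.0f/%.0f/%.0f%%\n",
      x$bland_altman$mean_percent_difference,
      x$bland_altman$sd_percent_difference,
      x$bland_altman$ratio_quartiles["q1"],
      x$bland_altman$ratio_quartiles["median"],
      x$bland_altman$ratio_quartiles["q3"]))
  invisible(x)
}
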