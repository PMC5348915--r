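#' Default model, solver and adaptation settings
#'
#' Returns the complete, documented set of tunable constants used by the
#' pipeline: the reference adult that the generic network describes, blood
#' property constants, cardiac boundary conditions, numerical solver controls,
#' the venous pressure-area law, per-configuration anastomosis geometry and
#' the wall-shear-stress adaptation rule. Every run embeds the resolved
#' settings in its report so results are reproducible from the report alone.
#'
#' Units are stated per field; clinical units are used here and converted
#' internally.
#'
#' @param overrides optional named list (possibly nested) merged over the
#'   defaults, e.g. `list(solver = list(steps_per_cycle = 256))`.
#' @return nested list of settings with class `avf_settings`.
#' @examples
#' s <- avf_settings(list(adaptation = list(rate_constant = 0.1)))
#' s$adaptation$rate_constant
#' @export
avf_settings <- function(overrides = NULL) {
  s <- list(
    # the reference adult the generic network file describes; scaling factors
    # are defined relative to this subject so scaling it is the identity
    reference = list(
      height_cm = 176,
      weight_kg = 75,
      age_years = 50,
      sex = "male",
      systolic_mmHg = 130,         # reference BP: terminal resistances are
      diastolic_mmHg = 75,         # rescaled to reproduce the patient's MAP
      heart_rate = 70,             # bpm, used when the form omits heart rate
      female_diameter_factor = 0.92, # female reference lumen diameters -8%
      age_stiffness_per_year = 0.01, # +1% effective modulus per year above 50
      hypertension_stiffness = 1.3,
      diabetes_stiffness = 1.2
    ),
    blood = list(
      density = 1050,              # kg/m^3
      # viscosity model: mu = mu_plasma(protein) * exp(k_h * Hct_fraction)
      # mu_plasma in mPa*s, linear in plasma protein around 7 g/dL
      plasma_viscosity_7 = 1.10,   # mPa*s at 7 g/dL
      plasma_viscosity_slope = 0.08, # mPa*s per g/dL
      hematocrit_exponent = 2.31
    ),
    cardiac = list(
      cardiac_index = 3.0,         # L/min/m^2
      ejection_fraction = 0.35,    # fraction of the period with inflow
      waveform = "pulse"           # "pulse" (half-sine systolic) or "constant"
    ),
    solver = list(
      steps_per_cycle = 512,
      tolerance = 1e-4,            # cycle-to-cycle relative L2 residual
      max_cycles = 50,
      min_cycles = 3,
      compartment_length_cm = 2    # max lumped-compartment length
    ),
    venous = list(
      # pressure-area law A(P) = A_ref * (1 + kappa * Pw * atan(P / Pw)),
      # plus the thin-wall elastic term as a high-pressure floor;
      # compliance = length * dA/dP
      width_mmHg = 10,             # Pw: transition width of the atan law
      distensibility_per_mmHg = 0.03 # kappa * Pw expressed per mmHg at P = 0
    ),
    anastomosis = list(
      # effective orifice geometry and expansion-loss coefficient per
      # (location, kind); linear coefficient a = 8 mu_ref l / (pi r^4),
      # quadratic b = K rho / (2 A^2) (Borda-Carnot style loss)
      mu_ref = 3.5,                # mPa*s, reference viscosity for a
      length_mm = 7,
      radius_mm = list(
        `radio-cephalic` = list(`end-to-side` = 1.5, `end-to-end` = 1.4,
                                `side-to-side` = 1.7),
        `brachio-cephalic` = list(`end-to-side` = 1.7, `end-to-end` = 1.6,
                                  `side-to-side` = 1.8)
      ),
      loss_k = list(`end-to-side` = 2.0, `end-to-end` = 1.2,
                    `side-to-side` = 2.5),
      # the effective orifice scales with the calibers of the joined
      # vessels, sqrt((r_artery/ref_a) * (r_vein/ref_v)); the references
      # are the generic network's site radii
      site_reference_mm = list(
        `radio-cephalic` = list(artery = 1.25, vein = 1.25),
        `brachio-cephalic` = list(artery = 2.1, vein = 1.7))
    ),
    adaptation = list(
      wss_target_mode = "baseline-per-segment", # or "global-constant"
      tau_target = 5,              # Pa, used in global-constant mode
      rate_constant = 0.15,        # 1/day
      day_step = 1,                # days, explicit Euler step on the day grid
      days = 40,
      convergence_tol = 0.10,      # relative |tau/tau_target - 1| at day 40
      artery_floor_pa = 2.0,       # minimum WSS target, arteries
      vein_floor_pa = 5.0,         # minimum WSS target, veins
      min_radius_mm = 0.3
    )
  )
  if (!is.null(overrides)) s <- modify_settings(s, overrides)
  class(s) <- "avf_settings"
  s
}

modify_settings <- function(base, overrides) {
  stopifnot(is.list(overrides))
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_settings(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  base
}

#' Read settings overrides from a YAML config file
#'
#' The file may contain any subset of the blocks returned by
#' [avf_settings()]; values present override the defaults.
#'
#' @param path YAML file.
#' @return `avf_settings` list.
#' @export
read_settings_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  avf_settings(yaml::read_yaml(path))
}

#' Adaptation day grid implied by the settings
#' @param settings `avf_settings` list.
#' @return numeric vector of days, 0 ... `days`, strictly increasing.
#' @export
day_grid <- function(settings) {
  a <- settings$adaptation
  g <- seq(0, a$days, by = a$day_step)
  if (g[length(g)] != a$days) g <- c(g, a$days)
  g
}

#' @export
print.avf_settings <- function(x, ...) {
  cat("avfsim settings\n")
  cat("  solver: ", x$solver$steps_per_cycle, " steps/cycle, tol ",
      format(x$solver$tolerance), ", max ", x$solver$max_cycles, " cycles\n",
      sep = "")
  cat("  adaptation: k = ", x$adaptation$rate_constant, "/day, ",
      x$adaptation$days, " days, mode ", x$adaptation$wss_target_mode, "\n",
      sep = "")
  cat("  cardiac index: ", x$cardiac$cardiac_index, " L/min/m^2\n", sep = "")
  invisible(x)
}
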