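#' Body surface area (DuBois)
#'
#' BSA = 0.007184 * height^0.725 * weight^0.425, the DuBois-DuBois formula;
#' used with the cardiac index to set cardiac output and, through its square
#' root, to scale lumen diameters to body size.
#'
#' @param height cm.
#' @param weight kg.
#' @return m^2.
#' @examples
#' body_surface_area(170, 70) # ~1.81 m^2
#' @export
body_surface_area <- function(height, weight) {
  stopifnot(is.numeric(height), is.numeric(weight),
            all(height > 0), all(weight > 0))
  0.007184 * height^0.725 * weight^0.425
}

#' Blood rheological properties from hematocrit and plasma protein
#'
#' Empirical exponential-in-hematocrit viscosity law with a linear plasma
#' protein correction of the plasma viscosity:
#' \deqn{\mu = [\mu_{p,7} + s\,(c_p - 7)] \exp(k_h H)}
#' with hematocrit H as a fraction, constants from the `blood` settings
#' block. Density is constant (blood is treated as incompressible and
#' Newtonian throughout).
#'
#' @param hematocrit percent, in (0, 70).
#' @param plasma_protein g/dL.
#' @param settings `avf_settings` list (the `blood` block is used).
#' @return list of class `blood_properties` with `viscosity` (mPa*s) and
#'   `density` (kg/m^3).
#' @examples
#' blood_properties(33, 6.5)$viscosity # physiologic, ~2-3 mPa*s
#' @export
blood_properties <- function(hematocrit, plasma_protein,
                             settings = avf_settings()) {
  if (!is.numeric(hematocrit) || hematocrit <= 0 || hematocrit >= 70)
    stop("hematocrit must be in (0, 70) percent, got ", hematocrit)
  if (!is.numeric(plasma_protein) || plasma_protein <= 0)
    stop("plasma_protein must be positive (g/dL)")
  b <- settings$blood
  mu_plasma <- b$plasma_viscosity_7 +
    b$plasma_viscosity_slope * (plasma_protein - 7)
  if (mu_plasma <= 0) stop("plasma viscosity model gave a non-positive value")
  mu <- mu_plasma * exp(b$hematocrit_exponent * hematocrit / 100)
  structure(list(viscosity = mu, density = b$density),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("blood: viscosity %.3f mPa*s, density %g kg/m^3\n",
              x$viscosity, x$density))
  invisible(x)
}
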