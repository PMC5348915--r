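#' Unit conversion layer
#'
#' Clinical units (mm, cm, mmHg, mL/min, cm/s, mPa*s) appear at every user
#' interface; all hemodynamic computation is carried out in SI (m, Pa, m^3/s,
#' Pa*s). Every conversion in the package goes through these helpers so that
#' there is a single place where unit errors could live.
#'
#' @name units
#' @keywords internal
NULL

# 1 mmHg in Pa (conventional value)
MMHG_PA <- 133.322

# 1 mL/min in m^3/s
MLMIN_M3S <- 1e-6 / 60

mmHg_to_Pa <- function(p) p * MMHG_PA
Pa_to_mmHg <- function(p) p / MMHG_PA

mlmin_to_m3s <- function(q) q * MLMIN_M3S
m3s_to_mlmin <- function(q) q / MLMIN_M3S

mm_to_m <- function(x) x * 1e-3
m_to_mm <- function(x) x * 1e3

cm_to_m <- function(x) x * 1e-2
m_to_cm <- function(x) x * 1e2

# dynamic viscosity: clinical mPa*s -> Pa*s
mPas_to_Pas <- function(mu) mu * 1e-3
Pas_to_mPas <- function(mu) mu * 1e3

# terminal / lumped resistances: clinical mmHg*min/mL -> Pa*s/m^3
mmHgminml_to_SI <- function(r) r * MMHG_PA / MLMIN_M3S
SI_to_mmHgminml <- function(r) r * MLMIN_M3S / MMHG_PA
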