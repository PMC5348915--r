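---
title: "The avfsim maturation model: assumptions, parameters and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The avfsim maturation model: assumptions, parameters and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avfsim)
```

## The clinical problem

An arteriovenous fistula (AVF) — a surgical connection between an artery and
a vein of the arm — is the preferred vascular access for hemodialysis. Its
outcome hinges on the blood flow volume (BFV) reached after maturation, the
roughly 40-day period in which the feeding artery and draining vein dilate:
below ~300 mL/min the access cannot sustain dialysis; above ~1.5 L/min the
patient risks high-output cardiac strain and hand ischemia. `avfsim`
predicts, before surgery, the 0-40 day time course of BFV and vessel
diameters for each candidate anastomosis configuration (radio-cephalic or
brachio-cephalic; end-to-side, end-to-end or side-to-side), from routinely
collected data: demographics, a few clinical covariates, and Doppler
ultrasound (DUS) vessel diameters and velocities.

## The hemodynamic model

The arm circulation is a lumped-parameter (0D) network built on the
hydraulic-electric analogy (pressure ~ voltage, flow ~ current). Every
anatomical vessel is split into short compartments (<= 2 cm by default), a
chain of RLC cells that approximates 1-D transmission-line behavior without
a PDE discretization. For a compartment of radius $r$, length $\ell$, wall
thickness $h$ and effective elastic modulus $E$, with blood viscosity $\mu$
and density $\rho$, Poiseuille flow in a straight elastic tube gives

$$R' = \frac{8\mu}{\pi r^4}, \qquad L' = \frac{\rho}{\pi r^2}, \qquad
  C = \frac{3\pi r^3 \ell}{2 E h},$$

resistance and inertance per unit length and the whole-compartment storage
compliance. The governing equations are momentum per compartment,
$L'\ell\,\dot Q = \Delta P - R'\ell\,Q$, and mass per node,
$C\,\dot P = \sum Q_{in} - \sum Q_{out}$. Side branches and microvascular
beds are terminal elements: linear resistances draining to the
extravascular reference pressure, fixed at 0 mmHg. Blood is incompressible
and Newtonian; its viscosity comes from an empirical exponential-in-
hematocrit law with a linear plasma-protein correction of plasma viscosity
(constants in the `blood` settings block), and its density is constant at
1050 kg/m^3.

The network description ships as an editable YAML file
(`inst/extdata/arm_network.yaml`): an aortic inlet, the subclavian /
axillary / brachial / radial / ulnar arterial tree closed by the palmar
arch, the cephalic / cubital / basilic / subclavian venous tree, and lumped
terminals. One deliberately non-anatomical segment, `systemic-artery`,
carries the windkessel storage of the whole systemic arterial tree
(~1e-8 m^3/Pa): without it a handful of short, stiff segments cannot
reproduce a physiologic pulse pressure. Terminal resistances are set so the
reference adult perfuses the arm with ~100 mL/min (brachial) out of a
~5.7 L/min cardiac output at a mean arterial pressure of ~93 mmHg. All
numeric entries are documented physiologic stand-ins; the file is versioned
and the model simulates whatever file it is given.

### Venous compliance

Veins are highly distensible near zero transmural pressure and stiffen as
they round out. The package uses an arctangent pressure-area relation whose
derivative gives

$$C(P) = \ell\,A_{ref}\,\frac{\kappa}{1 + (P/P_w)^2} + C_{el},$$

with $\kappa$ the low-pressure distensibility (default 3%/mmHg), $P_w$ the
transition width (10 mmHg) and $C_{el}$ the thin-wall elastic compliance as
the artery-like high-pressure floor. The function is smooth, positive and
monotonically decreasing for $P \ge 0$.

### The anastomosis element

The surgical connection is a nonlinear element,
$\Delta P = aQ + bQ|Q|$: a Poiseuille term
$a = 8\mu_{ref}\ell_a/(\pi r_a^4)$ for the short anastomotic channel and a
Borda-Carnot-style expansion loss $b = K\rho/(2A^2)$ for the energy
dissipated in the disturbed flow at the junction. The loss coefficient $K$
depends on the geometry of the junction (end-to-end is the most
streamlined, side-to-side the least). The effective orifice radius is a
per-(location, kind) base value scaled by
$\sqrt{(r_{artery}/r_{a,ref})(r_{vein}/r_{v,ref})}$, the geometric mean of
the joined vessels' relative calibers: a surgeon sews a larger anastomosis
onto larger vessels, and this coupling is what propagates measured vessel
size into predicted flow. Base radii (1.4-1.8 mm radio-cephalic,
1.6-1.8 mm brachio-cephalic) reflect the deliberately limited orifices
used clinically to avoid high-output fistulae.

### Boundary conditions and patient specificity

Cardiac output is not measured pre-operatively; it is assumed from the
cardiac index (3.0 L/min/m^2) times the DuBois body surface area. A flow
inlet was chosen over a pressure inlet because cardiac output is the
quantity the assumption provides. The inflow waveform is a unit-mean
half-sine systolic pulse occupying 35% of the period, zero in diastole;
heart rate defaults to 70 bpm when the form omits it (it is not part of
the standard pre-operative data set).

The generic network describes a reference adult (male, 50 y, 176 cm, 75 kg,
BP 130/75). Personalization is deterministic: lengths scale with
height/176; lumen radii with $\sqrt{BSA/BSA_{ref}}$ (and x0.92 for female
patients, reflecting smaller reference calibers at equal BSA); wall
stiffness is multiplied by $1 + 0.01(\text{age}-50)$ above age 50, by 1.3
for hypertension and 1.2 for diabetes; terminal resistances are rescaled so
the circuit reproduces the patient's measured mean arterial pressure at the
patient's cardiac output. Measured DUS diameters then override the scaled
generic values at their named segments; unmeasured sites keep the scaled
defaults. Scaling the reference patient is the identity, a property the
test suite checks field by field.

## The adaptation algorithm

Endothelium senses wall shear stress (WSS); sustained deviation from its
homeostatic set point drives outward (high WSS) or inward (low WSS)
remodeling. The model regulates the Poiseuille peak WSS,
$\tau_{peak} = 4\mu Q_{peak}/(\pi r^3)$, per adapting segment (the arteries
feeding the anastomosis and the draining vein up to the subclavian
junction, flagged in the network file) with the multiplicative rate law

$$r \leftarrow r\left[1 + k\,\Delta t\left(\frac{\tau_{peak}}
  {\tau_{target}} - 1\right)\right],$$

the simplest law whose fixed point is the homeostatic set point. The
default rate $k = 0.15$/day completes ~90% of remodeling within the fixed
40-day horizon. Targets default to each segment's own pre-operative peak
WSS (`baseline-per-segment`), floored at 2 Pa for arteries and 5 Pa for
veins; a `global-constant` mode is available. The venous floor is
essential: terminal elements drain to the 0 mmHg reference, so the venous
tree carries almost no pre-operative flow, its baseline WSS is near zero,
and an unfloored target would dilate the vein without bound. The venous
floor of 5 Pa yields matured cephalic diameters around 5 mm, the clinically
expected caliber. Radii are floored at 0.3 mm.

Surgery itself is a topology edit. End-to-side ligates the peripheral
venous limb and keeps the artery patent. End-to-end transects the artery at
the proximal node of the configured site segment and diverts the proximal
stump into the vein; the distal arterial limb leaves the anastomosis path
and the hand is supplied through the palmar arch (for a radio-cephalic
fistula, by the ulnar artery). Side-to-side keeps all four limbs patent.
The day-0 entry of every time series is the immediate post-surgical,
pre-remodeling solution. Mean hand-bed perfusion is reported per day as a
steal-risk signal, but no threshold rule is applied.

## Numerics

The solver integrates the circuit with backward Euler at 512 steps per
cardiac cycle, marching cycle to cycle until the relative L2 difference of
the state between consecutive cycles falls below 1e-4 (at most 50 cycles).
Two structural choices make this fast and exactly analysable:

* **Venous compliance is frozen within each cycle** at the previous cycle's
  mean nodal pressures and updated between cycles — a fixed-point iteration
  folded into the periodicity loop. Each cycle is then a linear
  time-invariant system: one matrix factorization per cycle, one
  back-substitution per step. At convergence the compliances are consistent
  with the operating pressures.
* **The single nonlinear anastomosis resistance** is applied per step as a
  rank-1 Sherman-Morrison correction with three Picard iterations, so the
  factorized matrix is never touched.

The system matrix mixes momentum rows (~1e8 Pa s/m^3) with mass rows (~1),
and is equilibrated with characteristic flow (mean inlet) and pressure
(1e4 Pa) scales before inversion; without this the factorization is
numerically singular. Summing the discrete update over one periodic cycle
telescopes the storage terms away, so cycle-averaged flows satisfy the
steady circuit equations essentially independently of the step size — the
time-step convergence tests (halving the step changes day-40 BFV by well
under 0.5%) confirm the residual dependence through the nonlinear term is
negligible. Discrete nodal mass balance holds to rounding error
(~1e-14 of inlet flow) by construction of the implicit solve.

The maturation loop uses explicit Euler on a 1-day grid. Stability of the
remodeling recursion requires roughly $3k\,\Delta t < 2$ (the factor 3 from
$\tau \propto r^{-3}$ at fixed flow); the 1-day default is far inside, and
cohort-scale runs use 2-day steps, still comfortably stable. Each day's
periodic solve warm-starts from the previous day's state and typically
converges in 2-3 cycles. A full 41-day prediction at default resolution
takes a few seconds on one core; cohort-scale runs (validation, 60
patients) drop to 128 steps/cycle and 2-day remodeling steps, which changes
day-40 BFV by well under the agreement statistics' resolution.

Degenerate inputs behave sensibly: zero cardiac output yields the all-zero
equilibrium exactly; solver non-convergence raises a typed condition
carrying the residual history (exit code 3 in the CLI); non-finite states
name the offending segment.

## The synthetic cohort and in-silico validation

No patient-level dataset ships with the package. The cohort generator
draws, for each of the five configuration groups of the usability cohort,
continuous covariates from truncated normals at the group mean/SD
(truncation at the patient-record invariant bounds, far in the tails) and
flags from Bernoulli distributions at the group frequencies;
systolic/diastolic pairs are redrawn jointly until orthostatic ordering
holds. Synthetic DUS diameters are drawn uniformly from documented
physiologic ranges (e.g. radial 1.8-3.0 mm diameter) and scaled with
$\sqrt{BSA/BSA_{ref}}$; the group table carries no diameters, so these
ranges are package-level constants, not cohort statistics.

In-silico validation mirrors the clinical workflow: predict every patient,
perturb the predicted 40-day flows with multiplicative lognormal
measurement noise to form pseudo-"measured" values, apply the follow-up QC
filter, and compute the agreement statistics. The noise is correlated
within a patient's exam — a shared factor carries 90% of the variance and
a per-vessel factor the rest, total sigma 0.2 by default — because fully
independent per-vessel errors would trip the brachial-vs-radial+ulnar
consistency rule in a third of records, far above clinical exclusion
rates. The QC rule itself uses strict inequality (`brachial < radial +
ulnar` fails), with missing required measurements failing as incomplete.

Two reporting conventions coexist in method-agreement work: the percent
difference (predicted - measured)/measured and the percent ratio
predicted/measured. Both are computed under explicit names; quartiles of
the ratio use the linear-interpolation (type 7) convention, cross-checked
in the tests against a from-first-principles sort-based oracle. With zero
noise the validation is exact (R = 1, 0% mean difference) — a calibration
check of the harness, not a statement about predictive accuracy.

What passing these tests shows — and does not show: the synthetic cohort
reproduces the demographic and clinical moments of the published groups
and plausible DUS calibers, but real patients carry anatomical variants,
diseased vessel walls, and measurement conditions that no moment-matched
generator emulates. Agreement statistics on synthetic data validate the
statistical machinery and the pipeline's self-consistency, not clinical
accuracy.

## Known limitations

* Pre-operative venous flow is not modeled (terminals drain to the
  reference), so venous WSS targets come entirely from the configured
  floor.
* The 40-day horizon is fixed for all patients, though maturation is slower
  in, e.g., diabetic patients; the adaptation rate and law are package
  defaults, not fitted quantities.
* Radii remodel; wall thickness does not. Intimal hyperplasia, stenosis
  and collateral growth are out of scope.
* No anatomical variants (high radial bifurcation, accessory veins); the
  network is mirror-symmetric, with the arm choice recorded but not
  geometrically distinguished.
* Turbulence appears only as the anastomosis' quadratic loss; rheology is
  Newtonian; compartments are straight and untapered.

## Worked example

```{r example, eval = FALSE}
form <- read_patient_form(system.file("extdata", "example_patient.json",
                                      package = "avfsim"))
report <- predict_avf(form$patient, form$dus, form$config)
print(report)
write_report(report, "report.json")
```
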