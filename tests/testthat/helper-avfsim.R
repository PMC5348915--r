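# shared fixtures: all built in code at test time

default_test_patient <- function(...) {
  args <- list(age = 60, sex = "male", height = 170, weight = 75,
               systolic_pressure = 135, diastolic_pressure = 80,
               hematocrit = 33, plasma_protein = 6.5,
               hypertension = TRUE, diabetes = FALSE)
  do.call(patient_record, utils::modifyList(args, list(...)))
}

reference_patient <- function(settings = avf_settings()) {
  ref <- settings$reference
  patient_record(age = ref$age_years, sex = ref$sex,
                 height = ref$height_cm, weight = ref$weight_kg,
                 systolic_pressure = ref$systolic_mmHg,
                 diastolic_pressure = ref$diastolic_mmHg,
                 hematocrit = 33, plasma_protein = 6.5)
}

test_blood <- function() blood_properties(33, 6.5)

# reduced resolution for multi-run tests; default resolution stays the
# reference for the convergence checks. The 2-day adaptation step keeps the
# explicit Euler remodeling well inside its stability region (3 k dt < 1).
quick_settings <- function(overrides = NULL) {
  base <- list(solver = list(steps_per_cycle = 128, min_cycles = 2),
               adaptation = list(day_step = 2))
  if (!is.null(overrides)) base <- utils::modifyList(base, overrides)
  avf_settings(base)
}

# independent normal-equations oracle (no lm): beta = (X'X)^-1 X'y
ols_oracle <- function(y, x) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  resid <- y - X %*% beta
  n <- length(y)
  se_slope <- sqrt(sum(resid^2) / (n - 2) / sum((x - mean(x))^2))
  tval <- beta[2] / se_slope
  list(intercept = beta[1], slope = beta[2], r = r,
       p = 2 * stats::pt(-abs(tval), df = n - 2))
}

# sort-based quantile oracle implementing the linear-interpolation (type 7)
# convention from first principles
quantile7_oracle <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# memoized full-resolution maturation runs shared across the slower tests
.maturation_cache <- new.env(parent = emptyenv())
cached_maturation <- function(label, steps_per_cycle = 512, day_step = 1) {
  key <- paste(label, steps_per_cycle, day_step, sep = "/")
  if (is.null(.maturation_cache[[key]])) {
    s <- avf_settings(list(solver = list(steps_per_cycle = steps_per_cycle),
                           adaptation = list(day_step = day_step)))
    .maturation_cache[[key]] <- simulate_maturation(
      default_test_patient(), dus_measurements(), parse_avf_label(label), s)
  }
  .maturation_cache[[key]]
}

# single tube: inlet -> one vessel -> terminal bed
single_tube_network <- function(radius_mm = 2, length_cm = 10,
                                terminal_res = 1) {
  vascular_network(
    segments = data.frame(
      id = "tube", vessel_class = "artery", length = length_cm,
      radius = radius_mm, wall_thickness = 0.5, wall_stiffness = 0.4,
      proximal_node = "n0", distal_node = "n1", adapting = FALSE),
    terminals = data.frame(name = "bed", node = "n1",
                           resistance = terminal_res),
    inlet_node = "n0")
}

# two tubes in parallel between the same nodes, lengths l and 2l
# (resistances R and 2R)
parallel_network <- function(radius_mm = 2, length_cm = 10,
                             terminal_res = 1) {
  vascular_network(
    segments = data.frame(
      id = c("tube-a", "tube-b"), vessel_class = "artery",
      length = c(length_cm, 2 * length_cm), radius = radius_mm,
      wall_thickness = 0.5, wall_stiffness = 0.4,
      proximal_node = "n0", distal_node = "n1",
      adapting = FALSE),
    terminals = data.frame(name = "bed", node = "n1",
                           resistance = terminal_res),
    inlet_node = "n0")
}

# two-resistor adaptation toy: inlet node with a bypass bed (pressure
# source role), a fixed feed tube, an adapting access tube, and an outflow
adaptation_toy_network <- function(adapt_radius_mm = 2) {
  vascular_network(
    segments = data.frame(
      id = c("feed", "access"),
      vessel_class = "artery",
      length = c(20, 10),
      radius = c(2.5, adapt_radius_mm),
      wall_thickness = 0.5, wall_stiffness = 0.4,
      proximal_node = c("n0", "n1"), distal_node = c("n1", "n2"),
      adapting = c(FALSE, TRUE)),
    terminals = data.frame(name = c("bypass", "outflow"),
                           node = c("n0", "n2"),
                           resistance = c(1, 0.05)),
    inlet_node = "n0")
}

steady_input <- function(co_lmin = 1) {
  cardiac_input(cardiac_output = co_lmin, heart_rate = 70,
                waveform = "constant")
}

# independent closed-form oracle for the adaptation toy: solves the circuit
# equation jointly with the WSS-equilibrium radius by bisection on r
toy_equilibrium_oracle <- function(net, blood, co_lmin, tau_target) {
  mu <- blood$viscosity * 1e-3
  q0 <- co_lmin * 1e-3 / 60
  seg <- net$segments
  res_of <- function(radius_mm, length_cm) {
    8 * mu * (length_cm / 100) / (pi * (radius_mm / 1000)^4)
  }
  rf <- res_of(seg$radius[seg$id == "feed"], seg$length[seg$id == "feed"])
  l_acc <- seg$length[seg$id == "access"]
  rb <- net$terminals$resistance[net$terminals$name == "bypass"] *
    133.322 / (1e-6 / 60)
  rout <- net$terminals$resistance[net$terminals$name == "outflow"] *
    133.322 / (1e-6 / 60)
  tau_of_r <- function(r_m) {
    ra <- 8 * mu * (l_acc / 100) / (pi * r_m^4)
    p0 <- q0 / (1 / rb + 1 / (rf + ra + rout))
    qa <- p0 / (rf + ra + rout)
    4 * mu * qa / (pi * r_m^3)
  }
  r_star <- stats::uniroot(function(r) tau_of_r(r) - tau_target,
                           c(1e-4, 1e-2), tol = 1e-12)$root
  ra <- 8 * mu * (l_acc / 100) / (pi * r_star^4)
  p0 <- q0 / (1 / rb + 1 / (rf + ra + rout))
  qa <- p0 / (rf + ra + rout)
  list(radius_mm = r_star * 1000, flow_mlmin = qa / (1e-6 / 60))
}
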