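#' Electric-analogy parameters of a vessel segment
#'
#' Under fully developed incompressible Newtonian flow in a straight tube
#' (hydraulic-electric analogy: pressure <-> voltage, flow <-> current):
#' \deqn{R' = 8\mu/(\pi r^4), \quad L' = \rho/(\pi r^2), \quad
#'       C = 3\pi r^3 \ell/(2 E h)}
#' with `R'` the resistance and `L'` the inertance per unit length, and `C`
#' the whole-segment storage compliance of a thin-walled elastic tube.
#'
#' @param segment one-row data frame (or list) with `radius` (mm), `length`
#'   (cm), `wall_thickness` (mm), `wall_stiffness` (MPa).
#' @param blood `blood_properties`.
#' @return list of class `segment_parameters`: `resistance_per_length`
#'   (Pa s/m^4 per m), `inertance_per_length` (Pa s^2/m^4 per m),
#'   `compliance` (m^3/Pa).
#' @examples
#' b <- blood_properties(45, 7)
#' segment_parameters(list(radius = 2, length = 10, wall_thickness = 0.5,
#'                         wall_stiffness = 0.4), b)
#' @export
segment_parameters <- function(segment, blood) {
  r <- mm_to_m(segment$radius)
  l <- cm_to_m(segment$length)
  h <- mm_to_m(segment$wall_thickness)
  E <- segment$wall_stiffness * 1e6
  mu <- mPas_to_Pas(blood$viscosity)
  structure(list(
    resistance_per_length = 8 * mu / (pi * r^4),
    inertance_per_length = blood$density / (pi * r^2),
    compliance = 3 * pi * r^3 * l / (2 * E * h)
  ), class = "segment_parameters")
}

#' Pressure-dependent compliance of a vein segment
#'
#' Veins are highly distensible near zero transmural pressure and stiffen as
#' they are pressurized toward a circular, artery-like state. The package
#' uses an arctangent pressure-area relation,
#' \deqn{A(P) = A_{ref}\,[1 + \kappa P_w \arctan(P/P_w)] + (C_{el}/\ell) P}
#' whose derivative gives the whole-segment compliance
#' \deqn{C(P) = \ell\,A_{ref}\,\kappa / (1 + (P/P_w)^2) + C_{el}}
#' where \eqn{C_{el}} is the thin-wall elastic compliance
#' (the high-pressure floor), \eqn{\kappa} the low-pressure distensibility
#' and \eqn{P_w} the transition width (both in the `venous` settings block).
#' The function is smooth, strictly positive and monotonically decreasing in
#' pressure for P >= 0.
#'
#' @param pressure transmural pressure, mmHg.
#' @param segment one-row data frame/list with `vessel_class == "vein"`,
#'   `radius` (mm), `length` (cm), `wall_thickness` (mm), `wall_stiffness`
#'   (MPa).
#' @param blood `blood_properties` (density only enters through the elastic
#'   floor's formula indirectly; accepted for interface symmetry).
#' @param settings `avf_settings`.
#' @return compliance, m^3/Pa (vectorized over `pressure`).
#' @export
venous_compliance <- function(pressure, segment,
                              blood = blood_properties(33, 6.5),
                              settings = avf_settings()) {
  if (!identical(segment$vessel_class, "vein"))
    stop("venous_compliance() called on a non-vein segment ('",
         segment$id %||% "?", "'); arteries use the linear elastic compliance")
  p_pa <- mmHg_to_Pa(pressure)
  pw <- mmHg_to_Pa(settings$venous$width_mmHg)
  kappa <- settings$venous$distensibility_per_mmHg / MMHG_PA  # 1/Pa
  r <- mm_to_m(segment$radius)
  l <- cm_to_m(segment$length)
  a_ref <- pi * r^2
  c_el <- segment_parameters(segment, blood)$compliance
  l * a_ref * kappa / (1 + (p_pa / pw)^2) + c_el
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pressure drop across the nonlinear anastomosis element
#'
#' \deqn{\Delta P = a Q + b Q |Q|}
#' odd in Q and strictly increasing in |Q|: a Poiseuille-like linear term
#' for the short anastomotic channel plus a Borda-Carnot-style expansion
#' loss quadratic in flow.
#'
#' @param flow mL/min (signed).
#' @param element anastomosis element with `linear_coefficient` (Pa s/m^3)
#'   and `quadratic_coefficient` (Pa s^2/m^6).
#' @return pressure drop, mmHg (vectorized over `flow`).
#' @export
anastomosis_pressure_drop <- function(flow, element) {
  q <- mlmin_to_m3s(flow)
  Pa_to_mmHg(element$linear_coefficient * q +
               element$quadratic_coefficient * q * abs(q))
}

#' Cardiac inflow boundary condition for a patient
#'
#' Cardiac output is assumed from the cardiac index:
#' `CO = CI x BSA(height, weight)`. The inflow waveform is a unit-mean
#' periodic shape: a half-sine systolic pulse occupying the ejection
#' fraction of the period (diastolic inflow zero), or a constant for steady
#' analyses.
#'
#' @param patient `patient_record`.
#' @param cardiac_index L/min/m^2.
#' @param settings `avf_settings`.
#' @return `cardiac_input`: `cardiac_output` (L/min), `heart_rate` (bpm),
#'   `waveform`, `ejection_fraction`.
#' @export
cardiac_inflow <- function(patient,
                           cardiac_index = avf_settings()$cardiac$cardiac_index,
                           settings = avf_settings()) {
  bsa <- body_surface_area(patient$height, patient$weight)
  cardiac_input(
    cardiac_output = cardiac_index * bsa,
    heart_rate = patient$heart_rate %||% settings$reference$heart_rate,
    waveform = settings$cardiac$waveform,
    ejection_fraction = settings$cardiac$ejection_fraction
  )
}

#' Construct a cardiac inflow directly
#' @param cardiac_output L/min.
#' @param heart_rate beats/min.
#' @param waveform `"pulse"` or `"constant"`.
#' @param ejection_fraction fraction of the period carrying the pulse.
#' @return `cardiac_input`.
#' @export
cardiac_input <- function(cardiac_output, heart_rate = 70,
                          waveform = c("pulse", "constant"),
                          ejection_fraction = 0.35) {
  waveform <- match.arg(waveform)
  stopifnot(cardiac_output >= 0, heart_rate > 0,
            ejection_fraction > 0, ejection_fraction <= 1)
  structure(list(cardiac_output = cardiac_output, heart_rate = heart_rate,
                 waveform = waveform, ejection_fraction = ejection_fraction),
            class = "cardiac_input")
}

#' Discrete unit-mean inflow waveform over one period
#'
#' Samples the waveform at the `n_steps` implicit-step endpoints and
#' normalizes so the discrete mean is exactly 1 (the inflow series times the
#' cardiac output then integrates exactly to the stroke volume per cycle).
#'
#' @param input `cardiac_input`.
#' @param n_steps samples per cycle.
#' @return numeric vector of length `n_steps`, mean exactly 1.
#' @export
inflow_waveform <- function(input, n_steps) {
  if (input$waveform == "constant") return(rep(1, n_steps))
  period <- 60 / input$heart_rate
  t <- (seq_len(n_steps)) * period / n_steps
  ts <- input$ejection_fraction * period
  w <- ifelse(t <= ts, sin(pi * t / ts), 0)
  w / mean(w)
}

# ---- internal: network discretization into lumped RLC compartments --------

# Splits every anatomical segment into compartments of length <=
# settings$solver$compartment_length_cm (a chain of short RLC cells
# approximating 1-D transmission-line behavior) and assembles index
# structures for the circuit solver. All quantities SI.
discretize_network <- function(net, blood, settings) {
  seg <- net$segments
  comp_len_max <- settings$solver$compartment_length_cm
  comp <- list()
  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    n_c <- max(1L, ceiling(s$length / comp_len_max))
    par <- segment_parameters(s, blood)
    l_c <- cm_to_m(s$length) / n_c
    inner <- if (n_c > 1) paste0(s$id, "#", seq_len(n_c - 1)) else character(0)
    nodes_chain <- c(s$proximal_node, inner, s$distal_node)
    for (k in seq_len(n_c)) {
      comp[[length(comp) + 1]] <- list(
        seg_id = s$id, seg_idx = i,
        from = nodes_chain[k], to = nodes_chain[k + 1],
        R = par$resistance_per_length * l_c,
        L = par$inertance_per_length * l_c,
        C = par$compliance / n_c,
        quad = 0,
        is_vein = identical(s$vessel_class, "vein"),
        radius_m = mm_to_m(s$radius), length_m = l_c)
    }
  }
  if (!is.null(net$anastomosis)) {
    an <- net$anastomosis
    comp[[length(comp) + 1]] <- list(
      seg_id = ".anastomosis", seg_idx = NA_integer_,
      from = an$arterial_node, to = an$venous_node,
      R = an$linear_coefficient, L = an$inertance,
      C = 0, quad = an$quadratic_coefficient,
      is_vein = FALSE, radius_m = NA_real_, length_m = NA_real_)
  }
  d <- list(
    seg_id = vapply(comp, `[[`, "", "seg_id"),
    seg_idx = vapply(comp, `[[`, 1L, "seg_idx"),
    from = vapply(comp, `[[`, "", "from"),
    to = vapply(comp, `[[`, "", "to"),
    R = vapply(comp, `[[`, 1, "R"),
    L = vapply(comp, `[[`, 1, "L"),
    C = vapply(comp, `[[`, 1, "C"),
    quad = vapply(comp, `[[`, 1, "quad"),
    is_vein = vapply(comp, `[[`, TRUE, "is_vein"),
    radius_m = vapply(comp, `[[`, 1, "radius_m"),
    length_m = vapply(comp, `[[`, 1, "length_m"))
  d$nodes <- unique(c(d$from, d$to))
  d$ifrom <- match(d$from, d$nodes)
  d$ito <- match(d$to, d$nodes)
  d$inlet <- match(net$inlet_node, d$nodes)
  if (is.na(d$inlet)) stop("inlet node not found after discretization")
  # terminal conductances per node (SI)
  G <- numeric(length(d$nodes))
  if (nrow(net$terminals) > 0) {
    tn <- match(net$terminals$node, d$nodes)
    for (k in seq_along(tn))
      G[tn[k]] <- G[tn[k]] + 1 / mmHgminml_to_SI(net$terminals$resistance[k])
  }
  d$G <- G
  d$n_comp <- length(d$R)
  d$n_node <- length(d$nodes)
  d$j_quad <- which(d$quad > 0)  # at most one nonlinear element
  d
}

# compartment compliances at the given node operating pressures (SI, Pa):
# arteries keep the elastic value; veins follow the pressure-area law
# evaluated at the compartment's mean transmural pressure.
compartment_compliances <- function(d, net, blood, settings, p_op) {
  C <- d$C
  vein_idx <- which(d$is_vein)
  if (length(vein_idx) > 0) {
    pw <- mmHg_to_Pa(settings$venous$width_mmHg)
    kappa <- settings$venous$distensibility_per_mmHg / MMHG_PA
    p_mid <- pmax(0, 0.5 * (p_op[d$ifrom[vein_idx]] + p_op[d$ito[vein_idx]]))
    a_ref <- pi * d$radius_m[vein_idx]^2
    C[vein_idx] <- d$length_m[vein_idx] * a_ref * kappa /
      (1 + (p_mid / pw)^2) + d$C[vein_idx]
  }
  C
}

#' Solve the circuit for periodic pressure and flow waveforms
#'
#' Time-integrates the lumped network equations (momentum per compartment:
#' `L dQ/dt = P_prox - P_dist - R Q` plus the anastomosis' quadratic loss;
#' mass per node: `C dP/dt = sum(Q_in) - sum(Q_out) - P/R_term + Q_inlet(t)`)
#' with a backward-Euler scheme, cycle to cycle, until the relative L2
#' difference of the state between consecutive cycles falls below the
#' tolerance. Venous compliances are evaluated at each cycle's mean nodal
#' pressures and updated between cycles; the nonlinear anastomosis
#' resistance is handled per step by a rank-1 Sherman-Morrison correction
#' with Picard iteration. The scheme is fully deterministic.
#'
#' @param network `vascular_network`.
#' @param blood `blood_properties`.
#' @param input `cardiac_input`.
#' @param settings `avf_settings` (solver block: steps per cycle, tolerance,
#'   cycle limits, compartment length).
#' @param tolerance periodicity tolerance; defaults to the settings value.
#' @param init optional warm start: the `state` element of a previous
#'   solution of a structurally identical network.
#' @return `hemodynamic_solution`: `time` (s), `segment_flows` (named list of
#'   mL/min waveforms per anatomical segment), `node_pressures` (named list
#'   of mmHg waveforms for anatomical nodes), `anastomosis_flow` (mL/min or
#'   `NULL`), `converged`, `periodicity_residual`, `cycles`, and a `state`
#'   carrier for warm starts and conservation checks.
#' @export
solve_periodic <- function(network, blood, input,
                           settings = avf_settings(),
                           tolerance = settings$solver$tolerance,
                           init = NULL) {
  stopifnot(tolerance > 0)
  validate_network(network)
  d <- discretize_network(network, blood, settings)
  sv <- settings$solver
  n_steps <- sv$steps_per_cycle
  period <- 60 / input$heart_rate
  dt <- period / n_steps
  co_si <- input$cardiac_output * 1e-3 / 60        # L/min -> m^3/s
  qin <- co_si * inflow_waveform(input, n_steps)   # inlet inflow per step

  nq <- d$n_comp; nn <- d$n_node; N <- nq + nn
  # constant part of the system: momentum and mass couplings
  K <- matrix(0, N, N)
  for (j in seq_len(nq)) {
    K[j, j] <- d$R[j]
    K[j, nq + d$ifrom[j]] <- -1
    K[j, nq + d$ito[j]] <- 1
    K[nq + d$ifrom[j], j] <- K[nq + d$ifrom[j], j] + 1
    K[nq + d$ito[j], j] <- K[nq + d$ito[j], j] - 1
  }
  for (i in seq_len(nn)) K[nq + i, nq + i] <- d$G[i]

  x <- if (!is.null(init)) init$x else numeric(N)
  if (length(x) != N) stop("warm-start state does not match this network")
  p_op <- if (!is.null(init)) init$p_op else numeric(nn)

  Q <- matrix(0, nq, n_steps)
  P <- matrix(0, nn, n_steps)
  jq <- if (length(d$j_quad) == 1) d$j_quad else NA_integer_
  b_quad <- if (!is.na(jq)) d$quad[jq] else 0

  residual_history <- numeric(0)
  converged <- FALSE
  c_node_used <- NULL
  x_prev_end <- x
  scale <- max(co_si, 1e-30)
  cycles_run <- 0

  for (cyc in seq_len(sv$max_cycles)) {
    cycles_run <- cyc
    Cc <- compartment_compliances(d, network, blood, settings, p_op)
    c_node <- numeric(nn)
    half <- Cc / 2
    for (j in seq_len(nq)) {
      c_node[d$ifrom[j]] <- c_node[d$ifrom[j]] + half[j]
      c_node[d$ito[j]] <- c_node[d$ito[j]] + half[j]
    }
    if (any(c_node <= 0))
      stop("node without storage capacity: ",
           paste(d$nodes[c_node <= 0], collapse = ", "))
    m_diag <- c(d$L, c_node)
    A <- K + diag(m_diag / dt)
    # equilibrate before inversion: flows O(q0), pressures O(p0); momentum
    # rows are pressure balances, mass rows flow balances
    q0 <- max(co_si, 1e-6)
    p0 <- 1e4  # Pa, arterial pressure scale
    col_s <- c(rep(q0, nq), rep(p0, nn))
    row_s <- c(rep(1 / p0, nq), rep(1 / q0, nn))
    As <- A * outer(row_s, col_s)
    Ainv <- t(t(solve(As) * col_s) * row_s)  # physical-units inverse
    w <- if (!is.na(jq)) Ainv[, jq] else NULL
    x_start <- x

    for (s in seq_len(n_steps)) {
      rhs <- (m_diag / dt) * x
      rhs[nq + d$inlet] <- rhs[nq + d$inlet] + qin[s]
      y <- drop(Ainv %*% rhs)
      if (!is.na(jq) && b_quad > 0) {
        r <- b_quad * abs(x[jq])
        for (it in 1:3) {
          xj <- y[jq] - w[jq] * (r * y[jq]) / (1 + r * w[jq])
          r <- b_quad * abs(xj)
        }
        x <- y - w * (r * y[jq]) / (1 + r * w[jq])
      } else {
        x <- y
      }
      Q[, s] <- x[seq_len(nq)]
      P[, s] <- x[nq + seq_len(nn)]
    }
    c_node_used <- c_node
    res <- sqrt(sum((x - x_prev_end)^2)) /
      max(sqrt(sum(x^2)), scale * 1e-9)
    if (co_si == 0) res <- 0
    residual_history <- c(residual_history, res)
    x_prev_end <- x
    p_op <- rowMeans(P)
    if (cyc >= sv$min_cycles && res <= tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged && co_si > 0) {
    cond <- structure(
      class = c("avfsim_nonconvergence", "error", "condition"),
      list(message = paste0(
        "periodic solver did not converge within ", sv$max_cycles,
        " cycles (last residual ",
        format(residual_history[length(residual_history)], digits = 4), ")"),
        call = sys.call(), residual_history = residual_history))
    stop(cond)
  }
  if (any(!is.finite(x))) {
    bad <- unique(d$seg_id[!is.finite(x[seq_len(nq)])])
    stop("non-finite state in segment(s): ", paste(bad, collapse = ", "))
  }

  # aggregate compartments back to anatomical segments (mean over the chain)
  seg_ids <- network$segments$id
  segment_flows <- lapply(seg_ids, function(id) {
    rows <- which(d$seg_id == id)
    m3s_to_mlmin(colMeans(Q[rows, , drop = FALSE]))
  })
  names(segment_flows) <- seg_ids
  anat_nodes <- intersect(d$nodes, network_nodes(network))
  node_pressures <- lapply(anat_nodes, function(nd) {
    Pa_to_mmHg(P[match(nd, d$nodes), ])
  })
  names(node_pressures) <- anat_nodes
  anastomosis_flow <- if (!is.na(jq)) m3s_to_mlmin(Q[jq, ]) else NULL

  structure(list(
    time = dt * seq_len(n_steps),
    segment_flows = segment_flows,
    node_pressures = node_pressures,
    anastomosis_flow = anastomosis_flow,
    converged = converged,
    periodicity_residual = residual_history[length(residual_history)],
    cycles = cycles_run,
    residual_history = residual_history,
    state = list(x = x, p_op = p_op, Q = Q, P = P, d = d,
                 c_node = c_node_used, dt = dt, qin = qin,
                 mean_inlet = co_si, x_start = x_start)
  ), class = "hemodynamic_solution")
}

#' @export
print.hemodynamic_solution <- function(x, ...) {
  cat(sprintf(
    "hemodynamic solution: %d segments, %d samples/cycle, %d cycles, %s\n",
    length(x$segment_flows), length(x$time), x$cycles,
    if (x$converged) sprintf("converged (residual %.2e)",
                             x$periodicity_residual) else "NOT converged"))
  invisible(x)
}

#' Cycle-mean and peak flow of a segment
#'
#' The cycle mean is the blood flow volume (BFV) reported clinically; the
#' peak drives the wall-shear-stress adaptation.
#'
#' @param solution `hemodynamic_solution`.
#' @param segment_id anatomical segment id.
#' @return named numeric: `mean` and `peak`, mL/min.
#' @export
mean_and_peak_flow <- function(solution, segment_id) {
  q <- solution$segment_flows[[segment_id]]
  if (is.null(q)) stop("unknown segment id: ", segment_id)
  c(mean = mean(q), peak = max(q))
}

#' Peak wall shear stress of a segment (Poiseuille)
#'
#' \deqn{\tau_{peak} = 4 \mu Q_{peak} / (\pi r^3)}
#' evaluated at the cycle's peak flow; the homeostatic quantity the
#' adaptation algorithm regulates.
#'
#' @param solution `hemodynamic_solution`.
#' @param segment one-row data frame/list with `id` and `radius` (mm).
#' @param blood `blood_properties`.
#' @return Pa.
#' @export
peak_wss <- function(solution, segment, blood) {
  qp <- mlmin_to_m3s(mean_and_peak_flow(solution, segment$id)[["peak"]])
  4 * mPas_to_Pas(blood$viscosity) * qp / (pi * mm_to_m(segment$radius)^3)
}

#' Maximum relative mass-conservation residual of a solution
#'
#' Evaluates the discrete nodal mass balance
#' `C (P_s - P_{s-1})/dt + sum(signed Q_s) + G P_s - Q_inlet(s)` at every
#' node and sample of the final (periodic) cycle, normalized by the mean
#' inlet flow. For a converged solve this is at rounding-error level.
#'
#' @param solution `hemodynamic_solution`.
#' @return maximum relative imbalance (dimensionless).
#' @export
mass_residual <- function(solution) {
  st <- solution$state
  d <- st$d
  if (st$mean_inlet == 0) return(0)
  n_steps <- ncol(st$P)
  nq0 <- st$d$n_comp
  p0 <- st$x_start[nq0 + seq_len(st$d$n_node)]
  Pprev <- cbind(p0, st$P[, seq_len(n_steps - 1), drop = FALSE])
  dPdt <- (st$P - Pprev) / st$dt
  nq <- d$n_comp
  imb <- st$c_node * dPdt + d$G * st$P
  for (j in seq_len(nq)) {
    imb[d$ifrom[j], ] <- imb[d$ifrom[j], ] + st$Q[j, ]
    imb[d$ito[j], ] <- imb[d$ito[j], ] - st$Q[j, ]
  }
  imb[d$inlet, ] <- imb[d$inlet, ] - st$qin
  max(abs(imb)) / st$mean_inlet
}
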