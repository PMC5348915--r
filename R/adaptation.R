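# Anatomical attachment sites for each AVF location in the reference arm
# network: the configured site segment, the venous anastomosis node, and the
# venous-limb elements ligated when the peripheral vein limb is taken down.
avf_site_table <- function(location) {
  switch(location,
    `radio-cephalic` = list(
      site_segment = "radial-artery-distal",
      vein_node = "n-wrist-v",
      vein_segment = "cephalic-vein-wrist",
      ligate_terminals = "hand-venous-bed",
      ligate_segments = character(0)),
    `brachio-cephalic` = list(
      site_segment = "brachial-artery-elbow",
      vein_node = "n-elbow-v",
      vein_segment = "cephalic-vein-upper",
      ligate_terminals = "hand-venous-bed",
      ligate_segments = c("cephalic-vein-forearm", "cephalic-vein-wrist")),
    stop("unknown AVF location: ", location))
}

#' Create the post-surgical network for an AVF configuration
#'
#' Inserts a nonlinear anastomosis element joining the configured artery
#' site (distal radial artery for radio-cephalic, brachial artery at the
#' elbow for brachio-cephalic) to the cephalic vein:
#' * **end-to-side** (clinical side-to-end): artery stays fully patent; the
#'   peripheral (distal) venous limb is ligated;
#' * **end-to-end**: the artery is transected at the proximal node of the
#'   site segment and its proximal stump diverted entirely into the vein;
#'   the distal arterial limb is disconnected from the anastomosis node (for
#'   a radio-cephalic fistula the hand is then supplied by the ulnar artery
#'   through the palmar arch); the peripheral venous limb is ligated;
#' * **side-to-side**: both arterial and both venous limbs stay patent.
#'
#' The anastomosis coefficients come from the effective orifice:
#' `a = 8 mu_ref l / (pi r^4)` (Poiseuille term of the short anastomotic
#' channel) and `b = K rho / (2 A^2)` (Borda-Carnot expansion loss). The
#' orifice radius is the configured per-(location, kind) base value scaled
#' by the geometric mean of the joined vessels' relative calibers, so
#' patients with larger site vessels receive proportionally larger
#' anastomoses.
#'
#' @param network pre-operative `vascular_network` (no anastomosis).
#' @param config `avf_configuration`.
#' @param settings `avf_settings`.
#' @return post-surgical `vascular_network` with an `anastomosis` element.
#' @export
create_avf <- function(network, config, settings = avf_settings()) {
  if (!is.null(network$anastomosis))
    stop("network already carries an anastomosis")
  site <- avf_site_table(config$location)
  seg <- network$segments
  si <- match(site$site_segment, seg$id)
  if (is.na(si))
    stop("configuration site segment '", site$site_segment,
         "' missing from network")
  if (!site$vein_node %in% network_nodes(network))
    stop("configuration vein node '", site$vein_node,
         "' missing from network")

  net <- network
  if (config$kind %in% c("end-to-side", "end-to-end")) {
    # take down the peripheral venous limb
    net$terminals <- net$terminals[
      !net$terminals$name %in% site$ligate_terminals, , drop = FALSE]
    net$segments <- net$segments[
      !net$segments$id %in% site$ligate_segments, , drop = FALSE]
  }
  if (config$kind == "end-to-end") {
    # transect the artery at the proximal node of the site segment; the
    # feeder's distal end becomes the anastomosis node, the site segment
    # stays behind as the disconnected distal limb
    cut_node <- seg$proximal_node[si]
    feeder <- which(net$segments$distal_node == cut_node &
                      net$segments$vessel_class == "artery" &
                      net$segments$id != site$site_segment)
    if (length(feeder) != 1)
      stop("cannot locate a unique feeding artery for end-to-end at node '",
           cut_node, "'")
    art_node <- "avf-anastomosis"
    net$segments$distal_node[feeder] <- art_node
  } else {
    art_node <- seg$distal_node[si]
  }

  an <- settings$anastomosis
  # effective orifice: configured base radius scaled with the calibers of
  # the two vessels actually joined (patients with larger site vessels get
  # proportionally larger anastomoses)
  ref <- an$site_reference_mm[[config$location]]
  r_art <- seg$radius[si]
  vi <- match(site$vein_segment, seg$id)
  r_vein <- if (is.na(vi)) ref$vein else seg$radius[vi]
  caliber <- sqrt((r_art / ref$artery) * (r_vein / ref$vein))
  r <- mm_to_m(an$radius_mm[[config$location]][[config$kind]] * caliber)
  l <- mm_to_m(an$length_mm)
  K <- an$loss_k[[config$kind]]
  area <- pi * r^2
  net$anastomosis <- list(
    kind = config$kind, location = config$location,
    arterial_node = art_node, venous_node = site$vein_node,
    linear_coefficient = 8 * mPas_to_Pas(an$mu_ref) * l / (pi * r^4),
    quadratic_coefficient = K * settings$blood$density / (2 * area^2),
    inertance = settings$blood$density * l / area,
    radius_mm = m_to_mm(r))
  validate_network(net)
  net
}

#' Wall-shear-stress homeostasis targets for the adapting segments
#'
#' In the default `baseline-per-segment` mode each adapting segment's target
#' is its own pre-operative peak wall shear stress, floored at the
#' configured minimum (arterial and venous floors differ: pre-operative
#' venous WSS is near zero, and the floor is what prevents runaway venous
#' dilation). In `global-constant` mode all adapting segments share
#' `tau_target`.
#'
#' @param network pre-operative `vascular_network`.
#' @param preop_solution converged `hemodynamic_solution` of `network`.
#' @param settings `avf_settings`.
#' @param blood `blood_properties`.
#' @return named numeric vector, Pa, one entry per adapting segment.
#' @export
set_wss_targets <- function(network, preop_solution,
                            settings = avf_settings(),
                            blood = blood_properties(33, 6.5)) {
  ad <- settings$adaptation
  seg <- network$segments
  idx <- which(seg$adapting)
  targets <- numeric(length(idx))
  names(targets) <- seg$id[idx]
  for (k in seq_along(idx)) {
    s <- seg[idx[k], ]
    if (ad$wss_target_mode == "global-constant") {
      targets[k] <- ad$tau_target
    } else {
      floor_pa <- if (s$vessel_class == "vein") ad$vein_floor_pa
                  else ad$artery_floor_pa
      targets[k] <- max(peak_wss(preop_solution, s, blood), floor_pa)
    }
  }
  targets
}

#' One explicit-Euler step of the WSS-driven remodeling rule
#'
#' For every adapting segment,
#' \deqn{r \leftarrow r\,[1 + k\,\Delta t\,(\tau_{peak}/\tau_{target} - 1)]}
#' dilation when shear is above target, constriction back toward baseline
#' when below; the fixed point is \eqn{\tau_{peak} = \tau_{target}}.
#' Non-adapting segments are untouched; radii are floored at the configured
#' minimum.
#'
#' @param network current `vascular_network`.
#' @param solution converged `hemodynamic_solution` of `network`.
#' @param targets named vector from [set_wss_targets()].
#' @param dt day step, days.
#' @param settings `avf_settings`.
#' @param blood `blood_properties`.
#' @return updated `vascular_network`.
#' @export
adaptation_step <- function(network, solution, targets, dt,
                            settings = avf_settings(),
                            blood = blood_properties(33, 6.5)) {
  stopifnot(dt > 0)
  ad <- settings$adaptation
  seg <- network$segments
  for (id in names(targets)) {
    i <- match(id, seg$id)
    if (is.na(i)) next  # segment may have been removed by the surgery
    tau <- peak_wss(solution, seg[i, ], blood)
    factor <- 1 + ad$rate_constant * dt * (tau / targets[[id]] - 1)
    seg$radius[i] <- max(seg$radius[i] * factor, ad$min_radius_mm)
  }
  network$segments <- seg
  network
}

#' Simulate AVF maturation from surgery to 40 days
#'
#' Full pipeline: build the generic network, scale it to the patient, apply
#' DUS diameter overrides, solve the pre-operative state, fix the WSS
#' targets, create the configured anastomosis, then march over the day grid
#' alternating periodic solves and remodeling steps. Day 0 is the immediate
#' post-surgical (pre-remodeling) state. Deterministic throughout.
#'
#' @param patient `patient_record`.
#' @param dus `dus_measurements`.
#' @param config `avf_configuration`.
#' @param settings `avf_settings`.
#' @param network optional pre-built generic `vascular_network` (defaults to
#'   the packaged reference arm).
#' @return `maturation_series`: `days`; `bfv` and `diameters` (named lists
#'   of per-day series at the reporting sites: brachial artery, radial
#'   artery for distal fistulae, cephalic vein); pre-operative values;
#'   WSS-convergence diagnostics; mean hand-bed perfusion per day (steal
#'   signal, reported but not thresholded).
#' @export
simulate_maturation <- function(patient, dus, config,
                                settings = avf_settings(),
                                network = NULL) {
  validate_patient(patient)
  blood <- blood_properties(patient$hematocrit, patient$plasma_protein,
                            settings)
  net0 <- if (is.null(network)) build_generic_network() else network
  scaled <- scale_to_patient(net0, patient, settings)
  scaled <- apply_dus_overrides(scaled, dus)
  input <- cardiac_inflow(patient, settings$cardiac$cardiac_index, settings)

  preop_sol <- solve_periodic(scaled, blood, input, settings)
  targets <- set_wss_targets(scaled, preop_sol, settings, blood)
  post <- create_avf(scaled, config, settings)

  sites <- reporting_sites(config)
  days <- day_grid(settings)
  nd <- length(days)
  bfv <- sapply(sites$bfv, function(s) rep(NA_real_, nd), simplify = FALSE)
  dia <- sapply(sites$diameters, function(s) rep(NA_real_, nd),
                simplify = FALSE)
  hand <- rep(NA_real_, nd)
  cycles <- rep(NA_integer_, nd)

  sol <- NULL
  for (i in seq_len(nd)) {
    if (i > 1)
      post <- adaptation_step(post, sol, targets, days[i] - days[i - 1],
                              settings, blood)
    sol <- tryCatch(
      solve_periodic(post, blood, input, settings,
                     init = if (i > 1) sol$state[c("x", "p_op")] else NULL),
      error = function(e) stop("day ", days[i], ": ", conditionMessage(e),
                               call. = FALSE))
    for (s in names(bfv))
      bfv[[s]][i] <- mean_and_peak_flow(sol, sites$bfv[[s]])[["mean"]]
    for (s in names(dia))
      dia[[s]][i] <- 2 * post$segments$radius[
        match(sites$diameters[[s]], post$segments$id)]
    hand[i] <- hand_perfusion(post, sol)
    cycles[i] <- sol$cycles
  }

  # final-day homeostasis check
  rel_err <- vapply(names(targets), function(id) {
    i <- match(id, post$segments$id)
    if (is.na(i)) return(0)
    abs(peak_wss(sol, post$segments[i, ], blood) / targets[[id]] - 1)
  }, 1)

  structure(list(
    days = days,
    bfv = bfv,
    diameters = dia,
    preop = list(
      bfv = sapply(sites$bfv, function(sid)
        mean_and_peak_flow(preop_sol, sid)[["mean"]], simplify = FALSE),
      diameters = sapply(sites$diameters, function(sid) {
        i <- match(sid, scaled$segments$id)
        if (is.na(i)) NA_real_ else 2 * scaled$segments$radius[i]
      }, simplify = FALSE)),
    hand_perfusion = hand,
    wss_converged = all(rel_err <= settings$adaptation$convergence_tol),
    wss_rel_error = rel_err,
    wss_targets = targets,
    solver_cycles = cycles,
    config = config,
    final_network = post
  ), class = "maturation_series")
}

# reporting sites per configuration; the cephalic station nearest the
# anastomosis that survives the surgery
reporting_sites <- function(config) {
  distal <- config$location == "radio-cephalic"
  bfv <- list(brachial = "brachial-artery-mid")
  if (distal) bfv$radial <- "radial-artery-distal"
  dia <- list(brachial = "brachial-artery-mid",
              radial = "radial-artery-distal",
              cephalic = if (distal) "cephalic-vein-wrist"
                         else "cephalic-vein-upper")
  list(bfv = bfv, diameters = dia)
}

# cycle-mean flow into the hand terminal beds (mL/min): steal-risk signal
hand_perfusion <- function(network, solution) {
  hb <- network$terminals[grepl("^hand-(radial|ulnar)", network$terminals$name), ,
                          drop = FALSE]
  if (nrow(hb) == 0) return(NA_real_)
  total <- 0
  for (k in seq_len(nrow(hb))) {
    p <- solution$node_pressures[[hb$node[k]]]
    if (is.null(p)) next
    total <- total + mean(p) / hb$resistance[k]  # mmHg / (mmHg min/mL)
  }
  total
}

#' @export
print.maturation_series <- function(x, ...) {
  nd <- length(x$days)
  cat(sprintf("AVF maturation (%s %s): day 0-%g\n",
              x$config$location, x$config$kind, x$days[nd]))
  cat(sprintf("  brachial BFV: pre-op %.0f -> day 0 %.0f -> day %g %.0f mL/min\n",
              x$preop$bfv$brachial, x$bfv$brachial[1], x$days[nd],
              x$bfv$brachial[nd]))
  cat(sprintf("  WSS homeostasis %s (max rel. error %.3f)\n",
              if (x$wss_converged) "reached" else "NOT reached",
              max(x$wss_rel_error)))
  invisible(x)
}
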