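#' Build the generic adult vascular network
#'
#' Reads a network-description YAML file (segments, terminals, inlet) into a
#' `vascular_network` object and validates it. The default file shipped with
#' the package describes a reference adult: aortic inlet, subclavian /
#' axillary / brachial artery, radial and ulnar arteries joined by the palmar
#' arch, the cephalic / cubital / basilic / subclavian venous tree, and
#' lumped terminal beds (side branches, hand, systemic remainder, central
#' venous outflow). Every Doppler-ultrasound protocol site is a named
#' segment so measured diameters can override the generic ones.
#'
#' @param config path to a network YAML file; default is the packaged
#'   reference-arm description.
#' @return `vascular_network`: list with `segments` (data frame), `terminals`
#'   (data frame), `inlet_node`, and `anastomosis` (`NULL` pre-operatively).
#' @examples
#' net <- build_generic_network()
#' nrow(net$segments)
#' @export
build_generic_network <- function(config = default_network_file()) {
  if (!file.exists(config)) stop("network config not found: ", config)
  y <- yaml::read_yaml(config)
  if (is.null(y$segments) || is.null(y$terminals) || is.null(y$inlet_node))
    stop("malformed network config '", config,
         "': needs 'segments', 'terminals' and 'inlet_node'")

  seg <- do.call(rbind, lapply(y$segments, function(s) {
    for (f in c("id", "vessel_class", "proximal_node", "distal_node",
                "length_cm", "radius_mm", "wall_mm", "stiffness_MPa"))
      if (is.null(s[[f]]))
        stop("malformed network config: segment '",
             if (is.null(s$id)) "<unnamed>" else s$id,
             "' is missing field '", f, "'")
    data.frame(id = s$id, name = s$id, vessel_class = s$vessel_class,
               length = as.numeric(s$length_cm),
               radius = as.numeric(s$radius_mm),
               wall_thickness = as.numeric(s$wall_mm),
               wall_stiffness = as.numeric(s$stiffness_MPa),
               proximal_node = s$proximal_node, distal_node = s$distal_node,
               adapting = isTRUE(s$adapting),
               stringsAsFactors = FALSE)
  }))
  term <- do.call(rbind, lapply(y$terminals, function(t) {
    for (f in c("name", "node", "resistance_mmHg_min_ml"))
      if (is.null(t[[f]]))
        stop("malformed network config: terminal '",
             if (is.null(t$name)) "<unnamed>" else t$name,
             "' is missing field '", f, "'")
    data.frame(name = t$name, node = t$node,
               resistance = as.numeric(t$resistance_mmHg_min_ml),
               stringsAsFactors = FALSE)
  }))

  net <- structure(list(segments = seg, terminals = term,
                        inlet_node = y$inlet_node, anastomosis = NULL),
                   class = "vascular_network")
  validate_network(net)
  net
}

#' Path to the packaged reference-arm network description
#' @return file path.
#' @export
default_network_file <- function() {
  system.file("extdata", "arm_network.yaml", package = "avfsim",
              mustWork = TRUE)
}

#' Construct a vascular network from parts (used for toy/test circuits)
#'
#' @param segments data frame with columns `id`, `vessel_class`, `length`
#'   (cm), `radius` (mm), `wall_thickness` (mm), `wall_stiffness` (MPa),
#'   `proximal_node`, `distal_node`, `adapting`.
#' @param terminals data frame with columns `name`, `node`, `resistance`
#'   (mmHg*min/mL).
#' @param inlet_node node id receiving the cardiac inflow.
#' @param anastomosis optional anastomosis element (see [create_avf()]).
#' @return `vascular_network`.
#' @export
vascular_network <- function(segments, terminals, inlet_node,
                             anastomosis = NULL) {
  if (!"name" %in% names(segments)) segments$name <- segments$id
  if (!"adapting" %in% names(segments)) segments$adapting <- FALSE
  net <- structure(list(segments = as.data.frame(segments),
                        terminals = as.data.frame(terminals),
                        inlet_node = inlet_node, anastomosis = anastomosis),
                   class = "vascular_network")
  validate_network(net)
  net
}

network_nodes <- function(net) {
  unique(c(net$segments$proximal_node, net$segments$distal_node,
           if (!is.null(net$anastomosis))
             c(net$anastomosis$arterial_node, net$anastomosis$venous_node)))
}

# igraph view of the network. Terminal elements drain to the extravascular
# reference; including that reference as a ground vertex makes the electrical
# graph (arterial tree -> beds -> ground <- veins) a single component.
network_igraph <- function(net, include_ground = TRUE) {
  edges <- rbind(
    data.frame(from = net$segments$proximal_node,
               to = net$segments$distal_node),
    if (!is.null(net$anastomosis))
      data.frame(from = net$anastomosis$arterial_node,
                 to = net$anastomosis$venous_node),
    if (include_ground && nrow(net$terminals) > 0)
      data.frame(from = net$terminals$node, to = "..ground..")
  )
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Validate a vascular network's structural invariants
#'
#' Checks unique segment ids, positive geometry, resolvable node references,
#' a single inlet, electrical connectivity (through the terminal beds and
#' the common extravascular reference), and that every dead-end node carries
#' a terminal element or is the inlet.
#'
#' @param net `vascular_network`.
#' @return `net` invisibly; stops with a message naming the offending
#'   elements otherwise.
#' @export
validate_network <- function(net) {
  seg <- net$segments
  errs <- character(0)
  dup <- seg$id[duplicated(seg$id)]
  if (length(dup) > 0)
    errs <- c(errs, paste0("duplicate segment id(s): ",
                           paste(unique(dup), collapse = ", ")))
  bad_geom <- seg$id[!(seg$length > 0 & seg$radius > 0 &
                         seg$wall_thickness > 0 & seg$wall_stiffness > 0)]
  if (length(bad_geom) > 0)
    errs <- c(errs, paste0("non-positive geometry in segment(s): ",
                           paste(bad_geom, collapse = ", ")))
  bad_class <- seg$id[!seg$vessel_class %in% c("artery", "vein")]
  if (length(bad_class) > 0)
    errs <- c(errs, paste0("vessel_class must be artery/vein in: ",
                           paste(bad_class, collapse = ", ")))
  nodes <- network_nodes(net)
  if (!net$inlet_node %in% nodes)
    errs <- c(errs, paste0("inlet node '", net$inlet_node,
                           "' is not referenced by any segment"))
  if (nrow(net$terminals) > 0) {
    bad_t <- net$terminals$name[!net$terminals$node %in% nodes]
    if (length(bad_t) > 0)
      errs <- c(errs, paste0("terminal(s) reference unknown node: ",
                             paste(bad_t, collapse = ", ")))
    if (any(net$terminals$resistance <= 0))
      errs <- c(errs, "terminal resistances must be > 0")
  }
  if (length(errs) == 0) {
    g <- network_igraph(net)
    if (igraph::components(g)$no != 1)
      errs <- c(errs, "network graph is not connected")
    # leaves on the segment graph (degree 1, ignoring terminals/ground)
    deg <- table(c(seg$proximal_node, seg$distal_node,
                   if (!is.null(net$anastomosis))
                     c(net$anastomosis$arterial_node,
                       net$anastomosis$venous_node)))
    leaves <- names(deg)[deg == 1]
    uncapped <- setdiff(leaves, c(net$inlet_node, net$terminals$node))
    if (length(uncapped) > 0)
      errs <- c(errs, paste0("leaf node(s) without terminal: ",
                             paste(uncapped, collapse = ", ")))
  }
  if (length(errs) > 0)
    stop("invalid vascular network:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(net)
}

#' @export
print.vascular_network <- function(x, ...) {
  cat(sprintf("vascular network: %d segments, %d terminals, inlet '%s'\n",
              nrow(x$segments), nrow(x$terminals), x$inlet_node))
  if (!is.null(x$anastomosis))
    cat(sprintf("  anastomosis: %s, %s <-> %s\n", x$anastomosis$kind,
                x$anastomosis$arterial_node, x$anastomosis$venous_node))
  invisible(x)
}

#' Personalize the generic network to a patient
#'
#' Deterministic scaling of the reference geometry and material properties:
#' * segment lengths multiplied by `height / reference height`;
#' * lumen radii multiplied by `sqrt(BSA / BSA_ref)` (body-size factor) and,
#'   for female patients, by the female reference-diameter factor;
#' * wall stiffness multiplied by `1 + 0.01 (age - 50)` for age above the
#'   reference, and by the hypertension / diabetes factors when flagged;
#' * terminal resistances rescaled so the circuit reproduces the patient's
#'   mean arterial pressure at the patient's cardiac output.
#'
#' Scaling the reference patient is the identity. Topology is untouched.
#'
#' @param network `vascular_network` from [build_generic_network()].
#' @param patient `patient_record`.
#' @param settings `avf_settings`.
#' @return scaled `vascular_network`.
#' @export
scale_to_patient <- function(network, patient, settings = avf_settings()) {
  validate_patient(patient)
  ref <- settings$reference
  len_f <- patient$height / ref$height_cm
  bsa <- body_surface_area(patient$height, patient$weight)
  bsa_ref <- body_surface_area(ref$height_cm, ref$weight_kg)
  dia_f <- sqrt(bsa / bsa_ref) *
    if (patient$sex == "female") ref$female_diameter_factor else 1
  stiff_f <- 1
  if (patient$age > ref$age_years)
    stiff_f <- stiff_f * (1 + ref$age_stiffness_per_year *
                            (patient$age - ref$age_years))
  if (patient$hypertension) stiff_f <- stiff_f * ref$hypertension_stiffness
  if (patient$diabetes) stiff_f <- stiff_f * ref$diabetes_stiffness

  map_ref <- ref$diastolic_mmHg +
    (ref$systolic_mmHg - ref$diastolic_mmHg) / 3
  # terminal R scaled to reproduce measured MAP at the patient's CO; with a
  # common cardiac index, CO_ref / CO = BSA_ref / BSA
  res_f <- (mean_arterial_pressure(patient) / map_ref) * (bsa_ref / bsa)

  net <- network
  net$segments$length <- net$segments$length * len_f
  net$segments$radius <- net$segments$radius * dia_f
  net$segments$wall_stiffness <- net$segments$wall_stiffness * stiff_f
  net$terminals$resistance <- net$terminals$resistance * res_f
  validate_network(net)
  net
}

#' Override scaled diameters with measured DUS diameters
#'
#' Measured lumen diameters replace the scaled generic values at the
#' corresponding named segments (`radius = diameter / 2`); unmeasured
#' segments keep their scaled values. The operation is idempotent.
#'
#' @param network `vascular_network`.
#' @param dus `dus_measurements`.
#' @return `vascular_network` with overridden radii.
#' @export
apply_dus_overrides <- function(network, dus) {
  validate_dus(dus)
  dia <- c(dus$arterial_diameters, dus$venous_diameters)
  if (length(dia) == 0) return(network)
  unknown <- setdiff(names(dia), network$segments$id)
  if (length(unknown) > 0)
    stop("DUS site(s) not present in this network: ",
         paste(unknown, collapse = ", "),
         "\n  valid sites: ",
         paste(intersect(c(DUS_ARTERIAL_SITES, DUS_VENOUS_SITES),
                         network$segments$id), collapse = ", "),
         call. = FALSE)
  idx <- match(names(dia), network$segments$id)
  network$segments$radius[idx] <- as.numeric(dia) / 2
  validate_network(network)
  network
}
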