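# reachability helper independent of the package's igraph usage: breadth
# first search over the segment + anastomosis edge list
reachable_from <- function(net, start, drop_segments = character(0)) {
  seg <- net$segments[!net$segments$id %in% drop_segments, , drop = FALSE]
  edges <- rbind(cbind(seg$proximal_node, seg$distal_node),
                 if (!is.null(net$anastomosis))
                   cbind(net$anastomosis$arterial_node,
                         net$anastomosis$venous_node))
  seen <- start
  repeat {
    nxt <- unique(c(edges[edges[, 1] %in% seen, 2],
                    edges[edges[, 2] %in% seen, 1]))
    new <- setdiff(nxt, seen)
    if (length(new) == 0) return(seen)
    seen <- c(seen, new)
  }
}

scaled_default_network <- function() {
  scale_to_patient(build_generic_network(), default_test_patient())
}

test_that("end-to-side keeps artery and vein patent and ligates the
           peripheral vein limb", {
  net <- scaled_default_network()
  post <- create_avf(net, avf_configuration("radio-cephalic", "end-to-side"))
  expect_true(all(c("radial-artery-distal", "cephalic-vein-wrist") %in%
                    post$segments$id))
  # peripheral venous drainage at the wrist is taken down
  expect_false("hand-venous-bed" %in% post$terminals$name)
  # anastomosis joins the distal radial node to the cephalic origin
  expect_equal(post$anastomosis$arterial_node, "n-wrist-rad")
  expect_equal(post$anastomosis$venous_node, "n-wrist-v")
  expect_error(create_avf(post, avf_configuration("radio-cephalic",
                                                  "end-to-side")),
               "already carries")
})

test_that("radio-cephalic end-to-end disconnects the distal radial limb from
           the anastomosis path but keeps the hand supplied via the palmar
           arch", {
  net <- scaled_default_network()
  post <- create_avf(net, avf_configuration("radio-cephalic", "end-to-end"))
  an <- post$anastomosis$arterial_node
  # inlet-to-anastomosis connectivity must not need the distal radial artery
  expect_true(an %in% reachable_from(post, post$inlet_node,
                                     drop_segments = "radial-artery-distal"))
  # the distal radial segment is NOT on any inlet-to-anastomosis path: with
  # the feeder cut, the anastomosis is unreachable, distal radial or not
  expect_false(an %in% reachable_from(post, post$inlet_node,
                                      drop_segments = c("radial-artery-mid")))
  # ulnar-to-palmar-arch path still reaches the hand terminals
  hand_nodes <- post$terminals$node[grepl("^hand-(radial|ulnar)",
                                          post$terminals$name)]
  reach <- reachable_from(post, post$inlet_node)
  expect_true(all(hand_nodes %in% reach))
})

test_that("side-to-side keeps both limbs of artery and vein", {
  net <- scaled_default_network()
  post <- create_avf(net, avf_configuration("radio-cephalic", "side-to-side"))
  expect_true("hand-venous-bed" %in% post$terminals$name)
  expect_equal(nrow(post$segments), nrow(net$segments))
  expect_equal(post$segments$proximal_node, net$segments$proximal_node)
})

test_that("all six configurations produce valid post-surgical networks", {
  net <- scaled_default_network()
  for (cf in avf_configuration_grid()) {
    post <- create_avf(net, cf)
    expect_silent(validate_network(post))
    expect_false(is.null(post$anastomosis))
    expect_gt(post$anastomosis$linear_coefficient, 0)
    expect_gt(post$anastomosis$quadratic_coefficient, 0)
  }
})

test_that("creating a fistula raises feeding-artery flow", {
  net <- scaled_default_network()
  p <- default_test_patient()
  b <- test_blood()
  s <- quick_settings()
  pre <- solve_periodic(net, b, cardiac_inflow(p), s)
  post <- solve_periodic(create_avf(net, parse_avf_label("rc-se")), b,
                         cardiac_inflow(p), s)
  expect_gt(mean_and_peak_flow(post, "brachial-artery-mid")[["mean"]],
            mean_and_peak_flow(pre, "brachial-artery-mid")[["mean"]])
})

test_that("WSS targets: baseline per segment with class-specific floors,
           or a global constant", {
  net <- scaled_default_network()
  p <- default_test_patient()
  b <- blood_properties(p$hematocrit, p$plasma_protein)
  s <- quick_settings()
  sol <- solve_periodic(net, b, cardiac_inflow(p), s)
  targets <- set_wss_targets(net, sol, s, b)
  expect_setequal(names(targets), net$segments$id[net$segments$adapting])
  i <- match("brachial-artery-mid", net$segments$id)
  tau_brach <- peak_wss(sol, net$segments[i, ], b)
  expect_equal(unname(targets["brachial-artery-mid"]),
               max(tau_brach, s$adaptation$artery_floor_pa))
  # pre-op venous WSS is ~0: the venous floor must apply
  expect_equal(unname(targets["cephalic-vein-wrist"]),
               s$adaptation$vein_floor_pa)
  g <- avf_settings(list(adaptation = list(wss_target_mode = "global-constant",
                                           tau_target = 5)))
  expect_true(all(set_wss_targets(net, sol, g, b) == 5))
})

test_that("the remodeling step follows the multiplicative rate law", {
  net <- single_tube_network()
  net$segments$adapting <- TRUE
  b <- test_blood()
  sol <- solve_periodic(net, b, steady_input(co_lmin = 0.5))
  tau <- peak_wss(sol, net$segments[1, ], b)
  s <- avf_settings(list(adaptation = list(rate_constant = 0.1)))
  # tau_target = tau/2 makes tau/target = 2: radius multiplied by 1 + k dt
  stepped <- adaptation_step(net, sol, c(tube = tau / 2), dt = 1, s, b)
  expect_equal(stepped$segments$radius, net$segments$radius * 1.1)
  # fixed point: at target, nothing moves
  fixed <- adaptation_step(net, sol, c(tube = tau), dt = 1, s, b)
  expect_equal(fixed$segments$radius, net$segments$radius)
})

test_that("iterated remodeling converges to the analytic equilibrium of the
           two-resistor circuit and approaches it monotonically", {
  b <- test_blood()
  net <- adaptation_toy_network(adapt_radius_mm = 2)
  s <- avf_settings(list(solver = list(min_cycles = 2)))
  tau_target <- 5
  oracle <- toy_equilibrium_oracle(net, b, co_lmin = 1, tau_target)
  inp <- steady_input(co_lmin = 1)
  gaps <- numeric(0)
  for (day in 1:40) {
    sol <- solve_periodic(net, b, inp, s)
    i <- match("access", net$segments$id)
    gaps <- c(gaps, abs(peak_wss(sol, net$segments[i, ], b) - tau_target))
    net <- adaptation_step(net, sol, c(access = tau_target), dt = 1, s, b)
  }
  sol <- solve_periodic(net, b, inp, s)
  expect_equal(net$segments$radius[match("access", net$segments$id)],
               oracle$radius_mm, tolerance = 0.01)
  expect_equal(mean_and_peak_flow(sol, "access")[["mean"]],
               oracle$flow_mlmin, tolerance = 0.01)
  expect_true(all(diff(gaps) <= 1e-9))
})

test_that("frozen remodeling (k = 0) keeps diameters and BFV constant", {
  s <- quick_settings()
  s$adaptation$rate_constant <- 1e-12  # rate_constant invariant requires > 0
  m <- simulate_maturation(default_test_patient(), dus_measurements(),
                           parse_avf_label("rc-se"), s)
  # diameters are bitwise constant; BFV constant up to the periodicity
  # tolerance carried between warm-started daily solves
  expect_equal(max(abs(diff(m$diameters$cephalic))), 0)
  expect_equal(max(abs(diff(m$diameters$brachial))), 0)
  expect_lt(max(abs(diff(m$bfv$brachial))) / mean(m$bfv$brachial), 1e-4)
})

test_that("maturation raises BFV: day 40 > day 0 > pre-op, and the series
           covers the full day grid", {
  s <- quick_settings()
  m <- simulate_maturation(default_test_patient(), dus_measurements(),
                           parse_avf_label("rc-se"), s)
  nd <- length(m$days)
  expect_equal(m$days[1], 0)
  expect_equal(m$days[nd], 40)
  expect_gt(m$bfv$brachial[nd], m$bfv$brachial[1])
  expect_gt(m$bfv$brachial[1], m$preop$bfv$brachial)
  expect_true(all(is.finite(unlist(m$bfv))))
  expect_true(all(unlist(m$diameters) > 0))
})

test_that("a maturation run restarted from its own equilibrium is a fixed
           point", {
  s <- quick_settings()
  p <- default_test_patient()
  b <- blood_properties(p$hematocrit, p$plasma_protein)
  m <- simulate_maturation(p, dus_measurements(), parse_avf_label("rc-se"), s)
  net <- m$final_network
  inp <- cardiac_inflow(p, s$cardiac$cardiac_index, s)
  sol <- solve_periodic(net, b, inp, s)
  stepped <- adaptation_step(net, sol, m$wss_targets, dt = 1, s, b)
  rel <- abs(stepped$segments$radius / net$segments$radius - 1)
  expect_lt(max(rel), s$adaptation$convergence_tol)
})
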