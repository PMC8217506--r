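# unit conversions at the solver boundary: interfaces are um / ms / kPa,
# the core integrates in SI (m / s / Pa)
UM <- 1e-6
MS <- 1e-3
KPA <- 1e3

#' Couple beam nodes to their host hexahedra
#'
#' Solves the inverse isoparametric mapping (Newton iteration) for every
#' beam node, returning the host element and trilinear natural coordinates;
#' ties at element boundaries go to the lower element id. The round-trip
#' reconstruction residual is checked against 1e-9 um.
#'
#' @param mesh a `hex_mesh`.
#' @param beams a `beam_mesh`.
#' @return object of class `coupling_map`: data.frame with `elem`, `xi1`,
#'   `xi2`, `xi3`, `residual` (um), one row per beam node.
#' @export
build_coupling <- function(mesh, beams) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(beams, "beam_mesh"))
  pts <- as.matrix(beams$nodes[, c("x", "y", "z")])
  loc <- cpp_locate_points(mesh$nodes, mesh$elements, pts)
  miss <- which(loc$elem == 0L)
  if (length(miss) > 0) {
    stop("beam node(s) outside the tissue mesh (or Newton non-convergence): ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  }
  bad <- which(loc$residual > 1e-9)
  if (length(bad) > 0) {
    stop("coupling round-trip residual exceeds 1e-9 um for node(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out <- data.frame(elem = loc$elem, xi1 = loc$xi[, 1], xi2 = loc$xi[, 2],
                    xi3 = loc$xi[, 3], residual = loc$residual)
  class(out) <- c("coupling_map", "data.frame")
  out
}

dilatational_wave_speed <- function(tissue) {
  mu_inst <- tissue$mu0 + if (nrow(tissue$prony) > 0) sum(tissue$prony$G) else 0
  sqrt((tissue$bulk_modulus + 4 / 3 * mu_inst) * KPA / tissue$density)  # m/s
}

hex_min_edge <- function(mesh) {
  pairs <- cbind(c(1, 2, 3, 4, 5, 6, 7, 8, 1, 2, 3, 4),
                 c(2, 3, 4, 1, 6, 7, 8, 5, 5, 6, 7, 8))
  mins <- rep(Inf, nrow(mesh$elements))
  for (p in seq_len(nrow(pairs))) {
    a <- mesh$elements[, pairs[p, 1]]
    b <- mesh$elements[, pairs[p, 2]]
    d <- sqrt(rowSums((mesh$nodes[a, , drop = FALSE] -
                         mesh$nodes[b, , drop = FALSE])^2))
    mins <- pmin(mins, d)
  }
  mins
}

#' Stable explicit time step (CFL)
#'
#' dt = safety x min over elements of characteristic length / dilatational
#' wave speed. Beams are included through the frequency they add to their
#' host nodes: beam nodes are slaved to the solid, so a beam of stiffness
#' EA/L loads the host-node mass rather than its own (negligible) lumped
#' mass, giving dt_beam = 2 sqrt(m_host / (2 EA/L)).
#' @param mesh a `hex_mesh`.
#' @param beams optional `beam_mesh`.
#' @param tissue an `ogden_prony_material`.
#' @param vessel a `vessel_material` (required when `beams` given).
#' @param safety CFL safety factor, default 0.9.
#' @return time step in ms.
#' @export
stable_timestep <- function(mesh, beams = NULL, tissue = brain_material(),
                            vessel = vessel_material(), safety = 0.9) {
  if (tissue$density <= 0) stop("zero or negative density")
  c_t <- dilatational_wave_speed(tissue)
  hmin <- min(hex_min_edge(mesh)) * UM
  dt <- hmin / c_t
  if (!is.null(beams) && nrow(beams$elements) > 0) {
    m_host <- tissue$density * hmin^3 / 8
    ra <- beams$nodes$radius[beams$elements$node_a] * UM
    rb <- beams$nodes$radius[beams$elements$node_b] * UM
    area <- pi * (ra^2 + ra * rb + rb^2) / 3
    k <- vessel$elastic_modulus * KPA * area / (beam_lengths(beams) * UM)
    dt <- min(dt, 2 * sqrt(m_host / (2 * max(k))))
  }
  safety * dt / MS
}

#' Solver controls
#'
#' @param output_interval history sampling interval, ms (default 0.01).
#' @param safety CFL safety factor.
#' @param hourglass viscous hourglass coefficient (default 0.05).
#' @param hourglass_stiffness stiffness hourglass coefficient (default
#'   0.05); gives zero-energy modes a restoring force.
#' @param damping mass-proportional damping coefficient, 1/ms (0 = none;
#'   used for quasi-static submodel settling).
#' @param penalty_scale contact penalty stiffness as a fraction of
#'   K x element size.
#' @param t_end simulated time, ms; defaults to the scenario schedule.
#' @param prescribed optional prescribed-motion set: list with `nodes`
#'   (indices or "all"), `times` (ms waypoints) and `positions`
#'   (waypoints x nodes x 3 array, um); see [affine_motion()].
#' @param fixed_base clamp the bottom (min z) node layer.
#' @param fixed_sides clamp the four lateral faces too (skull-like
#'   confinement of the tissue block).
#' @param v_init optional n x 3 initial nodal velocity, um/ms.
#' @param dt explicit time step override, ms.
#' @param bulk_q1,bulk_q2 linear/quadratic shock bulk viscosity
#'   coefficients (compression only).
#' @param tip_fillet impactor rim edge radius, um; defaults to one element
#'   edge (flat tips have finite edge radii; also regularizes the edge
#'   shear on coarse meshes).
#' @param contact_damping viscous contact damping as a fraction of critical
#'   (suppresses penalty-spring rebound chatter).
#' @param record_energy track the kinetic/internal/external-work ledger.
#' @return list of class `solver_controls`.
#' @export
solver_controls <- function(output_interval = 0.01, safety = 0.9,
                            hourglass = 0.05, hourglass_stiffness = 0.05,
                            damping = 0,
                            penalty_scale = 0.05, t_end = NULL,
                            prescribed = NULL, fixed_base = NULL,
                            fixed_sides = FALSE,
                            v_init = NULL, dt = NULL,
                            bulk_q1 = 0.06, bulk_q2 = 1.5,
                            tip_fillet = NULL, contact_damping = 0.2,
                            record_energy = TRUE) {
  structure(as.list(environment()), class = "solver_controls")
}

#' Prescribed affine motion of a node set
#'
#' Builds a prescribed-motion waypoint table driving nodes along
#' x(t) = X + s(t) (F - I) X, with s a smoothstep (zero start/end velocity)
#' or linear ramp — the homogeneous-deformation loading used for embedded
#' fibre validation and for hydrostatic/shear mechanism studies.
#'
#' @param mesh a `hex_mesh`.
#' @param F_end 3x3 target deformation gradient.
#' @param t_end ramp duration, ms.
#' @param nodes node indices or "all".
#' @param n_waypoints waypoint count (linear interpolation between them).
#' @param ramp "smoothstep" or "linear".
#' @param hold extra hold time at F_end, ms.
#' @return prescribed-motion list for [solver_controls()].
#' @export
affine_motion <- function(mesh, F_end, t_end, nodes = "all",
                          n_waypoints = 41, ramp = c("smoothstep", "linear"),
                          hold = 0) {
  ramp <- match.arg(ramp)
  idx <- if (identical(nodes, "all")) seq_len(nrow(mesh$nodes)) else
    as.integer(nodes)
  X <- mesh$nodes[idx, , drop = FALSE]
  times <- seq(0, t_end, length.out = n_waypoints)
  s <- times / t_end
  if (ramp == "smoothstep") s <- s * s * (3 - 2 * s)
  if (hold > 0) {
    times <- c(times, t_end + hold)
    s <- c(s, 1)
  }
  A <- F_end - diag(3)
  pos <- array(0, c(length(times), length(idx), 3))
  U <- X %*% t(A)
  for (w in seq_along(times)) {
    pos[w, , ] <- X + s[w] * U
  }
  list(nodes = idx, times = times, positions = pos)
}

#' Run the explicit macroscale simulation
#'
#' Central-difference dynamics of the tissue block with embedded vessel
#' beams: one-point hexahedra with viscous hourglass control, truss beams
#' slaved to their host elements (forces distributed back with the
#' transposed trilinear weights), optional rigid flat-tipped impactor by
#' penalty contact, optional prescribed motion, history sampled every
#' `output_interval` ms (first frame = undeformed reference, zero stress).
#'
#' @param mesh a `hex_mesh`.
#' @param beams optional `beam_mesh`.
#' @param tissue an `ogden_prony_material`.
#' @param vessel a `vessel_material`.
#' @param scenario optional [cci_scenario()]; when given, the impactor
#'   contacts the top (max z) surface, centred in x/y.
#' @param controls a [solver_controls()] list.
#' @param coupling optional precomputed [build_coupling()] map.
#' @return object of class `sim_history` with `times` (ms), `positions`
#'   (frames x nodes x 3, um), `stress`/`strain` (frames x elements x 6
#'   Voigt, kPa / Green-Lagrange), `beam_stress` (frames x beams, kPa),
#'   `beam_dir` (frames x beams x 3 unit vectors), `energy` (J), plus the
#'   input geometry.
#' @export
run_macro <- function(mesh, beams = NULL, tissue = brain_material(),
                      vessel = vessel_material(), scenario = NULL,
                      controls = solver_controls(), coupling = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  ctl <- controls
  have_beams <- !is.null(beams) && nrow(beams$elements) > 0
  if (have_beams && is.null(coupling)) coupling <- build_coupling(mesh, beams)

  t_end <- ctl$t_end %||% (if (!is.null(scenario)) scenario$total_sim_time
                           else stop("t_end or a scenario is required"))
  # the CFL estimate is 1D; the worst discrete mode of the one-point hex
  # stack oscillates at sqrt(6) c / h, so scale by sqrt(2/3)
  dt <- ctl$dt %||% (sqrt(2 / 3) *
                       stable_timestep(mesh, beams, tissue, vessel,
                                       ctl$safety))
  # make the step divide the output interval so frames land exactly
  dt <- ctl$output_interval / ceiling(ctl$output_interval / dt)

  zr <- range(mesh$nodes[, 3])
  contact <- list(on = FALSE)
  if (!is.null(scenario) && is.null(ctl$prescribed)) {
    if (scenario$impact_depth > diff(zr)) {
      stop("impact depth exceeds the block height")
    }
    contact <- list(on = TRUE,
                    cx = mean(range(mesh$nodes[, 1])) * UM,
                    cy = mean(range(mesh$nodes[, 2])) * UM,
                    R = scenario$impactor_radius * UM,
                    z0 = zr[2] * UM,
                    v = scenario$impact_velocity * UM / MS,
                    depth = scenario$impact_depth * UM,
                    dwell = scenario$dwell_time * MS,
                    retract = isTRUE(scenario$retract),
                    k = ctl$penalty_scale * tissue$bulk_modulus * KPA *
                      min(mesh$element_size) * UM,
                    fillet = (ctl$tip_fillet %||% min(mesh$element_size)) *
                      UM,
                    xi = ctl$contact_damping %||% 0.2)
    if (scenario$impact_depth == 0) contact$on <- FALSE
  }

  fixed_base <- ctl$fixed_base %||% contact$on
  fixed_idx <- if (isTRUE(fixed_base)) {
    which(mesh$nodes[, 3] < zr[1] + 1e-9 * max(1, diff(zr)))
  } else integer(0)
  if (isTRUE(ctl$fixed_sides)) {
    xr <- range(mesh$nodes[, 1])
    yr <- range(mesh$nodes[, 2])
    tolxy <- 1e-9 * max(1, diff(xr), diff(yr))
    fixed_idx <- union(fixed_idx,
                       which(mesh$nodes[, 1] < xr[1] + tolxy |
                             mesh$nodes[, 1] > xr[2] - tolxy |
                             mesh$nodes[, 2] < yr[1] + tolxy |
                             mesh$nodes[, 2] > yr[2] - tolxy))
  }

  if (!is.null(ctl$prescribed)) {
    pr <- ctl$prescribed
    presc_idx <- as.integer(pr$nodes)
    presc_times <- pr$times * MS
    presc_pos <- pr$positions * UM
    fixed_idx <- setdiff(fixed_idx, presc_idx)
  } else {
    presc_idx <- integer(0)
    presc_times <- c(0, t_end * MS)
    presc_pos <- array(0, c(2, 0, 3))
  }

  if (have_beams) {
    ra <- beams$nodes$radius[beams$elements$node_a] * UM
    rb <- beams$nodes$radius[beams$elements$node_b] * UM
    beam_area <- pi * (ra^2 + ra * rb + rb^2) / 3  # frustum-mean section
    beam_conn <- as.matrix(beams$elements[, c("node_a", "node_b")])
    bn_elem <- coupling$elem
    bn_xi <- as.matrix(coupling[, c("xi1", "xi2", "xi3")])
  } else {
    beam_area <- numeric(0)
    beam_conn <- matrix(0L, 0, 2)
    bn_elem <- integer(0)
    bn_xi <- matrix(0, 0, 3)
  }

  v_init <- if (is.null(ctl$v_init)) matrix(0, 0, 3) else
    as.matrix(ctl$v_init) * UM / MS

  res <- cpp_run_solver(
    mesh$nodes * UM, mesh$elements,
    tissue$ogden$mu * KPA, tissue$ogden$alpha,
    if (nrow(tissue$prony) > 0) tissue$prony$G * KPA else numeric(0),
    if (nrow(tissue$prony) > 0) tissue$prony$tau * MS else numeric(0),
    tissue$density, tissue$bulk_modulus * KPA,
    beam_conn, beam_area, vessel$elastic_modulus * KPA, vessel$density,
    bn_elem, bn_xi,
    as.integer(fixed_idx),
    presc_idx, presc_times, presc_pos,
    contact,
    dt * MS, t_end * MS, ctl$output_interval * MS,
    ctl$hourglass, ctl$hourglass_stiffness %||% 0.05, ctl$damping / MS,
    isTRUE(ctl$record_energy), v_init,
    ctl$bulk_q1 %||% 0.06, ctl$bulk_q2 %||% 1.5)

  structure(list(times = as.numeric(res$times) / MS,
                 positions = res$pos / UM,
                 stress = res$stress / KPA,
                 strain = res$strain,
                 beam_stress = res$beam_stress / KPA,
                 beam_dir = res$beam_dir,
                 energy = data.frame(time = as.numeric(res$times) / MS,
                                     kinetic = res$energy[, 1],
                                     internal = res$energy[, 2],
                                     external_work = res$energy[, 3]),
                 dt = dt, mesh = mesh, beams = beams, coupling = coupling,
                 scenario = scenario),
            class = "sim_history")
}

#' @export
print.sim_history <- function(x, ...) {
  cat(sprintf(paste0("<sim_history> %d frames over %g ms (dt %.3g ms), ",
                     "%d hexahedra, %d beams\n"),
              length(x$times), max(x$times), x$dt,
              dim(x$stress)[2], if (length(dim(x$beam_stress)) > 1)
                dim(x$beam_stress)[2] else 0L))
  invisible(x)
}

#' Run a refined submodel driven by a parent solution
#'
#' Boundary node displacements are interpolated from the parent history —
#' trilinear in space through the stored parent natural coordinates, linear
#' in time between parent output frames — and prescribed; the interior is
#' integrated as in [run_macro()] without contact.
#'
#' @param sub a bundle from [extract_submodel()].
#' @param parent_history the parent `sim_history`.
#' @param tissue,vessel materials (defaults as in [run_macro()]).
#' @param controls a [solver_controls()]; `t_end` defaults to the parent
#'   window and must not exceed it.
#' @return a `sim_history` for the submodel.
#' @export
run_submodel <- function(sub, parent_history, tissue = brain_material(),
                         vessel = vessel_material(),
                         controls = solver_controls()) {
  stopifnot(!is.null(sub$boundary), inherits(parent_history, "sim_history"))
  ctl <- controls
  pt <- parent_history$times
  t_end <- ctl$t_end %||% max(pt)
  if (t_end > max(pt) + 1e-9) {
    stop("submodel window (", t_end, " ms) exceeds the parent history (",
         max(pt), " ms)")
  }
  keep <- which(pt <= t_end + 1e-9)
  pmesh <- parent_history$mesh
  bnd <- sub$boundary
  np <- nrow(bnd)
  pos <- array(0, c(length(keep), np, 3))
  for (b in seq_len(np)) {
    conn <- pmesh$elements[bnd$parent_element[b], ]
    w <- hex_shape(c(bnd$xi1[b], bnd$xi2[b], bnd$xi3[b]))
    for (k in 1:3) {
      pos[, b, k] <- matrix(parent_history$positions[keep, conn, k],
                            ncol = 8) %*% w
    }
  }
  ctl$prescribed <- list(nodes = bnd$node, times = pt[keep], positions = pos)
  ctl$t_end <- t_end
  ctl$fixed_base <- FALSE
  run_macro(sub$mesh, sub$beams, tissue, vessel, scenario = NULL,
            controls = ctl)
}
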