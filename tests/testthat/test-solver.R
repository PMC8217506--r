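test_that("inverse isoparametric location recovers natural coordinates", {
  m <- block_mesh(2, 100)
  beams <- beam_mesh(data.frame(x = c(50, 100), y = c(50, 100),
                                z = c(50, 100), radius = 5),
                     data.frame(node_a = 1, node_b = 2,
                                source_segment = 1))
  cpl <- build_coupling(m, beams)
  # centroid of the first element -> (0,0,0)
  expect_equal(as.numeric(cpl[1, c("xi1", "xi2", "xi3")]), c(0, 0, 0),
               tolerance = 1e-9)
  # a shared corner: natural coords +-1, tie broken to the lowest element id
  expect_equal(abs(as.numeric(cpl[2, c("xi1", "xi2", "xi3")])), c(1, 1, 1),
               tolerance = 1e-9)
  expect_equal(cpl$elem[2], min(cpl$elem))
  expect_error(build_coupling(m, beam_mesh(
    data.frame(x = c(50, 500), y = 50, z = 50, radius = 5),
    data.frame(node_a = 1, node_b = 2, source_segment = 1))), "outside")
})

test_that("round-trip location works in a distorted hex", {
  set.seed(42)
  base <- block_mesh(1, 100)
  distorted <- base
  distorted$nodes <- base$nodes + matrix(runif(24, -15, 15), 8, 3)
  Xe <- distorted$nodes[distorted$elements[1, ], ]
  # random interior points built from random natural coordinates
  xi <- matrix(runif(300, -0.95, 0.95), 100, 3)
  pts <- t(apply(xi, 1, function(x) {
    crossprod(vascufem:::hex_shape(x), Xe)
  }))
  loc <- cpp_locate_points(distorted$nodes, distorted$elements, pts)
  expect_true(all(loc$elem == 1))
  rebuilt <- t(vapply(seq_len(100), function(i) {
    as.numeric(crossprod(vascufem:::hex_shape(loc$xi[i, ]), Xe))
  }, numeric(3)))
  expect_lt(max(abs(rebuilt - pts)), 1e-9)
})

test_that("stable timestep follows the CFL scaling", {
  mat <- brain_material()
  m1 <- block_mesh(1, 100)
  c_d <- vascufem:::dilatational_wave_speed(mat)
  expect_equal(stable_timestep(m1, tissue = mat),
               0.9 * 100e-6 / c_d / 1e-3, tolerance = 1e-12)
  m2 <- block_mesh(1, 50)
  expect_equal(stable_timestep(m2, tissue = mat),
               stable_timestep(m1, tissue = mat) / 2, tolerance = 1e-12)
  # brute-force min over elements of an anisotropic mesh
  mask <- array(TRUE, c(2, 1, 1))
  attr(mask, "spacing") <- c(30, 80, 80)
  m3 <- voxelize(mask, c(30, 80, 80))
  expect_equal(stable_timestep(m3, tissue = mat),
               0.9 * 30e-6 / c_d / 1e-3, tolerance = 1e-12)
  mat0 <- mat
  mat0$density <- 0
  expect_error(stable_timestep(m1, tissue = mat0), "density")
})

test_that("zero-depth scenario and rigid translation produce zero stress", {
  m <- block_mesh(3, 100)
  h0 <- run_macro(m, NULL, scenario = cci_scenario(impact_depth = 0,
                                                   total_sim_time = 0.1),
                  controls = solver_controls(t_end = 0.1))
  expect_lt(max(abs(h0$stress)), 1e-9)

  dirs <- random_unit_rows(3)
  beams <- oriented_beams(dirs, centre = c(150, 150, 150))
  shift <- affine_motion(m, diag(3), 0.2)
  offs <- seq(0, 40, length.out = dim(shift$positions)[1])
  for (w in seq_along(offs)) {
    shift$positions[w, , ] <- shift$positions[w, , ] + offs[w]
  }
  h1 <- run_macro(m, beams, scenario = NULL,
                  controls = solver_controls(t_end = 0.2,
                                             prescribed = shift,
                                             fixed_base = FALSE))
  expect_lt(max(abs(h1$stress)), 1e-6)
  expect_lt(max(abs(h1$beam_stress)), 1e-6)
})

test_that("embedded beams follow homogeneous-stretch kinematics", {
  set.seed(5)
  m <- block_mesh(3, 100)
  dirs <- random_unit_rows(8)
  beams <- oriented_beams(dirs, centre = c(150, 150, 150), half_len = 40)
  Fend <- diag(c(1.08, 0.97, 1 / (1.08 * 0.97)))
  h <- run_macro(m, beams, scenario = NULL,
                 controls = solver_controls(
                   t_end = 0.5, prescribed = affine_motion(m, Fend, 0.5),
                   fixed_base = FALSE))
  nf <- length(h$times)
  lam <- sqrt(rowSums((dirs %*% t(Fend))^2))
  expected <- vessel_material()$elastic_modulus * (lam - 1)
  expect_equal(as.numeric(h$beam_stress[nf, ]), expected,
               tolerance = 0.01 * max(abs(expected)))
  # current directions rotate with F
  dnew <- dirs %*% t(Fend)
  dnew <- dnew / sqrt(rowSums(dnew^2))
  got <- matrix(h$beam_dir[nf, , ], length(lam), 3)
  expect_lt(max(abs(abs(rowSums(got * dnew)) - 1)), 1e-6)
})

test_that("momentum is conserved for a free block (beams included)", {
  set.seed(6)
  m <- block_mesh(3, 100)
  beams <- oriented_beams(random_unit_rows(4), centre = c(150, 150, 150))
  v0 <- matrix(rep(c(30, -20, 10), each = nrow(m$nodes)), ncol = 3)
  h <- run_macro(m, beams, scenario = NULL,
                 controls = solver_controls(t_end = 0.3, v_init = v0,
                                            fixed_base = FALSE,
                                            hourglass = 0.05))
  nf <- length(h$times)
  # total momentum from consecutive frames (lumped masses all equal here)
  p_first <- colSums(h$positions[2, , ] - h$positions[1, , ])
  p_last <- colSums(h$positions[nf, , ] - h$positions[nf - 1, , ])
  expect_equal(p_last, p_first, tolerance = 1e-6 * max(abs(p_first)))
})

test_that("energy ledger balances for an impact run", {
  m <- block_mesh(4, 100)
  scen <- cci_scenario(impact_depth = 80, impact_velocity = 1000,
                       impactor_radius = 180, dwell_time = 0.05,
                       retract = FALSE)
  h <- run_macro(m, NULL, scenario = scen,
                 controls = solver_controls(t_end = 0.2))
  e <- h$energy
  drift <- abs(e$kinetic + e$internal - e$external_work)
  expect_lt(max(drift) / max(e$external_work), 0.02)
  expect_gt(max(abs(h$stress)), 0.1)  # the impact actually loaded the block
})

test_that("first history frame is the undeformed zero-stress reference", {
  m <- block_mesh(2, 100)
  h <- run_macro(m, NULL, scenario = cci_scenario(impact_depth = 50,
                                                  impactor_radius = 120,
                                                  retract = FALSE),
                 controls = solver_controls(t_end = 0.05))
  expect_equal(h$times[1], 0)
  expect_equal(matrix(h$positions[1, , ], nrow(m$nodes), 3), m$nodes,
               ignore_attr = TRUE)
  expect_true(all(h$stress[1, , ] == 0))
  expect_true(all(diff(h$times) > 0))
})

test_that("submodel patch tests reproduce affine parent fields", {
  m <- block_mesh(5, 100)
  # kinematic patch property: hyperelastic tissue, ramp then a quasi-static
  # settle under light mass damping
  hyper <- ogden_prony_material(prony = data.frame(G = numeric(0),
                                                   tau = numeric(0)))
  Fend <- matrix(c(1.002, 0.001, 0,
                   0, 0.999, 0,
                   0, 0.0005, 1.0015), 3, 3, byrow = TRUE)
  h <- run_macro(m, NULL, tissue = hyper, scenario = NULL,
                 controls = solver_controls(
                   t_end = 4,
                   prescribed = affine_motion(m, Fend, 0.6, hold = 3.4),
                   fixed_base = FALSE))
  mean_stress <- numeric(2)
  for (refn in 1:2) {
    sub <- extract_submodel(m, NULL,
                            submodel_spec(c(100, 100, 100),
                                          c(400, 400, 400), refn,
                                          allow_small = TRUE))
    hs <- run_submodel(sub, h, tissue = hyper,
                       controls = solver_controls(t_end = 4,
                                                  damping = 1.5))
    nf <- dim(hs$positions)[1]
    err <- hs$positions[nf, , ] - sub$mesh$nodes %*% t(Fend)
    expect_lt(max(abs(err)), 1e-6)
    mean_stress[refn] <- mean(hs$stress[nf, , 1])
  }
  # refining does not move the volume-averaged interior stress
  expect_equal(mean_stress[2], mean_stress[1],
               tolerance = 0.01 * max(abs(mean_stress[1]), 1e-6))
  # frozen parent -> zero response
  h0 <- run_macro(m, NULL, scenario = NULL,
                  controls = solver_controls(
                    t_end = 0.2,
                    prescribed = affine_motion(m, diag(3), 0.2),
                    fixed_base = FALSE))
  sub <- extract_submodel(m, NULL, submodel_spec(c(100, 100, 100),
                                                 c(300, 300, 300), 1,
                                                 allow_small = TRUE))
  hs0 <- run_submodel(sub, h0, controls = solver_controls(t_end = 0.2))
  expect_lt(max(abs(hs0$positions[dim(hs0$positions)[1], , ] -
                      sub$mesh$nodes)), 1e-9)
  expect_error(run_submodel(sub, h0,
                            controls = solver_controls(t_end = 5)),
               "exceeds")
})

test_that("rotating the prescribed deformation rotates the Cauchy stress", {
  set.seed(9)
  m <- block_mesh(2, 100)
  Fbase <- diag(c(1.06, 0.98, 1 / (1.06 * 0.98)))
  R <- random_rotation()
  pr1 <- affine_motion(m, Fbase, 0.4)
  # the superposed-rigid-motion path: every waypoint rotated by R, so the
  # two runs share the same strain history in rotated frames
  pr2 <- pr1
  for (w in seq_along(pr1$times)) {
    pr2$positions[w, , ] <- pr1$positions[w, , ] %*% t(R)
  }
  vec6_to_sym <- function(v) matrix(c(v[1], v[4], v[6], v[4], v[2],
                                      v[5], v[6], v[5], v[3]), 3, 3)
  run_with <- function(pr) {
    h <- run_macro(m, NULL, scenario = NULL,
                   controls = solver_controls(t_end = 0.4, prescribed = pr,
                                              fixed_base = FALSE))
    vec6_to_sym(h$stress[length(h$times), 1, ])
  }
  s1 <- run_with(pr1)
  s2 <- run_with(pr2)
  expect_equal(s2, R %*% s1 %*% t(R), tolerance = 1e-6 * max(abs(s1)))
})
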