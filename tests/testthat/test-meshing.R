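test_that("segment_image equals the voxelwise comparison", {
  set.seed(21)
  arr <- array(runif(6^3, 0, 255), c(6, 6, 6))
  img <- voxel_image(arr, 10)
  mask <- segment_image(img, 120)
  expect_identical(as.vector(mask), as.vector(arr >= 120))
  expect_true(all(segment_image(voxel_image(array(200, c(2, 2, 2)), 1), 100)))
  expect_false(any(segment_image(img, 300)))
})

test_that("voxelize counts elements and nodes on lattices", {
  mask <- array(TRUE, c(2, 2, 2))
  m <- voxelize(mask, 10)
  expect_equal(nrow(m$elements), 8)
  expect_equal(nrow(m$nodes), 27)
  # coarsening 4^3 by 2 -> 8 elements of doubled size
  mask4 <- array(TRUE, c(4, 4, 4))
  m2 <- voxelize(mask4, 10, coarsen = 2)
  expect_equal(nrow(m2$elements), 8)
  expect_equal(m2$element_size, rep(20, 3))
  expect_error(voxelize(array(FALSE, c(3, 3, 3)), 10), "empty")
})

test_that("voxelize matches brute-force counting on random masks", {
  set.seed(31)
  mask <- array(runif(8^3) > 0.5, c(8, 8, 8))
  m <- voxelize(mask, 5)
  expect_equal(nrow(m$elements), sum(mask))
  # brute-force unique corner count
  corners <- new.env(hash = TRUE)
  idx <- which(mask, arr.ind = TRUE) - 1L
  for (r in seq_len(nrow(idx))) {
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      key <- paste(idx[r, 1] + di, idx[r, 2] + dj, idx[r, 3] + dk)
      assign(key, TRUE, envir = corners)
    }
  }
  expect_equal(nrow(m$nodes), length(ls(corners)))
  expect_true(all(hex_jacobians(m) > 0))
})

test_that("voxelized volume of a ball converges monotonically with spacing", {
  r <- 200
  errs <- vapply(c(40, 20, 10), function(sp) {
    img <- generate_tissue_image(rep(2 * r + 4 * sp, 3), spacing = sp,
                                 shape = "sphere", sphere_radius = r,
                                 noise_sd = 0)
    m <- voxelize(segment_image(img, 100), sp)
    abs(sum(hex_volumes(m)) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.02)
})

test_that("surface smoothing is identity at 0 iterations and shape-restricted", {
  m <- block_mesh(3, 50)
  expect_identical(smooth_outer_surface(m, iterations = 0), m)
  sm <- smooth_outer_surface(m, iterations = 3, strength = 0.4)
  # connectivity untouched, volume nearly preserved, Jacobians positive
  expect_identical(sm$elements, m$elements)
  expect_lt(abs(sum(hex_volumes(sm)) - sum(hex_volumes(m))) /
              sum(hex_volumes(m)), 0.05)
  expect_true(all(hex_jacobians(sm) > 0))
  # interior nodes did not move
  quads <- vascufem:::boundary_quads(m)
  interior <- setdiff(seq_len(nrow(m$nodes)), unique(as.vector(quads)))
  expect_equal(sm$nodes[interior, ], m$nodes[interior, ])
})

test_that("smoothing reduces surface roughness of a staircase shape", {
  sp <- 25
  r <- 8 * sp
  img <- generate_tissue_image(rep(2 * r + 4 * sp, 3), spacing = sp,
                               shape = "sphere", sphere_radius = r,
                               noise_sd = 0)
  m <- voxelize(segment_image(img, 100), sp)
  roughness <- function(mesh) {
    quads <- vascufem:::boundary_quads(mesh)
    bn <- sort(unique(as.vector(quads)))
    ctr <- colMeans(mesh$nodes[bn, ])
    radii <- sqrt(rowSums(sweep(mesh$nodes[bn, ], 2, ctr)^2))
    var(radii)
  }
  r0 <- roughness(m)
  r1 <- roughness(smooth_outer_surface(m, iterations = 4, strength = 0.5))
  expect_lt(r1, r0)
})

test_that("discretize_network splits beams and interpolates radii linearly", {
  net <- structure(list(
    nodes = data.frame(x = c(0, 100), y = 0, z = 0, radius = c(5, 10)),
    segments = data.frame(node_a = 1, node_b = 2),
    metadata = list(domain_size = c(100, 100, 100))),
    class = "vessel_network")
  b1 <- discretize_network(net, 100)
  expect_equal(nrow(b1$elements), 1)
  b4 <- discretize_network(net, 25)
  expect_equal(nrow(b4$elements), 4)
  interior <- sort(setdiff(unique(c(b4$elements$node_a, b4$elements$node_b)),
                           1:2))
  expect_equal(sort(b4$nodes$radius[interior]), c(6.25, 7.5, 8.75))
})

test_that("beam discretization conserves length and frustum volume", {
  net <- generate_network(c(600, 600, 600), seed = 13)
  seg_len <- sum(vascufem:::segment_lengths(net))
  seg_vol <- sum(vascufem:::segment_volumes(net))
  for (ml in c(15, 40, 500)) {
    beams <- discretize_network(net, ml)
    expect_equal(sum(vascufem:::beam_lengths(beams)), seg_len,
                 tolerance = 1e-9)
    expect_equal(sum(vascufem:::beam_volumes(beams)), seg_vol,
                 tolerance = 1e-6)
  }
})

test_that("submodel extraction refines elements and clips beams exactly", {
  m <- block_mesh(4, 48)
  # refinement 1 returns the parent elements inside the box
  s1 <- extract_submodel(m, NULL, submodel_spec(c(48, 48, 48),
                                                c(144, 144, 144), 1,
                                                allow_small = TRUE))
  expect_equal(nrow(s1$mesh$elements), 8)
  expect_equal(sort(unique(round(s1$mesh$element_size))), 48)
  # one 48 um element split in two -> 8 elements of 24 um
  m1 <- block_mesh(1, 48)
  s2 <- extract_submodel(m1, NULL, submodel_spec(c(0, 0, 0), c(48, 48, 48),
                                                 2, allow_small = TRUE))
  expect_equal(nrow(s2$mesh$elements), 8)
  expect_equal(s2$mesh$element_size, rep(24, 3))
  # warning when refined size drops under the 20 um floor
  expect_warning(extract_submodel(m1, NULL,
                                  submodel_spec(c(0, 0, 0), c(48, 48, 48),
                                                4)),
                 "20 um")

  # beam crossing a box face: endpoint on the face, radius interpolated
  beams <- beam_mesh(data.frame(x = c(24, 120), y = c(50, 90),
                                z = c(60, 100), radius = c(6, 12)),
                     data.frame(node_a = 1, node_b = 2,
                                source_segment = 1))
  s3 <- extract_submodel(m, beams, submodel_spec(c(48, 48, 48),
                                                 c(144, 144, 144), 1,
                                                 allow_small = TRUE))
  # parametric intersection with plane x = 48
  t0 <- (48 - 24) / (120 - 24)
  pa <- c(24, 50, 60) + t0 * c(96, 40, 40)
  got <- as.numeric(s3$beams$nodes[s3$beams$elements$node_a[1],
                                   c("x", "y", "z")])
  expect_equal(got, pa, tolerance = 1e-9)
  expect_equal(s3$beams$nodes$radius[s3$beams$elements$node_a[1]],
               6 + t0 * 6, tolerance = 1e-9)
})
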