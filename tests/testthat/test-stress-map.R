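# a minimal history carrying only beam stresses (what the mapping needs)
fake_history <- function(beam_stress_matrix) {
  structure(list(beam_stress = beam_stress_matrix,
                 times = seq_len(nrow(beam_stress_matrix)) * 0.01 - 0.01),
            class = "sim_history")
}

test_that("single and competing beams map by the maximum rule", {
  m <- block_mesh(2, 100)
  beams <- beam_mesh(data.frame(x = c(40, 60, 45, 55), y = c(50, 50, 60, 60),
                                z = c(50, 50, 55, 55), radius = 6),
                     data.frame(node_a = c(1, 3), node_b = c(2, 4),
                                source_segment = 1:2))
  h <- fake_history(rbind(c(100, 250), c(300, 100)))
  map <- map_vessel_stress(h, m, beams, radius = 60)
  expect_equal(map$value[1], 300)   # max over beams of max over time
  expect_equal(map$beam[1], 1)
  # elements with no nearby beam are marked, not zeroed
  expect_false(map$has_vessel[8])
  expect_true(is.na(map$value[8]))
})

test_that("tensile mode excludes compressive peaks; signed mode keeps them", {
  m <- block_mesh(1, 100)
  beams <- beam_mesh(data.frame(x = c(40, 60), y = 50, z = 50, radius = 5),
                     data.frame(node_a = 1, node_b = 2,
                                source_segment = 1))
  h <- fake_history(matrix(c(-50, -200), 2, 1))
  expect_equal(map_vessel_stress(h, m, beams, radius = 100)$value, 0)
  expect_equal(map_vessel_stress(h, m, beams, radius = 100,
                                 mode = "signed")$value, -50)
})

test_that("mapping equals the brute-force double loop on random instances", {
  set.seed(17)
  m <- block_mesh(5, 60)
  nb <- 20
  mids <- matrix(runif(nb * 3, 10, 290), nb, 3)
  half <- 8
  dirs <- random_unit_rows(nb)
  beams <- beam_mesh(
    data.frame(x = c(mids[, 1] - dirs[, 1] * half,
                     mids[, 1] + dirs[, 1] * half),
               y = c(mids[, 2] - dirs[, 2] * half,
                     mids[, 2] + dirs[, 2] * half),
               z = c(mids[, 3] - dirs[, 3] * half,
                     mids[, 3] + dirs[, 3] * half),
               radius = 5),
    data.frame(node_a = seq_len(nb), node_b = nb + seq_len(nb),
               source_segment = seq_len(nb)))
  bs <- matrix(rnorm(5 * nb, 100, 80), 5, nb)
  h <- fake_history(bs)
  for (radius in c(40, 90, 200)) {
    map <- map_vessel_stress(h, m, beams, radius = radius)
    peak <- pmax(apply(bs, 2, max), 0)
    cents <- vascufem:::element_centroids(m)
    for (e in seq_len(nrow(m$elements))) {
      d <- sqrt(colSums((t(mids) - cents[e, ])^2))
      inr <- which(d <= radius)
      if (length(inr) == 0) {
        expect_true(is.na(map$value[e]))
      } else {
        expect_equal(map$value[e], max(peak[inr]))
      }
    }
  }
})

test_that("mapped values never decrease when the radius doubles", {
  set.seed(19)
  m <- block_mesh(4, 60)
  nb <- 15
  mids <- matrix(runif(nb * 3, 20, 220), nb, 3)
  beams <- beam_mesh(
    data.frame(x = c(mids[, 1] - 5, mids[, 1] + 5),
               y = c(mids[, 2], mids[, 2]),
               z = c(mids[, 3], mids[, 3]), radius = 5),
    data.frame(node_a = seq_len(nb), node_b = nb + seq_len(nb),
               source_segment = seq_len(nb)))
  h <- fake_history(matrix(rnorm(3 * nb, 150, 60), 3, nb))
  m1 <- map_vessel_stress(h, m, beams, radius = 70)
  m2 <- map_vessel_stress(h, m, beams, radius = 140)
  both <- which(m1$has_vessel)
  expect_true(all(m2$has_vessel[both]))
  expect_true(all(m2$value[both] >= m1$value[both] - 1e-12))
})

test_that("threshold areas match hand enumeration and are monotone", {
  # constructed 4x4 slice with known values
  mask <- array(TRUE, c(4, 4, 1))
  attr(mask, "spacing") <- 100
  m <- voxelize(mask, 100)
  vals <- c(160, 210, 260, 310,
            155, 205, 255, 120,
            170, 220, 90, 80,
            150, 70, 60, 50)
  map <- structure(data.frame(element = 1:16, value = vals,
                              beam = 1L, n_beams = 1L, has_vessel = TRUE),
                   class = c("vessel_stress_map", "data.frame"))
  ta <- threshold_area(map, m, thresholds = c(150, 200, 250, 300),
                       slice = list(axis = 3, coordinate = 50))
  expect_equal(ta$n_exceed, c(9, 6, 3, 1))
  expect_equal(ta$area_mm2, c(9, 6, 3, 1) * 0.01)
  expect_true(all(diff(ta$n_exceed) <= 0))
  # extreme thresholds
  lo <- threshold_area(map, m, thresholds = 1,
                       slice = list(axis = 3, coordinate = 50))
  expect_equal(lo$n_exceed, 16)
  hi <- threshold_area(map, m, thresholds = 1e6,
                       slice = list(axis = 3, coordinate = 50))
  expect_equal(hi$n_exceed, 0)
})

test_that("area is monotone in threshold for random maps", {
  set.seed(23)
  mask <- array(TRUE, c(6, 6, 3))
  attr(mask, "spacing") <- 50
  m <- voxelize(mask, 50)
  for (rep in 1:5) {
    vals <- rnorm(nrow(m$elements), 200, 90)
    vals[sample(length(vals), 10)] <- NA
    map <- structure(data.frame(element = seq_along(vals), value = vals,
                                beam = 1L, n_beams = 1L,
                                has_vessel = !is.na(vals)),
                     class = c("vessel_stress_map", "data.frame"))
    ta <- threshold_area(map, m, thresholds = seq(50, 350, by = 50))
    expect_true(all(diff(ta$n_exceed) <= 0))
  }
})

test_that("ROI labels are honoured and unknown labels fail", {
  mask <- array(TRUE, c(4, 4, 1))
  attr(mask, "spacing") <- 100
  m <- voxelize(mask, 100)
  m$region_labels <- rep(c("cortex", "hippocampus"), each = 8)
  map <- structure(data.frame(element = 1:16, value = 300,
                              beam = 1L, n_beams = 1L, has_vessel = TRUE),
                   class = c("vessel_stress_map", "data.frame"))
  ta <- threshold_area(map, m, thresholds = 150, roi = "cortex",
                       slice = list(axis = 3, coordinate = 50))
  expect_equal(ta$n_exceed, 8)
  expect_error(threshold_area(map, m, roi = "thalamus",
                              slice = list(axis = 3, coordinate = 50)),
               "unknown ROI")
})

test_that("exceedance-area regression matches closed-form OLS", {
  # lm warns that the y = 2x fit is "essentially perfect"; that is the point
  r <- suppressWarnings(regress_area_vs_observation(1:5, 2 * (1:5)))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # closed-form check on a 4-point set: slope Sxy/Sxx = 7/5, R^2 = 49/50
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 5, 6)
  r2 <- regress_area_vs_observation(x, y)
  expect_equal(r2$slope, 7 / 5, tolerance = 1e-12)
  expect_equal(r2$intercept, 4 - 7 / 5 * 2.5, tolerance = 1e-12)
  expect_equal(r2$r_squared, 49 / 50, tolerance = 1e-12)
  expect_error(regress_area_vs_observation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  expect_error(regress_area_vs_observation(1:2, 1:2), "3")
})

test_that("regression p-values are uniform under the null", {
  set.seed(29)
  p <- vapply(seq_len(200), function(i) {
    regress_area_vs_observation(rnorm(8), rnorm(8))$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  expect_lt(unname(ks$statistic), 0.1)
})
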