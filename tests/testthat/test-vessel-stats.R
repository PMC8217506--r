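test_that("beam_direction normalizes and is rotation-equivariant", {
  expect_equal(beam_direction(c(0, 0, 0), c(1, 0, 0)), c(1, 0, 0))
  expect_equal(beam_direction(c(0, 0, 0), c(3, 4, 0)), c(0.6, 0.8, 0))
  expect_error(beam_direction(c(1, 2, 3), c(1, 2, 3)), "coincident")
  set.seed(3)
  for (i in 1:10) {
    R <- random_rotation()
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(beam_direction(as.numeric(R %*% a), as.numeric(R %*% b)),
                 as.numeric(R %*% beam_direction(a, b)), tolerance = 1e-12)
  }
})

test_that("principal decomposition sorts descending and reconstructs", {
  d <- principal_decomposition(diag(c(5, 2, 1)))
  expect_equal(d$values, c(5, 2, 1))
  expect_equal(abs(d$vectors[, 1]), c(1, 0, 0))
  # hydrostatic: all eigenvalues p, any orthonormal basis accepted
  dh <- principal_decomposition(3 * diag(3))
  expect_equal(dh$values, rep(3, 3))
  expect_equal(crossprod(dh$vectors), diag(3), tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    A <- random_symmetric3(10)
    d <- principal_decomposition(A)
    expect_true(all(diff(d$values) <= 1e-12))
    rec <- d$vectors %*% diag(d$values) %*% t(d$vectors)
    expect_lt(max(abs(rec - A)), 1e-9)
  }
  expect_error(principal_decomposition(matrix(rnorm(9), 3, 3)),
               "symmetric")
})

test_that("deviatoric part removes exactly the hydrostatic component", {
  expect_equal(deviatoric_part(7 * diag(3)), matrix(0, 3, 3))
  set.seed(11)
  A <- random_symmetric3()
  Adev <- deviatoric_part(A)
  expect_lt(abs(sum(diag(Adev))), 1e-12)
  expect_equal(Adev + sum(diag(A)) / 3 * diag(3), A, tolerance = 1e-15)
  expect_equal(deviatoric_part(Adev), Adev, tolerance = 1e-15)
})

test_that("vessel angle is the sign-free acute angle in degrees", {
  expect_equal(vessel_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(vessel_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(vessel_angle(c(1, 0, 0), c(1, 1, 0) / sqrt(2)), 45,
               tolerance = 1e-12)
  expect_equal(vessel_angle(c(1, 0, 0), c(-1, 0, 0)), 0)  # sign-free
  expect_error(vessel_angle(c(2, 0, 0), c(1, 0, 0)), "unit")
})

test_that("records have beam x frame cardinality and consistent angles", {
  set.seed(13)
  m <- block_mesh(3, 100)
  dirs <- random_unit_rows(5)
  beams <- oriented_beams(dirs, centre = c(150, 150, 150), half_len = 35)
  Fend <- diag(c(1.06, 1 / sqrt(1.06), 1 / sqrt(1.06)))
  h <- run_macro(m, beams, scenario = NULL,
                 controls = solver_controls(
                   t_end = 0.3, prescribed = affine_motion(m, Fend, 0.3),
                   fixed_base = FALSE))
  rec <- build_records(h, m, beams)
  expect_equal(nrow(rec), 5 * length(h$times))
  expect_equal(unique(rec$beam), 1:5)
  # under uniaxial tissue stress the angle equals the beam-to-axis angle
  last <- rec[rec$time == max(rec$time), ]
  geo <- acos(pmin(1, abs(dirs %*% t(Fend))[, 1] /
                     sqrt(rowSums((dirs %*% t(Fend))^2)))) * 180 / pi
  expect_equal(last$angle_stress, as.numeric(geo), tolerance = 0.1)
  # angles bounded, directions unit
  expect_true(all(rec$angle_stress >= 0 & rec$angle_stress <= 90))
  expect_lt(max(abs(sqrt(rec$dir_x^2 + rec$dir_y^2 + rec$dir_z^2) - 1)),
            1e-9)
})

test_that("correlation suite matches definitional formulas", {
  set.seed(17)
  x <- rnorm(20)
  z <- rnorm(20)
  y <- -x + 0.5 * z + rnorm(20, sd = 0.2)
  df <- data.frame(x = x, y = y, z = z)
  cs <- correlation_suite(df, "x", "y", control = "z")
  expect_equal(cs$r, cor(x, y), tolerance = 1e-12)
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  expect_equal(cs$partial_r,
               (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2)),
               tolerance = 1e-12)
  fit <- lm(y ~ x)
  expect_equal(cs$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  # exact anti-correlation (lm warns about the perfect fit)
  expect_equal(suppressWarnings(
    correlation_suite(data.frame(x = 1:5, y = -(1:5)), "x", "y")$r),
    -1, tolerance = 1e-12)
  # y = z and x orthogonal to z by construction -> partial r = 0
  xo <- c(1, -1, 1, -1, 1, -1)
  zo <- c(1, 1, -1, -1, 1, 1) - mean(c(1, 1, -1, -1, 1, 1))
  xo <- xo - mean(xo)
  zo <- zo - sum(zo * xo) / sum(xo^2) * xo
  dfo <- data.frame(x = xo, y = zo, z = zo)
  expect_lt(abs(correlation_suite(dfo, "x", "y", control = "z")$partial_r),
            1e-12)
})

test_that("log10 transform drops non-positive responses with a count", {
  df <- data.frame(x = 1:6, y = c(10, 100, -5, 1000, 0, 10))
  cs <- correlation_suite(df, "x", "y", transform = "log10")
  expect_equal(cs$n_dropped, 2)
  expect_equal(cs$n, 4)
  fit <- lm(log10(c(10, 100, 1000, 10)) ~ c(1, 2, 4, 6))
  expect_equal(cs$slope, unname(coef(fit)[2]), tolerance = 1e-12)
  expect_error(correlation_suite(data.frame(x = 1:3, y = -(1:3)),
                                 "x", "y", transform = "log10"), "3")
})

test_that("ROC AUC matches exhaustive pair counting with ties", {
  # 6-point set with one tie: label TRUE = tension
  angle <- c(10, 20, 30, 30, 50, 70)
  stress <- c(5, 4, 3, -1, -2, -3)
  df <- data.frame(angle_stress = angle, axial_stress = stress)
  roc <- tension_compression_roc(df, n_boot = 10, seed = 1)
  # brute force over (tension, compression) pairs with score = -angle
  pos <- -angle[stress > 0]
  neg <- -angle[stress < 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  expect_equal(roc$auc, wins / (length(pos) * length(neg)))
  # perfectly separated data
  dfp <- data.frame(angle_stress = c(5, 10, 80, 85),
                    axial_stress = c(1, 2, -1, -2))
  expect_equal(tension_compression_roc(dfp, n_boot = 10, seed = 1)$auc, 1)
  expect_error(tension_compression_roc(
    data.frame(angle_stress = 1:3, axial_stress = c(1, 2, 3)),
    n_boot = 10), "both")
})

test_that("AUC is near 0.5 for an uninformative predictor", {
  set.seed(31)
  df <- data.frame(angle_stress = runif(2000, 0, 90),
                   axial_stress = rnorm(2000))
  roc <- tension_compression_roc(df, n_boot = 50, seed = 2)
  expect_lt(abs(roc$auc - 0.5), 0.03)
  expect_true(roc$ci[1] <= roc$auc && roc$auc <= roc$ci[2])
})

test_that("in-package AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(37)
  n <- 300
  angle <- runif(n, 0, 90)
  stress <- ifelse(angle + rnorm(n, sd = 25) < 45, abs(rnorm(n)),
                   -abs(rnorm(n)))
  df <- data.frame(angle_stress = angle, axial_stress = stress)
  ours <- tension_compression_roc(df, n_boot = 10, seed = 1)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(
    response = factor(stress > 0), predictor = -angle,
    direction = "<", quiet = TRUE)))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})
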