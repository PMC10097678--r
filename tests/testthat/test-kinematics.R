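test_that("forward kinematics matches hand circle-intersection geometry", {
  g <- pantograph_geometry(2, 1, 2)
  ## elbows at (0,1) and (2,1); circles of radius 2 meet at (1, 1 +- sqrt(3))
  p <- forward_kinematics(g, pi / 2, pi / 2)
  expect_equal(p, c(1, 1 + sqrt(3)), tolerance = 1e-12)
  ## mirror symmetry: theta_R = pi - theta_L puts the endpoint on x = d/2
  for (th in c(0.9, 1.2, 1.5)) {
    p <- forward_kinematics(g, th, pi - th)
    expect_equal(p[1], g$d / 2, tolerance = 1e-12)
  }
  expect_error(forward_kinematics(pantograph_geometry(5, 1, 2), pi / 2, pi / 2),
               "unreachable")
})

test_that("inverse kinematics round-trips with forward kinematics", {
  g <- pantograph_geometry(2, 2, 3)
  set.seed(101)
  n_ok <- 0
  for (i in 1:100) {
    target <- c(runif(1, -1, 3), runif(1, 2, 4.5))
    ik <- tryCatch(inverse_kinematics(g, target), error = function(e) NULL)
    if (is.null(ik)) next
    p <- forward_kinematics(g, ik$theta_left, ik$theta_right)
    expect_lt(sqrt(sum((p - target)^2)), 1e-9)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 50)
  ## angle round trip through the outward working mode
  ik <- inverse_kinematics(pantograph_geometry(2, 1, 2), c(1, 1 + sqrt(3)))
  expect_equal(c(ik$theta_left, ik$theta_right), c(pi / 2, pi / 2),
               tolerance = 1e-9)
  ## midline target with symmetric geometry: theta_R = pi - theta_L
  ik <- inverse_kinematics(g, c(1, 3.4))
  expect_equal(ik$theta_right, pi - ik$theta_left, tolerance = 1e-9)
})

test_that("inverse kinematics handles boundary and unreachable targets", {
  g <- pantograph_geometry(2, 1, 2)
  ## maximal reach of the left chain (collinear links): the proximal link
  ## points straight at the target (law-of-cosines boundary solution)
  target <- c(1.5, sqrt(9 - 1.5^2) - 1e-9)
  ik <- inverse_kinematics(g, target, tol = 1e-4)
  expect_equal(ik$theta_left, atan2(target[2], target[1]), tolerance = 1e-3)
  expect_error(inverse_kinematics(g, c(0, 5)), "unreachable")
})

test_that("trapezoidal trajectories have the closed-form duration and conserve distance", {
  ## 7 mm at 2 cm/s with 20 cm/s^2: d/v + v/a = 0.35 + 0.1 = 0.45 s
  tr <- trapezoid_trajectory(c(0, 0), c(0.7, 0), 2, 20)
  expect_equal(tr$duration_s, 0.45, tolerance = 1e-12)
  ## rectangular limit: duration -> d / v = 0.35 s
  tr2 <- trapezoid_trajectory(c(0, 0), c(0.7, 0), 2, 1e7)
  expect_equal(tr2$duration_s, 0.35, tolerance = 1e-5)
  ## speed integral equals commanded distance (0.1%)
  for (tt in list(tr, trapezoid_trajectory(c(1, 1), c(1.3, 1.4), 3, 15))) {
    disp <- sum(diff(tt$times_s) *
                  (head(tt$speed_cms, -1) + tail(tt$speed_cms, -1)) / 2)
    d <- tt$amplitude_mm / 10
    expect_lt(abs(disp - d) / d, 1e-3)
    ## peak speed reached up to grid resolution (exact during a cruise phase,
    ## one accel step at the apex of a triangular profile)
    expect_lt(abs(max(tt$speed_cms) - tt$peak_velocity),
              tt$accel * 1e-3 + 1e-9)
    ## path is the straight start-to-end segment: zero cross product
    u <- tt$positions[nrow(tt$positions), ] - tt$positions[1, ]
    rel <- sweep(tt$positions, 2, tt$positions[1, ])
    expect_lt(max(abs(rel[, 1] * u[2] - rel[, 2] * u[1])), 1e-9)
  }
  expect_error(trapezoid_trajectory(c(0, 0), c(0, 0), 2, 20), "zero-distance")
})

test_that("triangulation recovers synthetic joints exactly and flags symmetry", {
  sc <- gen_stereo_scene(small_grid(), pixel_noise_sd = 0)
  for (i in seq_len(3)) {
    X <- triangulate_joints(sc$pixel_pairs[[i]], sc$cameras)
    expect_lt(max(abs(X - sc$joints_world[[i]])), 1e-9)
  }
  ## swapping camera order leaves the world point unchanged (same frame,
  ## both matrices are expressed in it)
  swapped <- sc$pixel_pairs[[1]][, c(3, 4, 1, 2)]
  X2 <- triangulate_joints(swapped, list(sc$cameras$P2, sc$cameras$P1))
  expect_lt(max(abs(X2 - sc$joints_world[[1]])), 1e-9)
})

test_that("noisy triangulation error matches a reprojection Monte-Carlo oracle", {
  set.seed(202)
  grid <- small_grid()
  sc0 <- gen_stereo_scene(grid, pixel_noise_sd = 0)
  P1 <- sc0$cameras$P1; P2 <- sc0$cameras$P2
  project <- function(P, X) { x <- P %*% c(X, 1); c(x[1], x[2]) / x[3] }
  truth <- sc0$joints_world[[1]]["endpoint", ]
  pix0 <- c(project(P1, truth), project(P2, truth))
  ## oracle: nonlinear reprojection minimization, independent of the DLT
  oracle_err <- replicate(120, {
    noisy <- pix0 + rnorm(4, sd = 0.5)
    fn <- function(X) sum((c(project(P1, X), project(P2, X)) - noisy)^2)
    est <- optim(truth + 0.3, fn, method = "BFGS")$par
    sqrt(sum((est - truth)^2))
  })
  dlt_err <- replicate(120, {
    noisy <- pix0 + rnorm(4, sd = 0.5)
    X <- triangulate_joints(rbind(noisy), list(P1, P2))
    sqrt(sum((X - truth)^2))
  })
  expect_lt(abs(median(dlt_err) - median(oracle_err)) / median(oracle_err), 0.2)
})

test_that("similarity transform fitting is exact, reflection-free and invertible", {
  set.seed(7)
  X <- matrix(rnorm(30), 10, 3)
  th <- pi / 6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- 2 * X %*% t(R) + matrix(c(1, 2, 3), 10, 3, byrow = TRUE)
  f <- fit_similarity_transform(X, Y)
  expect_equal(f$scale, 2, tolerance = 1e-9)
  expect_lt(max(abs(f$rotation - R)), 1e-9)
  expect_lt(max(abs(f$translation - c(1, 2, 3))), 1e-9)
  expect_lt(f$rms_residual, 1e-9)
  ## identity correspondence
  fi <- fit_similarity_transform(X, X)
  expect_lt(max(abs(fi$rotation - diag(3))), 1e-9)
  expect_equal(fi$scale, 1, tolerance = 1e-9)
  ## apply then invert is the identity
  back <- apply_similarity_transform(invert_similarity_transform(f),
                                     apply_similarity_transform(f, X))
  expect_lt(max(abs(back - X)), 1e-10)
  ## mirrored targets never produce a reflection
  Ym <- X %*% diag(c(-1, 1, 1))
  fm <- fit_similarity_transform(X, Ym)
  expect_gt(det(fm$rotation), 0)
  expect_gt(fm$rms_residual, 0.1)
  expect_error(fit_similarity_transform(matrix(rep(1:3, 3), 3, byrow = TRUE) *
                                          c(1, 2, 3), Y[1:3, ]),
               "collinear|degenerate")
})

test_that("humerus azimuth angle follows the -Z / XZ-plane convention", {
  js <- function(g, e) list(glenohumeral = g, elbow = e)
  ## straight-down humerus: 0 degrees
  expect_equal(humerus_azimuth_angle(js(c(0, 0, 1), c(0, 0, 0))), 0)
  ## horizontal lateral humerus: +90 degrees (abduction)
  expect_equal(humerus_azimuth_angle(js(c(0, 0, 0), c(1, 0, 0))), 90)
  ## elbow at (-1, 0, -1) from the glenohumeral point: -45 (adduction)
  expect_equal(humerus_azimuth_angle(js(c(0, 0, 0), c(-1, 0, -1))), -45)
  ## Y component is ignored (projection onto XZ)
  expect_equal(humerus_azimuth_angle(js(c(0, 0, 0), c(1, 5, 0))), 90)
  expect_error(humerus_azimuth_angle(js(c(0, 0, 0), c(0, 1, 0))), "undefined")
})

test_that("angle maps interpolate exactly on nodes and linear fields", {
  grid <- as.matrix(expand.grid(x = 0:4, y = 0:3))
  ang <- 3 * grid[, 1] - 2 * grid[, 2] + 1      # linear field
  m <- build_angle_map(grid, angles = ang)
  ## node reproduction
  expect_equal(interpolate_angle_map(m, grid), ang, tolerance = 1e-12)
  ## directional derivative of a linear field
  for (dir in c(0, 30, 135, 250)) {
    got <- angle_change_for_displacement(m, c(1.3, 1.1), dir, 7)
    want <- (3 * cos(dir * pi / 180) - 2 * sin(dir * pi / 180)) * 0.7
    expect_equal(got, want, tolerance = 1e-9)
  }
  ## zero displacement and constant field
  expect_equal(angle_change_for_displacement(m, c(2, 2), 45, 0), 0)
  mc <- build_angle_map(grid, angles = rep(5, nrow(grid)))
  expect_equal(angle_change_for_displacement(mc, c(2, 1.5), 120, 6), 0)
  expect_error(interpolate_angle_map(m, c(10, 10)), "outside")
})
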