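test_that("rigid transforms compose, invert and validate", {
  R <- rotation_about_axis(c(1, -1, 2), 33)
  tr <- rigid_transform(R, c(1, 2, 3))
  expect_equal(max(abs(crossprod(tr$rotation) - diag(3))), 0,
               tolerance = 1e-12)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-12)
  pts <- matrix(rnorm(30), 10)
  back <- transform_points(invert_transform(tr), transform_points(tr, pts))
  expect_equal(back, pts, tolerance = 1e-12)
  comp <- compose_transforms(invert_transform(tr), tr)
  expect_equal(rotation_angle(comp), 0, tolerance = 1e-7)
  expect_error(rigid_transform(matrix(1, 3, 3)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1))), "reflection")
})

test_that("Kabsch recovers exact rigid motions", {
  set.seed(101)
  src <- matrix(rnorm(30, sd = 10), 10)
  expect_equal(rotation_angle(estimate_rigid_transform(src, src)), 0,
               tolerance = 1e-9)
  shift <- estimate_rigid_transform(src, sweep(src, 2, c(5, 0, 0), "+"))
  expect_equal(shift$rotation, diag(3), tolerance = 1e-12)
  expect_equal(shift$translation, c(5, 0, 0), tolerance = 1e-12)
  R30 <- rotation_about_axis(c(0, 0, 1), 30)
  fit <- estimate_rigid_transform(src, src %*% t(R30))
  expect_equal(fit$rotation, R30, tolerance = 1e-9)
  # weighted fit ignores a corrupted pair with zero weight
  tgt <- src %*% t(R30)
  tgt[1, ] <- c(1e3, -1e3, 1e3)
  w <- c(0, rep(1, 9))
  fitw <- estimate_rigid_transform(src, tgt, weights = w)
  expect_equal(fitw$rotation, R30, tolerance = 1e-9)
  expect_error(estimate_rigid_transform(src[1:2, ], src[1:2, ]), "3 point")
  line <- cbind(1:10, 2 * (1:10), -(1:10))
  expect_error(estimate_rigid_transform(line, line), "collinear")
})

test_that("Kabsch is equivariant under conjugation by a rotation", {
  set.seed(7)
  src <- matrix(rnorm(45, sd = 5), 15)
  tgt <- src %*% t(rotation_about_axis(c(1, 1, 0), 20)) +
    matrix(rnorm(45, sd = 0.1), 15)
  base <- estimate_rigid_transform(src, tgt)
  Q <- rotation_about_axis(c(2, -1, 1), 55)
  conj <- estimate_rigid_transform(src %*% t(Q), tgt %*% t(Q))
  expect_equal(conj$rotation, Q %*% base$rotation %*% t(Q), tolerance = 1e-9)
})

test_that("initial alignment recovers large rotations on asymmetric shapes", {
  p <- generate_phantom_pair(phantom_spec())
  pts <- extract_points(p$t0, p$truth$roi1)$points
  # pure translation of an identical cloud
  tr <- initial_alignment(sweep(pts, 2, c(8, -4, 2), "+"), pts)
  expect_equal(rotation_angle(tr), 0, tolerance = 1e-6)
  expect_equal(tr$translation, c(-8, 4, -2), tolerance = 1e-6)
  # 170 degrees about z: far beyond the ICP basin, PCA must get close
  R <- rotation_about_axis(c(0, 0, 1), 170)
  init <- initial_alignment(pts %*% t(R), pts)
  expect_lt(rotation_angle(init$rotation %*% R), 5)
  reg <- icp_refine(pts %*% t(R), extract_submesh(p$t0, p$truth$roi1),
                    init = init)
  err <- compose_transforms(reg$final_transform, rigid_transform(R))
  expect_lt(rotation_angle(err), 0.05)
  # exactly isotropic cloud falls back to centroid alignment with a warning
  ball <- as.matrix(expand.grid(x = -2:2, y = -2:2, z = -2:2))
  expect_warning(iso <- initial_alignment(ball, sweep(ball, 2, c(1, 2, 3),
                                                      "+")),
                 "near-isotropic")
  expect_equal(iso$rotation, diag(3))
  expect_equal(iso$translation, c(1, 2, 3), tolerance = 1e-9)
})

test_that("point-to-triangle projection handles all regions exactly", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); c3 <- c(0, 1, 0)
  interior <- nearest_point_on_triangle(c(0.25, 0.25, 1), a, b, c3)
  expect_equal(interior$point, c(0.25, 0.25, 0))
  expect_equal(interior$distance, 1)
  vert <- nearest_point_on_triangle(c(-1, -1, 0), a, b, c3)
  expect_equal(vert$point, a)
  expect_equal(vert$distance, sqrt(2))
  edge <- nearest_point_on_triangle(c(0.5, -2, 0), a, b, c3)
  expect_equal(edge$point, c(0.5, 0, 0))
  expect_error(nearest_point_on_triangle(c(0, 0, 1), a, a, a), "degenerate")
})

test_that("point-to-triangle distance matches a dense barycentric grid", {
  set.seed(11)
  for (i in 1:50) {
    tri <- matrix(runif(9, -1, 1), 3)
    # keep the oracle honest: skip slivers the grid cannot resolve
    if (orthoicp:::face_areas(tri, matrix(1:3, 1)) < 0.05) next
    p <- runif(3, -2, 2)
    exact <- nearest_point_on_triangle(p, tri[1, ], tri[2, ], tri[3, ])
    approx <- grid_closest_distance(p, tri[1, ], tri[2, ], tri[3, ])
    expect_lt(abs(exact$distance - approx), 1e-4)
    expect_lte(exact$distance, approx + 1e-12)   # grid can never beat exact
  }
})

test_that("accelerated mesh queries equal the exhaustive scan", {
  set.seed(21)
  p <- generate_phantom_pair(phantom_spec(cranial_density = c(10L, 5L),
                                          maxilla_density = c(10L, 5L)))
  mesh <- p$t0
  queries <- matrix(runif(300, -100, 100), ncol = 3)
  fast <- nearest_point_on_mesh(queries, mesh)
  slow <- nearest_point_on_mesh(queries, mesh, exhaustive = TRUE)
  expect_identical(fast$face, slow$face)
  expect_equal(fast$distance, slow$distance, tolerance = 1e-15)
  # and both agree with the R-level per-face scan on a subsample
  for (i in seq(1, nrow(queries), by = 10)) {
    ref <- r_exhaustive_closest(queries[i, ], mesh)
    expect_identical(fast$face[i], ref$face)
    expect_equal(fast$distance[i], ref$distance, tolerance = 1e-9)
  }
  # a mesh vertex queries to distance zero on itself
  onv <- nearest_point_on_mesh(mesh$vertices[5, ], mesh)
  expect_equal(onv$distance, 0, tolerance = 1e-12)
  # a point high above the cube top face
  cube <- make_cube()
  above <- nearest_point_on_mesh(c(0, 0, 10), cube)
  expect_equal(above$distance, 9.5)
  expect_true(above$face %in% 3:4)             # a z = +0.5 face
})

test_that("ICP is a fixed point on exact overlap and recovers known motion", {
  p <- generate_phantom_pair(phantom_spec())
  ref1 <- extract_submesh(p$t0, p$truth$roi1)
  pts <- extract_points(p$t0, p$truth$roi1)$points
  fixed <- icp_refine(pts, ref1, params = icp_params(trim_fraction = 0))
  expect_lte(fixed$iterations_run, 2L)
  expect_lt(utils::tail(fixed$rms_per_iteration, 1), 1e-9)
  expect_lt(rotation_angle(fixed$final_transform), 1e-7)

  # identity init: tangential sliding on the smooth dome converges linearly,
  # so the tolerance-driven run needs headroom in iterations
  move <- rigid_transform(rotation_about_axis(c(0, 0, 1), 5),
                          c(0.5, 0.3, -0.2))
  reg <- icp_refine(transform_points(move, pts), ref1,
                    params = icp_params(max_iterations = 500,
                                        rms_change_tolerance = 1e-9,
                                        trim_fraction = 0))
  err <- recovery_error(reg$final_transform, move)
  expect_lt(err$rot_deg, 0.05)
  expect_lt(err$trans_mm, 0.01)
  # per-iteration RMS non-increasing after the first re-correspondence
  expect_true(all(diff(reg$rms_per_iteration) <= 1e-12))
  # composition correctness: applying the reported transform to the original
  # source reproduces the final iterate (same surface RMS it reported)
  moved <- transform_points(reg$final_transform,
                            transform_points(move, pts))
  final_rms <- sqrt(mean(nearest_point_on_mesh(moved, ref1)$distance^2))
  expect_equal(final_rms, utils::tail(reg$rms_per_iteration, 1),
               tolerance = 1e-6)
})

test_that("ICP under Gaussian noise reaches the noise floor", {
  sigma <- 0.1
  p <- generate_phantom_pair(phantom_spec())
  ref1 <- extract_submesh(p$t0, p$truth$roi1)
  pts <- extract_points(p$t0, p$truth$roi1)$points
  move <- rigid_transform(rotation_about_axis(c(1, 0, 0), 3), c(1, -1, 0.5))
  set.seed(31)
  noisy <- transform_points(move, pts) + matrix(rnorm(length(pts), 0, sigma),
                                                ncol = 3)
  reg <- icp_refine(noisy, ref1, params = icp_params(trim_fraction = 0))
  err <- recovery_error(reg$final_transform, move)
  expect_lt(err$rot_deg, 0.3)
  expect_lt(err$trans_mm, 0.1)
  final <- utils::tail(reg$rms_per_iteration, 1)
  expect_gt(final, 0.8 * sigma)
  expect_lt(final, 1.3 * sigma)
  # subsampling is seed-reproducible
  ps <- icp_params(sample_count = 200, seed = 9)
  r1 <- icp_refine(noisy, ref1, params = ps)
  r2 <- icp_refine(noisy, ref1, params = ps)
  expect_identical(r1$rms_per_iteration, r2$rms_per_iteration)
})
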