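test_that("sphere fit recovers exact spheres and generating radii", {
  # octahedron vertices of a radius-5 sphere
  p <- rbind(c(5, 0, 0), c(-5, 0, 0), c(0, 5, 0), c(0, -5, 0), c(0, 0, 5), c(0, 0, -5))
  f <- fit_sphere(p)
  expect_equal(f$radius, 5, tolerance = 1e-12)
  expect_lt(max(abs(f$center)), 1e-9)
  expect_lt(f$mean_abs_error, 1e-12)

  # noise-free synthetic cap at a generating radius from the cohort envelope
  g <- generate_cap(cap_spec(11.18, 60, resolution = 0.4, noise_sd = 0, sense = "concave", seed = 1))
  fit <- fit_sphere(g$mesh)
  expect_equal(fit$radius, 11.18, tolerance = 1e-7)
  expect_identical(fit$curvature_sense, "concave")

  # any >= 4 non-coplanar on-sphere points give an exact fit
  for (seed in 1:5) {
    pts <- sphere_points(4 + seed, radius = 2 + seed, seed = seed)
    ft <- fit_sphere(pts)
    expect_equal(ft$radius, 2 + seed, tolerance = 1e-9)
  }
})

test_that("radial Gaussian noise yields the half-normal mean error", {
  # oracle: E|N(0, sigma)| = sigma * sqrt(2/pi)
  sigma <- 0.1
  expected <- sigma * sqrt(2 / pi)
  g <- generate_cap(cap_spec(10, 60, resolution = 0.28, noise_sd = sigma,
                             elongation = 1, seed = 11))
  fit <- fit_sphere(g$mesh)
  expect_gt(nrow(g$mesh$vertices), 3000)
  expect_equal(fit$mean_abs_error, expected, tolerance = 0.1)
  expect_lt(abs(fit$radius - 10), 0.05)
})

test_that("sphere fit is equivariant under rigid motion and scaling", {
  g <- generate_cap(cap_spec(8, 50, resolution = 0.5, noise_sd = 0.05, seed = 2))
  base <- fit_sphere(g$mesh)
  for (seed in 1:3) {
    rot <- random_rotation(seed)
    shift <- c(3, -7, 11) * seed
    moved <- transform_mesh(g$mesh, rot, shift)
    f2 <- fit_sphere(moved)
    expect_equal(f2$radius, base$radius, tolerance = 1e-8)
    expect_equal(f2$mean_abs_error, base$mean_abs_error, tolerance = 1e-8)
    expect_equal(as.vector(rot %*% base$center + shift), f2$center, tolerance = 1e-6)
  }
  s <- 2.5
  scaled <- facet_mesh(g$mesh$vertices * s, g$mesh$faces, clean = FALSE)
  fs <- fit_sphere(scaled)
  expect_equal(fs$radius, s * base$radius, tolerance = 1e-8)
  expect_equal(fs$mean_abs_error, s * base$mean_abs_error, tolerance = 1e-8)
})

test_that("geometric refinement never exceeds the algebraic initialisation's SSE", {
  for (seed in 1:5) {
    g <- generate_cap(cap_spec(6 + seed, 45, resolution = 0.5, noise_sd = 0.15, seed = seed))
    p <- g$mesh$vertices
    alg <- oracle_algebraic_sphere(p)
    fit <- fit_sphere(p)
    expect_lte(
      sphere_sse(p, fit$center, fit$radius),
      sphere_sse(p, alg$center, alg$radius) + 1e-9
    )
  }
})

test_that("coplanar and undersized point sets are rejected", {
  flat <- cbind(runif(20), runif(20), 0)
  expect_error(fit_sphere(flat), class = "fm_coplanar_error")
  expect_error(fit_sphere(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))),
               class = "fm_degenerate_input")
})

test_that("signed residuals behave as distances from the sphere surface", {
  p <- sphere_points(50, 10, seed = 3)
  fit <- fit_sphere(p)
  # uniform outward offset: +0.2 each, 2% of the radius
  out <- p * 1.02
  res <- point_sphere_residuals(out, fit)
  expect_equal(unname(res), rep(0.2, 50), tolerance = 1e-9)
  expect_equal(mean(abs(res)) / fit$radius, 0.02, tolerance = 1e-9)
  # the centre sits at -radius; on-sphere points at 0
  expect_equal(point_sphere_residuals(matrix(fit$center, 1), fit), -10, tolerance = 1e-9)
  expect_lt(max(abs(point_sphere_residuals(p, fit))), 1e-9)
})

test_that("three-point radius matches worked values and a circumcentre oracle", {
  expect_equal(three_point_roc(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0)), 1.0, tolerance = 1e-12)
  expect_equal(three_point_roc(c(0, 0, 0), c(1, 0.2, 0), c(2, 0, 0)), 2.6, tolerance = 1e-9)
  expect_error(three_point_roc(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), class = "fm_collinear_error")

  set.seed(42)
  for (k in 1:1000) {
    tri <- matrix(rnorm(9, sd = 5), 3, 3)
    area2 <- sqrt(sum((c(
      (tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) - (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
      (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) - (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
      (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) - (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
    ))^2))
    if (area2 < 1e-6) next
    r <- three_point_roc(tri[1, ], tri[2, ], tri[3, ])
    r0 <- oracle_circumradius(tri[1, ], tri[2, ], tri[3, ])
    expect_equal(r, r0, tolerance = 1e-9)
  }
})

test_that("angles between vectors honour optional plane projection", {
  expect_equal(angle_between(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angle_between(c(2, 3, -1), c(2, 3, -1)), 0, tolerance = 1e-6)
  expect_equal(angle_between(c(1, 1, 1), c(1, 1, -1), plane_normal = c(0, 0, 1)), 0,
               tolerance = 1e-5)
  expect_error(angle_between(c(0, 0, 0), c(1, 0, 0)), class = "fm_undefined_angle")
  expect_error(angle_between(c(0, 0, 1), c(1, 0, 0), plane_normal = c(0, 0, 1)),
               class = "fm_undefined_angle")
})

test_that("total-least-squares plane fit recovers planes and noise levels", {
  set.seed(9)
  xy <- cbind(runif(1000, -5, 5), runif(1000, -5, 5))
  flat <- cbind(xy, 0)
  pl <- fit_plane(flat)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)
  expect_lt(pl$rms, 1e-12)

  offsets <- rnorm(1000, 0, 0.05)
  noisy <- cbind(xy, offsets)
  pl2 <- fit_plane(noisy)
  # oracle: rms of the generated offsets themselves
  expect_equal(pl2$rms, sqrt(mean(offsets^2)), tolerance = 0.2)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), class = "fm_degenerate_input")
  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), class = "fm_degenerate_input")
})

test_that("cross-sections produce the analytic arcs of known solids", {
  # hemisphere cut through the pole: a semicircle of length pi*R
  g <- generate_cap(cap_spec(10, 90, resolution = 0.3, noise_sd = 0, elongation = 1, seed = 1))
  cs <- cross_section(g$mesh, c(0, 0, 0), c(0, 1, 0))
  expect_equal(cs$arc_length, pi * 10, tolerance = 0.005)
  # unit square cut at mid-height
  sq <- unit_square_mesh()
  cs2 <- cross_section(sq, c(0.5, 0.5, 0), c(0, 1, 0))
  expect_equal(cs2$arc_length, 1.0, tolerance = 1e-9)
  expect_error(cross_section(sq, c(0, 0, 5), c(0, 0, 1)), class = "fm_no_intersection")
})

test_that("cross-section arc length is invariant under rigid motion", {
  g <- generate_cap(cap_spec(7, 55, resolution = 0.5, noise_sd = 0.05, seed = 5))
  cs <- cross_section(g$mesh, c(0, 0, 0), c(0, 1, 0))
  for (seed in 1:3) {
    rot <- random_rotation(seed + 10)
    shift <- c(-2, 4, 9)
    moved <- transform_mesh(g$mesh, rot, shift)
    cs2 <- cross_section(moved, as.vector(rot %*% c(0, 0, 0) + shift),
                         as.vector(rot %*% c(0, 1, 0)))
    expect_equal(cs2$arc_length, cs$arc_length, tolerance = 1e-8)
  }
})

test_that("surface area is exact on analytic shapes and additive over partitions", {
  expect_equal(surface_area(unit_square_mesh()), 1.0, tolerance = 1e-12)
  g <- generate_cap(cap_spec(10, 90, resolution = 0.3, noise_sd = 0, elongation = 1, seed = 1))
  expect_equal(surface_area(g$mesh), 2 * pi * 100, tolerance = 0.005)
  # additivity over an arbitrary face partition
  m <- g$mesh
  half <- seq_len(nrow(m$faces)) %% 2 == 0
  a1 <- facet_mesh(m$vertices, m$faces[half, , drop = FALSE], clean = FALSE)
  a2 <- facet_mesh(m$vertices, m$faces[!half, , drop = FALSE], clean = FALSE)
  expect_equal(surface_area(a1) + surface_area(a2), surface_area(m), tolerance = 1e-9)
})

test_that("anatomical frames follow PCA axes or supplied landmarks", {
  g <- generate_cap(cap_spec(9, 55, resolution = 0.4, noise_sd = 0, elongation = 1.8, seed = 1))
  fr <- build_frame(g$mesh)
  # elongation is along x: the sagittal axis must align within 1 degree
  expect_lt(angle_between(fr$sagittal_axis * sign(fr$sagittal_axis[1]), c(1, 0, 0)), 1)
  expect_lt(angle_between(fr$normal_axis * sign(fr$normal_axis[3]), c(0, 0, 1)), 1)
  # axes orthonormal
  B <- rbind(fr$sagittal_axis, fr$coronal_axis, fr$normal_axis)
  expect_equal(B %*% t(B), diag(3), tolerance = 1e-9, ignore_attr = TRUE)

  fr2 <- build_frame(g$mesh, xy_orientation())
  expect_equal(abs(sum(fr2$sagittal_axis * c(1, 0, 0))), 1, tolerance = 1e-6)
  expect_equal(abs(sum(fr2$coronal_axis * c(0, 1, 0))), 1, tolerance = 1e-6)
})

test_that("PCA frames with two equal smallest eigenvalues are rejected", {
  # points spread along x with equal, tiny spread in y and z
  d <- 0.3
  v <- rbind(
    c(-4, -d, 0), c(-4, d, 0), c(-4, 0, -d), c(-4, 0, d),
    c(0, -d, 0), c(0, d, 0), c(0, 0, -d), c(0, 0, d),
    c(4, -d, 0), c(4, d, 0), c(4, 0, -d), c(4, 0, d)
  )
  f <- rbind(c(1, 5, 2), c(2, 5, 6), c(5, 9, 6), c(6, 9, 10))
  m <- facet_mesh(v, f, clean = FALSE)
  expect_error(build_frame(m), class = "fm_ambiguous_frame")
})
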