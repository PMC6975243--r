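test_that("facet reports recover generating parameters of synthetic caps", {
  g <- generate_cap(cap_spec(9.94, 60, resolution = 0.35, noise_sd = 0, seed = 1))
  fr <- build_frame(g$mesh, xy_orientation())
  rep <- measure_facet(g$mesh, fr)
  expect_equal(rep$roc, 9.94, tolerance = 1e-7)
  expect_identical(rep$curvature_sense, "convex")
  expect_equal(rep$mean_error_pct, rep$mean_abs_error / rep$roc, tolerance = 1e-12)

  # flipping the normals (viewing from the concave side) flips the sense only
  flipped <- facet_mesh(g$mesh$vertices, g$mesh$faces[, c(1, 3, 2)], clean = FALSE)
  rep2 <- measure_facet(flipped, build_frame(flipped, xy_orientation()))
  expect_identical(rep2$curvature_sense, "concave")
  expect_equal(rep2$roc, rep$roc, tolerance = 1e-9)
  expect_equal(rep2$surface_area, rep$surface_area, tolerance = 1e-9)
  expect_equal(rep2$mid_sagittal_length, rep$mid_sagittal_length, tolerance = 1e-9)
})

test_that("a hemispherical facet reports its analytic area, length and width", {
  g <- generate_cap(cap_spec(10, 90, resolution = 0.3, noise_sd = 0, elongation = 1, seed = 1))
  fr <- anatomical_frame(origin = area_centroid_of(g$mesh))
  rep <- measure_facet(g$mesh, fr)
  expect_equal(rep$surface_area, 2 * pi * 100, tolerance = 0.005)
  expect_equal(rep$mid_sagittal_length, pi * 10, tolerance = 0.005)
  expect_equal(rep$mid_coronal_width, pi * 10, tolerance = 0.005)
})

test_that("planar facets are reported with plane statistics instead of a radius", {
  m <- tilted_plane_facet(0)
  fr <- anatomical_frame(origin = colMeans(m$vertices))
  expect_warning(rep <- measure_facet(m, fr), "planar")
  expect_true(is.na(rep$roc))
  expect_lt(rep$mean_abs_error, 1e-9)
})

test_that("dorsal flattening is flagged on constructed surfaces only", {
  ori <- xy_orientation()
  pure <- generate_cap(cap_spec(10, 60, resolution = 0.35, noise_sd = 0, seed = 1))
  fr <- build_frame(pure$mesh, ori)
  expect_false(detect_dorsal_flattening(pure$mesh, fr)$flagged)

  flat <- generate_flattened_cap(cap_spec(10, 60, resolution = 0.35, noise_sd = 0, seed = 2))
  fr2 <- build_frame(flat$mesh, ori)
  det <- detect_dorsal_flattening(flat$mesh, fr2)
  expect_true(det$flagged)
  expect_gt(det$sphere_mean_abs_error, 0.25)

  # an infinite threshold dominates any geometry
  expect_false(detect_dorsal_flattening(flat$mesh, fr2, threshold = Inf)$flagged)
})

test_that("bicondylar decomposition recovers generating spheres, split and divergence", {
  ori <- xy_orientation()
  for (case in list(
    list(rr = 7.47, ru = 8.07, div = 10.99, tgt = 29, sense = "convex"),
    list(rr = 7.92, ru = 11.63, div = 21.4, tgt = 30.21, sense = "concave")
  )) {
    g <- generate_bicondylar(bicondylar_spec(case$rr, case$ru, case$div,
                                             ulnar_area_target = case$tgt, noise_sd = 0,
                                             resolution = 0.25, sense = case$sense, seed = 1))
    fr <- build_frame(g$mesh, ori)
    bc <- partition_bicondylar(g$mesh, fr)
    expect_lt(abs(bc$radial_fit$radius - case$rr) / case$rr, 0.02)
    expect_lt(abs(bc$ulnar_fit$radius - case$ru) / case$ru, 0.02)
    expect_lt(abs(bc$divergence_angle - case$div), 1)
    expect_lt(abs(bc$ulnar_area_fraction - case$tgt), 3)
    expect_equal(bc$radial_area_fraction + bc$ulnar_area_fraction, 100, tolerance = 1e-9)
    expect_true(bc$converged)
    sense <- if (case$sense == "convex") "convex" else "concave"
    expect_identical(bc$radial_fit$curvature_sense, sense)
  }
})

test_that("the alternating fit does not increase the objective and is label-stable", {
  ori <- xy_orientation()
  g <- generate_bicondylar(bicondylar_spec(7.47, 8.07, 10.99, ulnar_area_target = 30,
                                           noise_sd = 0.1, resolution = 0.25, seed = 6))
  fr <- build_frame(g$mesh, ori)
  bc <- partition_bicondylar(g$mesh, fr)

  co <- facetmorph_frame_coords(g$mesh$vertices, fr)[, "c"]
  sse_for <- function(sel) {
    fa <- fit_sphere(g$mesh$vertices[sel, , drop = FALSE])
    fb <- fit_sphere(g$mesh$vertices[!sel, , drop = FALSE])
    sphere_sse(g$mesh$vertices[sel, , drop = FALSE], fa$center, fa$radius) +
      sphere_sse(g$mesh$vertices[!sel, , drop = FALSE], fb$center, fb$radius)
  }
  init <- co > median(co)
  final <- bc$assignment == "ulnar"
  expect_lte(sse_for(final), sse_for(init) + 1e-9)

  # swapping the initial groups yields the same partition up to names
  swapped_init <- ifelse(init, "radial", "ulnar")
  bc2 <- partition_bicondylar(g$mesh, fr, labels = swapped_init)
  expect_identical(bc2$assignment, bc$assignment)
  expect_equal(bc2$radial_fit$radius, bc$radial_fit$radius, tolerance = 1e-9)
})

test_that("a unicondylar cap yields near-identical radii and a lowered flag", {
  g <- generate_cap(cap_spec(10, 60, resolution = 0.35, noise_sd = 0, seed = 1))
  fr <- build_frame(g$mesh, xy_orientation())
  res <- tryCatch(partition_bicondylar(g$mesh, fr), error = function(e) e)
  if (inherits(res, "fm_degenerate_partition")) {
    succeed("degenerate partition signalled")
  } else {
    expect_lt(
      abs(res$radial_fit$radius - res$ulnar_fit$radius) /
        mean(c(res$radial_fit$radius, res$ulnar_fit$radius)),
      0.01
    )
    expect_false(res$bicondylar)
  }
})

test_that("divergence and inter-facet angles are invariant under rigid motion", {
  ori <- xy_orientation()
  g <- generate_bicondylar(bicondylar_spec(7.92, 11.63, 21.4, ulnar_area_target = 30.21,
                                           noise_sd = 0, resolution = 0.3, sense = "concave",
                                           seed = 1))
  fr <- build_frame(g$mesh, ori)
  bc <- partition_bicondylar(g$mesh, fr)

  rot <- random_rotation(21)
  shift <- c(4, -2, 6)
  moved <- transform_mesh(g$mesh, rot, shift)
  ori2 <- orientation_spec(as.vector(rot %*% c(1, 0, 0)), as.vector(rot %*% c(0, 1, 0)),
                           source = "landmarks")
  bc2 <- partition_bicondylar(moved, build_frame(moved, ori2))
  expect_equal(bc2$divergence_angle, bc$divergence_angle, tolerance = 1e-6)
  expect_equal(bc2$ulnar_area_fraction, bc$ulnar_area_fraction, tolerance = 1e-6)

  f4 <- tilted_plane_facet(0, name = "f4")
  f5 <- tilted_plane_facet(33.94, y_range = c(-6, -0.5), name = "f5")
  frame <- anatomical_frame()
  a <- interfacet_angle(f4, f5, frame)
  f4m <- transform_mesh(f4, rot, shift)
  f5m <- transform_mesh(f5, rot, shift)
  frame_m <- anatomical_frame(origin = as.vector(rot %*% c(0, 0, 0) + shift),
                              sagittal = as.vector(rot %*% c(1, 0, 0)),
                              coronal = as.vector(rot %*% c(0, 1, 0)))
  expect_equal(interfacet_angle(f4m, f5m, frame_m), a, tolerance = 1e-6)
})

test_that("inter-facet angles recover constructed dihedrals", {
  frame <- anatomical_frame()
  for (ang in c(0, 33.94, 90)) {
    f4 <- tilted_plane_facet(0, name = "f4")
    f5 <- tilted_plane_facet(ang, y_range = c(-6, -0.5), name = "f5")
    expect_lt(abs(interfacet_angle(f4, f5, frame) - ang), 0.5)
  }
  # empty cross-section errors
  f_far <- transform_mesh(tilted_plane_facet(0), translation = c(100, 0, 0))
  expect_error(interfacet_angle(f_far, tilted_plane_facet(10, y_range = c(-6, -0.5)), frame),
               class = "fm_no_intersection")
})

test_that("area fractions are exact on face subsets", {
  m <- unit_square_mesh()
  expect_equal(area_fraction(1, m), 50)
  expect_equal(area_fraction(1:2, m), 100)
  expect_equal(area_fraction(integer(0), m), 0)
  g <- generate_cap(cap_spec(6, 45, resolution = 0.4, noise_sd = 0, seed = 2))
  k <- nrow(g$mesh$faces)
  expect_equal(area_fraction(1:k, g$mesh), 100, tolerance = 1e-12)
})

test_that("the mid-axial three-point radius matches the generating sphere", {
  g <- generate_cap(cap_spec(9.66, 55, resolution = 0.35, noise_sd = 0, seed = 3))
  fr <- build_frame(g$mesh, xy_orientation())
  expect_equal(facet_three_point_roc(g$mesh, fr), 9.66, tolerance = 0.02)
})

test_that("tidiers summarise fitted objects as tibbles", {
  g <- generate_bicondylar(bicondylar_spec(7.47, 8.07, 10.99, noise_sd = 0,
                                           resolution = 0.3, seed = 1))
  fr <- build_frame(g$mesh, xy_orientation())
  bc <- partition_bicondylar(g$mesh, fr)
  td <- tidy(bc)
  expect_identical(td$condyle, c("radial", "ulnar"))
  gl <- glance(bc)
  expect_equal(gl$radial_roc, bc$radial_fit$radius)
  sf <- fit_sphere(g$mesh$vertices[bc$assignment == "radial", ])
  expect_identical(tidy(sf)$term, c("center_x", "center_y", "center_z", "radius"))
  expect_equal(glance(sf)$radius, sf$radius)
  p <- autoplot(bc)
  expect_s3_class(p, "ggplot")
})
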