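test_that("cap generation is deterministic and matches its analytic area", {
  spec <- cap_spec(10, 90, resolution = 0.3, noise_sd = 0, elongation = 1, seed = 1)
  g <- generate_cap(spec)
  expect_equal(surface_area(g$mesh), g$truth$analytic_area, tolerance = 0.005)
  expect_equal(g$truth$analytic_area, 2 * pi * 100)

  spec2 <- cap_spec(8, 60, resolution = 0.4, noise_sd = 0.1, seed = 42)
  a <- generate_cap(spec2)
  b <- generate_cap(spec2)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$faces, b$mesh$faces)
})

test_that("generator noise reproduces the requested radial sd", {
  spec <- cap_spec(10, 70, resolution = 0.3, noise_sd = 0.1, elongation = 1, seed = 7)
  g <- generate_cap(spec)
  expect_gt(nrow(g$mesh$vertices), 4000)
  # oracle: the radial residuals against the generating sphere ARE the draws
  resid <- sqrt(rowSums(g$mesh$vertices^2)) - 10
  expect_equal(sd(resid), 0.1, tolerance = 0.05)
})

test_that("elongation makes the facet longer than wide while keeping curvature exact", {
  g <- generate_cap(cap_spec(9, 50, resolution = 0.35, noise_sd = 0, elongation = 1.6, seed = 1))
  fr <- build_frame(g$mesh, xy_orientation())
  rep <- measure_facet(g$mesh, fr)
  expect_gt(rep$mid_sagittal_length, 1.15 * rep$mid_coronal_width)
  expect_equal(rep$roc, 9, tolerance = 1e-7)
})

test_that("too-coarse resolution raises an under-resolution error", {
  expect_error(generate_cap(cap_spec(4, 30, resolution = 3, noise_sd = 0, seed = 1)),
               class = "fm_under_resolution")
})

test_that("flattened caps record a ground-truth dorsal region with the required error", {
  g <- generate_flattened_cap(cap_spec(10, 60, resolution = 0.35, noise_sd = 0, seed = 3))
  expect_gt(g$truth$noise_free_mean_abs_error, 0.25)
  expect_true(all(g$truth$flat_vertices <= nrow(g$mesh$vertices)))
  # the flat region lies entirely dorsal of its split coordinate
  xs <- g$mesh$vertices[, 1]
  cut <- min(xs[g$truth$flat_vertices])
  others <- setdiff(seq_along(xs), g$truth$flat_vertices)
  expect_true(all(xs[others] <= cut + 1e-9))
  expect_error(
    generate_flattened_cap(cap_spec(10, 60, noise_sd = 0, seed = 1), flat_fraction = 0.9),
    class = "fm_validation_error"
  )
})

test_that("bicondylar ground truth hits the requested area split and labels are consistent", {
  g <- generate_bicondylar(bicondylar_spec(7.47, 8.07, 10.99, ulnar_area_target = 30,
                                           noise_sd = 0, resolution = 0.25, seed = 1))
  tr <- g$truth
  expect_length(tr$vertex_label, nrow(g$mesh$vertices))
  expect_length(tr$face_label, nrow(g$mesh$faces))
  # oracle: direct area sum over labelled faces
  areas <- numeric(nrow(g$mesh$faces))
  v <- g$mesh$vertices
  f <- g$mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  cr <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  areas <- 0.5 * sqrt(rowSums(cr^2))
  frac <- 100 * sum(areas[tr$face_label == "ulnar"]) / sum(areas)
  expect_equal(frac, tr$ulnar_area_fraction, tolerance = 1e-9)
  expect_lt(abs(frac - 30), 3)

  # determinism
  g2 <- generate_bicondylar(bicondylar_spec(7.47, 8.07, 10.99, ulnar_area_target = 30,
                                            noise_sd = 0, resolution = 0.25, seed = 1))
  expect_identical(g2$mesh$vertices, g$mesh$vertices)
})

test_that("symmetric equal-radius construction gives 50/50 split and no divergence", {
  g <- generate_bicondylar(bicondylar_spec(8, 8, 0, ulnar_area_target = 50,
                                           noise_sd = 0, resolution = 0.25, seed = 2))
  expect_lt(abs(g$truth$ulnar_area_fraction - 50), 2)
  expect_lt(g$truth$divergence, 1)
})

test_that("unreachable area targets raise an infeasibility error", {
  expect_error(
    generate_bicondylar(bicondylar_spec(18, 4.5, 10, ulnar_area_target = 90,
                                        noise_sd = 0, resolution = 0.4, seed = 1)),
    class = "fm_infeasible"
  )
})

test_that("study cohorts are deterministic and draw radii from the published envelope", {
  a <- generate_study_cohort(3, seed = 5, noise_sd = 0.05, resolution = 0.45)
  b <- generate_study_cohort(3, seed = 5, noise_sd = 0.05, resolution = 0.45)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(
    a$facets[[1]]$mesh$vertices,
    b$facets[[1]]$mesh$vertices
  )
  h4 <- dplyr::filter(a$ground_truth, role == "hamate4")
  expect_true(all(h4$true_roc >= 4.12 & h4$true_roc <= 21.07))
  expect_equal(nrow(a$ground_truth), 18)
  expect_setequal(unique(a$ground_truth$role),
                  c("hamate4", "mc4_base", "hamate5", "mc5_base", "imc4", "imc5"))
})
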