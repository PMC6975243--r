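# Synthetic spherical-cap facets with ground truth. These emulate
# laser-scanned articular patches: spherical caps in the radius envelope
# of the hamate/metacarpal facets, elongated footprints (length > width),
# and radial Gaussian noise at the scanner's accuracy.

#' Specification of a synthetic spherical-cap facet
#'
#' @param radius Sphere radius in mm.
#' @param cap_angle Half-angle of the cap in degrees (0, 90].
#' @param resolution Target edge length in mm (default 0.15).
#' @param noise_sd Radial Gaussian noise sd in mm (default 0.1, one sd of
#'   the scanner's stated accuracy).
#' @param sense `"convex"` or `"concave"` facet (normal orientation).
#' @param elongation Axis stretch (>= 1) of the cap footprint along the
#'   sagittal direction; stretched points are re-projected onto the
#'   sphere, so the curvature ground truth is exact while length exceeds
#'   width. Default 1.6.
#' @param seed Integer RNG seed for the noise.
#' @return A `cap_spec` list.
#' @export
cap_spec <- function(radius, cap_angle, resolution = 0.15, noise_sd = 0.1,
                     sense = c("convex", "concave"), elongation = 1.6, seed = 1L) {
  sense <- match.arg(sense)
  if (!is.finite(radius) || radius <= 0) fm_abort("radius must be positive", "fm_validation_error")
  if (!is.finite(cap_angle) || cap_angle <= 0 || cap_angle > 90) {
    fm_abort("cap_angle must lie in (0, 90] degrees", "fm_validation_error")
  }
  if (noise_sd < 0) fm_abort("noise_sd must be >= 0", "fm_validation_error")
  if (resolution <= 0) fm_abort("resolution must be positive", "fm_validation_error")
  if (elongation < 1) fm_abort("elongation must be >= 1", "fm_validation_error")
  structure(
    list(
      radius = radius, cap_angle = cap_angle, resolution = resolution,
      noise_sd = noise_sd, sense = sense, elongation = elongation,
      seed = as.integer(seed)
    ),
    class = "cap_spec"
  )
}

# Ring-based geodesic triangulation of a spherical cap (apex at +z,
# sphere centred at the origin). Returns vertices/faces; normals are
# oriented outward (+radial) afterwards.
triangulate_cap <- function(radius, cap_angle_deg, resolution) {
  theta <- cap_angle_deg * pi / 180
  K <- max(3L, ceiling(radius * theta / resolution))
  verts <- matrix(c(0, 0, radius), 1, 3)
  ring_idx <- list(1L)
  ring_ang <- list(0)
  for (k in seq_len(K)) {
    phi <- theta * k / K
    rk <- radius * sin(phi)
    nk <- max(6L, ceiling(2 * pi * rk / resolution))
    ang <- 2 * pi * (seq_len(nk) - 1 + 0.5 * (k %% 2)) / nk
    ring <- cbind(rk * cos(ang), rk * sin(ang), radius * cos(phi))
    idx <- nrow(verts) + seq_len(nk)
    verts <- rbind(verts, ring)
    ring_idx[[k + 1]] <- idx
    ring_ang[[k + 1]] <- ang
  }
  faces <- matrix(0L, 0, 3)
  # apex fan
  r1 <- ring_idx[[2]]
  n1 <- length(r1)
  faces <- rbind(faces, cbind(1L, r1, r1[c(2:n1, 1)]))
  # stitch successive rings by merging their angular sequences
  for (k in seq_len(K - 1) + 1L) {
    faces <- rbind(faces, stitch_rings(ring_idx[[k]], ring_ang[[k]],
                                       ring_idx[[k + 1]], ring_ang[[k + 1]]))
  }
  list(vertices = verts, faces = faces)
}

# Triangulate the band between two concentric rings given vertex indices
# and their angular positions (both ascending in [0, 2pi)).
stitch_rings <- function(ia, aa, ib, ab) {
  nA <- length(ia); nB <- length(ib)
  faces <- matrix(0L, nA + nB, 3)
  nf <- 0L
  i <- 1L; j <- 1L
  adv_a <- 0L; adv_b <- 0L
  next_ang <- function(ang, pos, n, adv) {
    nx <- pos %% n + 1L
    ang[nx] + 2 * pi * ((adv + 1L) %/% n)
  }
  while (adv_a < nA || adv_b < nB) {
    ca <- if (adv_a < nA) next_ang(aa, i, nA, adv_a) else Inf
    cb <- if (adv_b < nB) next_ang(ab, j, nB, adv_b) else Inf
    if (ca <= cb) {
      ni <- i %% nA + 1L
      nf <- nf + 1L
      faces[nf, ] <- c(ia[i], ia[ni], ib[j])
      i <- ni; adv_a <- adv_a + 1L
    } else {
      nj <- j %% nB + 1L
      nf <- nf + 1L
      faces[nf, ] <- c(ia[i], ib[nj], ib[j])
      j <- nj; adv_b <- adv_b + 1L
    }
  }
  faces[seq_len(nf), , drop = FALSE]
}

# Orient all face windings so normals point along +radial from `center`.
orient_faces_radial <- function(verts, faces, center = c(0, 0, 0), outward = TRUE) {
  fc <- (verts[faces[, 1], , drop = FALSE] + verts[faces[, 2], , drop = FALSE] +
           verts[faces[, 3], , drop = FALSE]) / 3
  e1 <- verts[faces[, 2], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  e2 <- verts[faces[, 3], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  nrm <- cross3_rows(e1, e2)
  dir <- sweep(fc, 2, center)
  dot <- rowSums(nrm * dir)
  flip <- if (outward) dot < 0 else dot > 0
  faces[flip, ] <- faces[flip, c(1, 3, 2), drop = FALSE]
  faces
}

#' Generate a synthetic spherical-cap facet
#'
#' Builds a geodesic triangulation of a spherical cap (apex at +z, sphere
#' centred at the origin), stretches the footprint along x (the sagittal
#' direction) by `elongation` with re-projection onto the sphere, adds
#' radial Gaussian noise, and orients normals outward from the bone
#' (away from the centre for a convex facet, toward it for concave).
#'
#' @param spec A [cap_spec()], or arguments passed to [cap_spec()].
#' @param ... Passed to [cap_spec()] when `spec` is not already one.
#' @return List with `mesh` (a [facet_mesh()]) and `truth`: the spec
#'   echo, analytic (unstretched) cap area `2*pi*R*h`, sphere `center`
#'   and `radius`, noise-free vertex radii, and generator version.
#' @export
generate_cap <- function(spec, ...) {
  if (!inherits(spec, "cap_spec")) spec <- cap_spec(spec, ...)
  tri <- triangulate_cap(spec$radius, spec$cap_angle, spec$resolution)
  v <- tri$vertices
  if (spec$elongation > 1) {
    v[, 1] <- v[, 1] * spec$elongation
    len <- sqrt(rowSums(v^2))
    v <- v * (spec$radius / len)
  }
  if (nrow(v) < 50) {
    fm_abort(
      sprintf("resolution %.3g mm yields only %d vertices (< 50); refine the resolution", spec$resolution, nrow(v)),
      "fm_under_resolution"
    )
  }
  if (spec$noise_sd > 0) {
    offs <- with_seed(spec$seed, rnorm(nrow(v), 0, spec$noise_sd))
    v <- v * (1 + offs / spec$radius)  # displacement along the radial direction
  }
  faces <- orient_faces_radial(v, tri$faces, outward = spec$sense == "convex")
  mesh <- facet_mesh(v, faces, name = sprintf("cap_r%.2f", spec$radius), clean = TRUE)
  h <- spec$radius * (1 - cos(spec$cap_angle * pi / 180))
  truth <- list(
    spec = spec,
    center = c(0, 0, 0),
    radius = spec$radius,
    sense = spec$sense,
    analytic_area = 2 * pi * spec$radius * h,
    generator = "facetmorph-cap-1"
  )
  list(mesh = mesh, truth = truth)
}

#' Generate a cap with a flattened dorsal region
#'
#' The dorsal `flat_fraction` of the cap (vertices above the
#' corresponding sagittal-coordinate quantile; dorsal = +sagittal = +x)
#' is projected onto the plane tangent to the sphere at the region's
#' centroid, emulating the dorsally flattened fourth-CMC articulations.
#' The generator verifies that the best single-sphere fit of the
#' noise-free flattened surface has mean absolute error above
#' `error_floor` (the flattening criterion), escalating `flat_fraction`
#' in 0.05 steps up to 0.8 if not, and errors if the criterion cannot be
#' reached.
#'
#' @param spec A [cap_spec()].
#' @param flat_fraction Fraction of vertices (by sagittal coordinate)
#'   flattened, in (0.1, 0.8). Default 0.4.
#' @param error_floor Required noise-free sphere mean absolute error in
#'   mm (default 0.25).
#' @return As [generate_cap()]; `truth` additionally carries
#'   `flat_vertices` (indices), `flat_fraction_used` and
#'   `noise_free_mean_abs_error`.
#' @export
generate_flattened_cap <- function(spec, flat_fraction = 0.4, error_floor = 0.25) {
  if (!inherits(spec, "cap_spec")) fm_abort("'spec' must be a cap_spec", "fm_validation_error")
  if (flat_fraction <= 0.1 || flat_fraction >= 0.8) {
    fm_abort("flat_fraction must lie in (0.1, 0.8)", "fm_validation_error")
  }
  base <- generate_cap(modifyList_spec(spec, noise_sd = 0))
  v0 <- base$mesh$vertices
  f0 <- base$mesh$faces

  ff <- flat_fraction
  repeat {
    v <- v0
    cut <- quantile(v[, 1], 1 - ff)
    flat_idx <- which(v[, 1] >= cut)
    ctr <- colMeans(v[flat_idx, , drop = FALSE])
    qpt <- normalize(ctr) * spec$radius          # tangency point on the sphere
    nrm <- normalize(qpt)
    dd <- sweep(v[flat_idx, , drop = FALSE], 2, qpt) %*% nrm
    v[flat_idx, ] <- v[flat_idx, , drop = FALSE] - dd %*% t(nrm)
    err <- fit_sphere(v)$mean_abs_error
    if (err > error_floor) break
    ff <- ff + 0.05
    if (ff > 0.8) {
      fm_abort(
        sprintf("flattening cannot reach a %.2f mm sphere error within flat_fraction <= 0.8", error_floor),
        "fm_infeasible"
      )
    }
  }
  if (spec$noise_sd > 0) {
    offs <- with_seed(spec$seed, rnorm(nrow(v), 0, spec$noise_sd))
    nrms <- v0 / sqrt(rowSums(v0^2))
    v <- v + nrms * offs
  }
  faces <- orient_faces_radial(v0, f0, outward = spec$sense == "convex")
  # clean = FALSE: vertex indices must stay aligned with truth$flat_vertices
  mesh <- facet_mesh(v, faces, name = sprintf("flatcap_r%.2f", spec$radius), clean = FALSE)
  truth <- base$truth
  truth$spec <- spec
  truth$flat_vertices <- flat_idx
  truth$flat_fraction_used <- ff
  truth$noise_free_mean_abs_error <- err
  truth$generator <- "facetmorph-flatcap-1"
  list(mesh = mesh, truth = truth)
}

# Return a cap_spec with some fields replaced.
modifyList_spec <- function(spec, ...) {
  repl <- list(...)
  for (nm in names(repl)) spec[[nm]] <- repl[[nm]]
  spec
}
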