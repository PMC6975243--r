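# Synthetic bicondylar surfaces: two overlapping-sphere cap patches
# joined along a ridge running in the sagittal direction, emulating the
# biconvex fifth metacarpal base (and, mirrored, the biconcave hamate
# facet). Ground truth carries the generating spheres, per-vertex and
# per-face condyle labels, the achieved ulnar area fraction and the
# achieved angle of divergence (centre-to-centroid rays in the
# coronal-normal plane).

#' Specification of a synthetic bicondylar facet
#'
#' @param radial_radius,ulnar_radius Sphere radii in mm.
#' @param divergence Target angle of divergence in degrees, in \[0, 90).
#' @param ulnar_area_target Target ulnar area fraction in percent
#'   (default 30), in (5, 95).
#' @param overlap Ridge blend width in mm over which the two sphere
#'   heights are cross-faded (0 = sharp ridge, the default; the true
#'   ridge shape is not quantified, so this is a free parameter).
#' @param noise_sd Radial noise sd in mm (default 0.1).
#' @param resolution Grid spacing in mm (default 0.15).
#' @param sense `"convex"` (metacarpal base) or `"concave"` (hamate).
#' @param seed Integer RNG seed.
#' @return A `bicondylar_spec` list.
#' @export
bicondylar_spec <- function(radial_radius, ulnar_radius, divergence,
                            ulnar_area_target = 30, overlap = 0,
                            noise_sd = 0.1, resolution = 0.15,
                            sense = c("convex", "concave"), seed = 1L) {
  sense <- match.arg(sense)
  if (radial_radius <= 0 || ulnar_radius <= 0) fm_abort("radii must be positive", "fm_validation_error")
  if (divergence < 0 || divergence >= 90) fm_abort("divergence must lie in [0, 90) degrees", "fm_validation_error")
  if (ulnar_area_target <= 5 || ulnar_area_target >= 95) {
    fm_abort("ulnar_area_target must lie in (5, 95) percent", "fm_validation_error")
  }
  if (noise_sd < 0 || resolution <= 0 || overlap < 0) {
    fm_abort("invalid noise_sd/resolution/overlap", "fm_validation_error")
  }
  structure(
    list(
      radial_radius = radial_radius, ulnar_radius = ulnar_radius,
      divergence = divergence, ulnar_area_target = ulnar_area_target,
      overlap = overlap, noise_sd = noise_sd, resolution = resolution,
      sense = sense, seed = as.integer(seed)
    ),
    class = "bicondylar_spec"
  )
}

# Build one biconvex mesh for construction parameters:
#   delta_c : construction divergence (deg, signed; condyle normals tilt apart)
#   ridge   : coronal coordinate of the ridge separating the condyles (mm)
# Axes: x sagittal, y coronal (+y = ulnar), z normal.
bicondylar_build <- function(spec, delta_c, ridge, resolution) {
  Rr <- spec$radial_radius
  Ru <- spec$ulnar_radius
  theta0 <- 32 * pi / 180                 # nominal condylar half-angle
  wr <- Rr * sin(theta0)
  wu <- Ru * sin(theta0)
  half <- delta_c / 2 * pi / 180
  dr <- c(0, -sin(half), cos(half))
  du <- c(0, sin(half), cos(half))
  y_min <- -0.9 * wr
  y_max <- 0.9 * wu
  # each condylar apex sits at the centre of its strip, so every condyle
  # shows its cap (not a flank) and the two surfaces meet at a ridge
  ar <- c(0, (y_min + ridge) / 2, 0)
  au <- c(0, (ridge + y_max) / 2, 0)
  cr <- ar - Rr * dr                      # sphere centres
  cu <- au - Ru * du
  W <- y_max - y_min
  L <- 1.35 * W
  yc <- (y_min + y_max) / 2

  sphere_z <- function(cc, R, x, y) {
    d2 <- (x - cc[1])^2 + (y - cc[2])^2
    z <- rep(NA_real_, length(x))
    ok <- d2 <= (0.95 * R)^2
    z[ok] <- cc[3] + sqrt(R^2 - d2[ok])
    z
  }
  # match the two sphere heights at the ridge centre (0, ridge)
  zr0 <- sphere_z(cr, Rr, 0, ridge)
  zu0 <- sphere_z(cu, Ru, 0, ridge)
  if (!is.finite(zr0) || !is.finite(zu0)) {
    fm_abort("ridge lies outside a generating sphere; adjust targets", "fm_infeasible")
  }
  cu[3] <- cu[3] + (zr0 - zu0)

  xs <- seq(-L / 2, L / 2, by = resolution)
  # anchor the grid at the ridge so the label boundary is exactly resolved
  # and the area split varies continuously with the ridge position
  ys <- c(rev(seq(ridge, y_min, by = -resolution)), seq(ridge + resolution, y_max, by = resolution))
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  inside <- (gx / (L / 2))^2 + ((gy - yc) / (W / 2))^2 <= 1

  zr <- sphere_z(cr, Rr, gx, gy)
  zu <- sphere_z(cu, Ru, gx, gy)
  is_ulnar <- gy > ridge
  z <- ifelse(is_ulnar, zu, zr)
  if (spec$overlap > 0) {
    w <- pmin(1, pmax(0, (gy - ridge) / spec$overlap + 0.5))
    both <- is.finite(zr) & is.finite(zu)
    z[both] <- (1 - w[both]) * zr[both] + w[both] * zu[both]
  }
  keep <- inside & is.finite(z)
  if (sum(keep) < 50) fm_abort("bicondylar footprint under-resolved", "fm_under_resolution")
  lab <- ifelse(is_ulnar, "ulnar", "radial")

  # grid triangulation over kept nodes
  nxg <- length(xs)
  id <- matrix(NA_integer_, nxg, length(ys))
  id[keep] <- seq_len(sum(keep))
  fa <- list()
  for (j in seq_len(length(ys) - 1)) {
    a <- id[-nxg, j]; b <- id[-1, j]; cI <- id[-1, j + 1]; dI <- id[-nxg, j + 1]
    full <- !is.na(a) & !is.na(b) & !is.na(cI) & !is.na(dI)
    if (any(full)) {
      fa[[length(fa) + 1]] <- cbind(a[full], b[full], cI[full])
      fa[[length(fa) + 1]] <- cbind(a[full], cI[full], dI[full])
    }
    three <- (!is.na(a)) + (!is.na(b)) + (!is.na(cI)) + (!is.na(dI)) == 3 & !full
    for (w in which(three)) {
      tri <- c(a[w], b[w], cI[w], dI[w])
      fa[[length(fa) + 1]] <- matrix(tri[!is.na(tri)], 1, 3)
    }
  }
  faces <- do.call(rbind, fa)
  verts <- cbind(gx[keep], gy[keep], z[keep])
  # orient face normals upward (+z)
  e1 <- verts[faces[, 2], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  e2 <- verts[faces[, 3], , drop = FALSE] - verts[faces[, 1], , drop = FALSE]
  up <- cross3_rows(e1, e2)[, 3] < 0
  faces[up, ] <- faces[up, c(1, 3, 2), drop = FALSE]

  vlab <- lab[keep]
  flab <- rowSums(matrix(vlab[faces] == "ulnar", ncol = 3))
  face_lab <- ifelse(flab >= 2, "ulnar", "radial")
  list(
    vertices = verts, faces = faces, vertex_label = vlab, face_label = face_lab,
    centers = list(radial = cr, ulnar = cu)
  )
}

# Ground-truth divergence: centre-to-label-centroid rays projected onto
# the coronal-normal (y-z) plane. Signed: positive when rays open apart.
bicondylar_truth_divergence <- function(built, signed = TRUE) {
  areas <- face_areas_vf(built$vertices, built$faces)
  fc <- (built$vertices[built$faces[, 1], , drop = FALSE] +
           built$vertices[built$faces[, 2], , drop = FALSE] +
           built$vertices[built$faces[, 3], , drop = FALSE]) / 3
  cen <- function(label) {
    sel <- built$face_label == label
    colSums(fc[sel, , drop = FALSE] * areas[sel]) / sum(areas[sel])
  }
  ray <- function(label) cen(label) - built$centers[[label]]
  rr <- ray("radial"); ru <- ray("ulnar")
  ang <- function(v) atan2(v[2], v[3])   # angle about the x axis in the y-z plane
  out <- (ang(ru) - ang(rr)) * 180 / pi
  if (signed) out else abs(out)
}

bicondylar_ulnar_fraction <- function(built) {
  areas <- face_areas_vf(built$vertices, built$faces)
  100 * sum(areas[built$face_label == "ulnar"]) / sum(areas)
}

#' Generate a synthetic bicondylar facet
#'
#' Constructs two spherical cap patches joined along a sagittal ridge;
#' the spheres' centre-to-condyle-centroid rays subtend the requested
#' divergence in the coronal-normal plane. The ridge position is tuned
#' by bisection so the ulnar condyle carries the requested share of the
#' surface area, and the construction divergence is calibrated by
#' fixed-point iteration; the emitted ground truth therefore matches the
#' requested targets (area fraction within 3 percentage points,
#' divergence within a fraction of a degree) before noise is added.
#'
#' @param spec A [bicondylar_spec()], or arguments forwarded to it.
#' @param ... Passed to [bicondylar_spec()] when `spec` is not one.
#' @return List with `mesh` and `truth` (spec echo, sphere centres and
#'   radii, per-vertex and per-face condyle labels, achieved
#'   `ulnar_area_fraction` and `divergence`, generator version).
#' @export
generate_bicondylar <- function(spec, ...) {
  if (!inherits(spec, "bicondylar_spec")) spec <- bicondylar_spec(spec, ...)
  res_coarse <- max(spec$resolution * 2, 0.45)
  theta0 <- 32 * pi / 180
  y_min <- -0.9 * spec$radial_radius * sin(theta0)
  y_max <- 0.9 * spec$ulnar_radius * sin(theta0)
  margin <- 0.15 * (y_max - y_min)
  t_lo <- y_min + margin
  t_hi <- y_max - margin

  frac_at <- function(delta_c, t, res) {
    bicondylar_ulnar_fraction(bicondylar_build(spec, delta_c, t, res))
  }
  tune_ridge <- function(delta_c, res, lo = t_lo, hi = t_hi, tol = 0.2, guard = TRUE) {
    f_lo <- frac_at(delta_c, lo, res)   # ridge near radial edge -> large ulnar share
    f_hi <- frac_at(delta_c, hi, res)
    if (!guard && (spec$ulnar_area_target >= f_lo || spec$ulnar_area_target <= f_hi)) {
      return(if (spec$ulnar_area_target >= f_lo) lo else hi)
    }
    if (spec$ulnar_area_target > f_lo + 0.5 || spec$ulnar_area_target < f_hi - 0.5) {
      fm_abort(
        sprintf(
          "ulnar_area_target %.1f%% infeasible for radii %.2f/%.2f (reachable %.1f-%.1f%%)",
          spec$ulnar_area_target, spec$radial_radius, spec$ulnar_radius, f_hi, f_lo
        ),
        "fm_infeasible"
      )
    }
    t <- (lo + hi) / 2
    for (it in 1:25) {
      t <- (lo + hi) / 2
      fr <- frac_at(delta_c, t, res)
      if (abs(fr - spec$ulnar_area_target) < tol) break
      if (fr > spec$ulnar_area_target) lo <- t else hi <- t  # fraction decreases with t
    }
    t
  }
  calibrate_delta <- function(delta_c, t, res, tol = 0.05) {
    for (it in 1:6) {
      achieved <- bicondylar_truth_divergence(bicondylar_build(spec, delta_c, t, res))
      if (abs(achieved - spec$divergence) < tol) break
      delta_c <- delta_c + (spec$divergence - achieved)
      if (abs(delta_c) > 80) fm_abort("divergence calibration diverged", "fm_infeasible")
    }
    delta_c
  }

  delta_c <- spec$divergence
  ridge <- 0
  for (outer in 1:2) {
    ridge <- tune_ridge(delta_c, res_coarse)
    delta_c <- calibrate_delta(delta_c, ridge, res_coarse)
  }
  # polish both at the final resolution
  delta_c <- calibrate_delta(delta_c, ridge, spec$resolution)
  ridge <- tune_ridge(delta_c, spec$resolution,
                      lo = max(t_lo, ridge - 1.5), hi = min(t_hi, ridge + 1.5),
                      guard = FALSE)

  built <- bicondylar_build(spec, delta_c, ridge, spec$resolution)
  ach_div <- abs(bicondylar_truth_divergence(built))
  ach_frac <- bicondylar_ulnar_fraction(built)
  if (abs(ach_frac - spec$ulnar_area_target) > 3) {
    fm_abort(
      sprintf("achieved ulnar area fraction %.1f%% misses target %.1f%% by more than 3 points",
              ach_frac, spec$ulnar_area_target),
      "fm_infeasible"
    )
  }

  v <- built$vertices
  faces <- built$faces
  centers <- built$centers
  if (spec$sense == "concave") {
    v[, 3] <- -v[, 3]
    centers$radial[3] <- -centers$radial[3]
    centers$ulnar[3] <- -centers$ulnar[3]
    # the z-reflection maps face normals n to (-nx, -ny, +nz): they already
    # point +z, outward from the bone and toward the centres, as a concave
    # facet requires — no winding flip needed
  }
  mesh0 <- structure(list(vertices = v, faces = faces, name = "bicondylar"), class = "facet_mesh")
  if (spec$noise_sd > 0) {
    nrms <- vertex_normals(mesh0)
    offs <- with_seed(spec$seed, rnorm(nrow(v), 0, spec$noise_sd))
    v <- v + nrms * offs
  }
  mesh <- facet_mesh(v, faces, name = "bicondylar", clean = FALSE)
  truth <- list(
    spec = spec,
    centers = centers,
    radii = c(radial = spec$radial_radius, ulnar = spec$ulnar_radius),
    vertex_label = built$vertex_label,
    face_label = built$face_label,
    ulnar_area_fraction = ach_frac,
    divergence = ach_div,
    generator = "facetmorph-bicondylar-2"
  )
  list(mesh = mesh, truth = truth)
}
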